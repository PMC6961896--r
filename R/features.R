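# The feature registry and the full per-patient extraction. Five
# channels (original patch + four Haar subbands) x (14 first-order +
# 22 GLCM stats x 4 angles + 11 GLRLM stats x 4 angles) = 5 x 146 = 730
# features in a fixed, named order.

.fo_names <- c("mean", "variance", "sd", "skewness", "kurtosis", "energy",
               "entropy", "min", "max", "median", "range", "rms", "mad",
               "uniformity")
.glcm_names <- c("autocorrelation", "contrast", "correlation",
                 "cluster_prominence", "cluster_shade", "dissimilarity",
                 "energy", "entropy", "homogeneity", "idm",
                 "max_probability", "sum_of_squares", "sum_average",
                 "sum_variance", "sum_entropy", "difference_variance",
                 "difference_entropy", "imc1", "imc2", "idn", "idmn",
                 "marginal_mean")
.glrlm_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                  "srlge", "srhge", "lrlge", "lrhge")
.angles <- c(0, 45, 90, 135)
.channels <- c("orig", "LL", "LH", "HL", "HH")

#' The ordered 730-feature registry
#'
#' Feature names have the form `<channel>_<family>_<statistic>[_<angle>]`
#' with channel in orig/LL/LH/HL/HH. Per channel: 14 first-order, 22
#' GLCM statistics at each of 4 angles, 11 GLRLM statistics at each of 4
#' angles (146); five channels give 730 unique names.
#'
#' @param channels channel subset (default all five).
#' @return character vector of feature names in extraction order.
#' @export
feature_registry <- function(channels = .channels) {
  unlist(lapply(channels, function(ch) {
    c(paste(ch, "fo", .fo_names, sep = "_"),
      unlist(lapply(.angles, function(a)
        paste(ch, "glcm", .glcm_names, a, sep = "_"))),
      unlist(lapply(.angles, function(a)
        paste(ch, "glrlm", .glrlm_names, a, sep = "_"))))
  }), use.names = FALSE)
}

# registry size is a structural invariant, checked when the package loads
.onLoad <- function(libname, pkgname) {
  reg <- feature_registry()
  stopifnot(length(reg) == 730L, !anyDuplicated(reg))
}

# 146 features of one channel: the patch must already be on its final
# intensity scale (normalized original, or raw wavelet coefficients).
.channel_features <- function(patch, channel, levels, clip, distance) {
  q <- quantize(patch, levels = levels, clip = clip)
  fo <- first_order_features(patch)
  gl <- unlist(lapply(.angles, function(a)
    glcm_features(compute_glcm(q, distance = distance, angle = a))))
  rl <- unlist(lapply(.angles, function(a)
    glrlm_features(compute_glrlm(q, angle = a))))
  unname(c(fo, gl, rl))
}

#' Extract the full 730-feature radiomics vector from one patch
#'
#' Applies the first-order, GLCM (4 angles) and GLRLM (4 angles) feature
#' sets to the normalized patch and to each of its four single-level
#' Haar wavelet subbands. Each subband is re-quantized independently
#' with the same gray-level count and clipping rule. Non-finite values
#' (degenerate statistics on constant regions) are replaced by 0 and the
#' affected names are recorded in the `degenerate` attribute.
#'
#' @param patch a normalized `roi_patch` (see [normalize_patch()]).
#' @param levels gray levels for quantization (default 32).
#' @param clip percentile clip pair for quantization (default c(1, 99)).
#' @param distance GLCM pixel distance (default 1).
#' @return named numeric vector of length 730 in [feature_registry()]
#'   order, with attribute `degenerate` listing zero-replaced features.
#' @export
extract_all_features <- function(patch, levels = 32L, clip = c(1, 99),
                                 distance = 1L) {
  stopifnot(inherits(patch, "roi_patch"))
  if (!patch$normalized) stop("patch must be normalized first")
  w <- wavelet_decompose(patch)
  vals <- c(
    .channel_features(patch, "orig", levels, clip, distance),
    .channel_features(.subband_patch(w, "LL"), "LL", levels, clip, distance),
    .channel_features(.subband_patch(w, "LH"), "LH", levels, clip, distance),
    .channel_features(.subband_patch(w, "HL"), "HL", levels, clip, distance),
    .channel_features(.subband_patch(w, "HH"), "HH", levels, clip, distance)
  )
  names(vals) <- feature_registry()
  bad <- !is.finite(vals)
  vals[bad] <- 0
  attr(vals, "degenerate") <- names(vals)[bad]
  vals
}

#' Extract features for every patient of a cohort
#'
#' Runs the ROI pipeline (grayscale conversion, ROI crop, z-
#' normalization, quantization, feature extraction) for each patient and
#' assembles the feature matrix.
#'
#' @param cohort either a list of in-memory patients (each with elements
#'   `patient_id`, `image`, `mask`) as produced by [generate_cohort()],
#'   or a manifest data.frame from [read_manifest()] with file paths.
#' @inheritParams extract_all_features
#' @return numeric matrix, one row per patient (rownames = patient_id),
#'   730 columns in registry order.
#' @export
extract_cohort_features <- function(cohort, levels = 32L, clip = c(1, 99),
                                    distance = 1L) {
  if (is.data.frame(cohort)) {
    ids <- cohort$patient_id
    get_patient <- function(k) {
      img <- tryCatch(read_gray_image(cohort$image[k]),
                      error = function(e) stop("patient ", ids[k], ": ",
                                               conditionMessage(e), call. = FALSE))
      msk <- tryCatch(read_mask(cohort$mask[k]),
                      error = function(e) stop("patient ", ids[k], ": ",
                                               conditionMessage(e), call. = FALSE))
      list(image = img, mask = msk)
    }
    n <- nrow(cohort)
  } else {
    ids <- vapply(cohort, `[[`, "", "patient_id")
    get_patient <- function(k) cohort[[k]]
    n <- length(cohort)
  }
  out <- matrix(NA_real_, n, 730L, dimnames = list(ids, feature_registry()))
  for (k in seq_len(n)) {
    p <- get_patient(k)
    patch <- normalize_patch(extract_roi(p$image, p$mask))
    out[k, ] <- extract_all_features(patch, levels = levels, clip = clip,
                                     distance = distance)
  }
  out
}

#' Write a cohort feature matrix as CSV with a JSON config sidecar
#'
#' @param features matrix from [extract_cohort_features()].
#' @param path output CSV path; `<path>.json` records the extraction
#'   configuration and a registry hash.
#' @param config named list of extraction settings to record.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, config = list()) {
  df <- data.frame(patient_id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  side <- c(config, list(
    n_features = ncol(features),
    registry_hash = registry_hash()
  ))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Stable hash of the feature registry (order-sensitive)
#' @return character scalar.
#' @export
registry_hash <- function() {
  reg <- feature_registry()
  # order-sensitive polynomial rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(paste(reg, collapse = "|")))
    h <- (h * 31 + ch) %% 2147483647
  sprintf("%d-%08x", length(reg), h)
}
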