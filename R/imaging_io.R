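# ---- grayscale images -------------------------------------------------------

#' Convert a raster to an 8-bit grayscale intensity image
#'
#' RGB input is collapsed to luminance with the ITU-R BT.601 weights
#' (0.299, 0.587, 0.114), i.e. hue and saturation are discarded and
#' luminance retained; single-channel input passes through unchanged.
#' Rounding is to the nearest integer (ties to even, R convention).
#'
#' @param x a numeric matrix (grayscale, values in \[0, 255\]) or a
#'   height x width x 3 array of 8-bit RGB values.
#' @return a `gray_image`: a numeric matrix of intensities in \[0, 255\]
#'   with class `"gray_image"`.
#' @export
to_grayscale <- function(x) {
  if (is.matrix(x)) {
    return(gray_image(x))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc == 1L) return(gray_image(x[, , 1L]))
    if (nc %in% c(3L, 4L)) {     # alpha, if present, is ignored
      lum <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
      return(gray_image(round(lum)))
    }
    stop("unsupported channel count: ", nc)
  }
  stop("unsupported image format: expected a matrix or H x W x 3 array")
}

#' Construct and validate a grayscale image
#'
#' @param pixels numeric matrix of intensities in \[0, 255\], at least 2 x 2.
#' @return the validated matrix with class `"gray_image"`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  structure(pixels, class = c("gray_image", class(pixels)))
}

#' Read an image file as a grayscale intensity image
#'
#' Supports 8-bit PNG and JPEG, grayscale or RGB(A). Values are rescaled
#' from the readers' \[0, 1\] convention to \[0, 255\] before luminance
#' conversion.
#'
#' @param path path to a .png, .jpg or .jpeg file.
#' @return a `gray_image`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (expected PNG or JPEG)")
  )
  if (length(dim(raw)) == 3L && dim(raw)[3L] == 2L)
    raw <- raw[, , 1L, drop = TRUE]          # gray + alpha
  if (is.matrix(raw)) return(gray_image(round(raw * 255)))
  to_grayscale(round(raw * 255))
}

# ---- ROI masks --------------------------------------------------------------

#' Construct and validate a binary ROI mask
#'
#' A valid tumor mask has at least 16 foreground pixels forming exactly
#' one 4-connected component.
#'
#' @param pixels logical or 0/1 numeric matrix; nonzero = foreground.
#' @param check_connectivity verify single-component connectivity
#'   (default TRUE; generators that emit convex masks may skip it).
#' @return a logical matrix with class `"roi_mask"`.
#' @export
roi_mask <- function(pixels, check_connectivity = TRUE) {
  if (!is.matrix(pixels)) stop("mask must be a matrix")
  m <- pixels != 0
  m[is.na(m)] <- FALSE
  area <- sum(m)
  if (area < 16L) stop("mask has fewer than 16 foreground pixels")
  if (check_connectivity && !.single_component(m))
    stop("mask foreground is not a single 4-connected component")
  structure(m, class = c("roi_mask", "matrix", "array"))
}

#' Read a PNG mask (nonzero = foreground)
#'
#' @param path path to a PNG file.
#' @inheritParams roi_mask
#' @return a `roi_mask`.
#' @export
read_mask <- function(path, check_connectivity = TRUE) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  roi_mask(raw > 0, check_connectivity = check_connectivity)
}

# Flood fill from one seed, expanding the frontier with vectorized
# shifts; foreground is 4-connected iff the fill reaches every pixel.
.single_component <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  visited <- matrix(FALSE, nrow(m), ncol(m))
  visited[idx[1L, 1L], idx[1L, 2L]] <- TRUE
  nr <- nrow(m)
  nc <- ncol(m)
  repeat {
    grown <- visited
    grown[-1L, ]  <- grown[-1L, ]  | visited[-nr, ]
    grown[-nr, ]  <- grown[-nr, ]  | visited[-1L, ]
    grown[, -1L]  <- grown[, -1L]  | visited[, -nc]
    grown[, -nc]  <- grown[, -nc]  | visited[, -1L]
    grown <- grown & m
    if (identical(grown, visited)) break
    visited <- grown
  }
  sum(visited) == sum(m)
}

# ---- ROI patches ------------------------------------------------------------

#' Extract the masked tumor patch from an image
#'
#' Crops image and mask to the tight bounding box of the mask. Pixels
#' outside the mask are retained in the array but are excluded from every
#' downstream statistic; after normalization they are set to zero so that
#' the wavelet channels cannot see them either.
#'
#' @param image a `gray_image` (or plain numeric matrix).
#' @param mask a `roi_mask` of the same shape.
#' @return a `roi_patch`: list with elements `pixels` (numeric matrix),
#'   `mask` (logical matrix), `normalized` and `degenerate` flags.
#' @export
extract_roi <- function(image, mask) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (!any(mask)) stop("mask is empty")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  new_roi_patch(
    pixels = unclass(image)[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE],
    mask   = unclass(mask)[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  )
}

new_roi_patch <- function(pixels, mask, normalized = FALSE, degenerate = FALSE) {
  structure(
    list(pixels = pixels, mask = mask,
         normalized = normalized, degenerate = degenerate),
    class = "roi_patch"
  )
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch %d x %d, %d masked pixels%s%s>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$mask),
              if (x$normalized) ", normalized" else "",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Masked pixel values of a patch
#' @param patch a `roi_patch`.
#' @return numeric vector of the masked-in intensities.
#' @export
masked_values <- function(patch) patch$pixels[patch$mask]

#' Z-normalize a patch over its masked pixels
#'
#' Masked intensities are centered and scaled to mean 0, SD 1 (population
#' SD). A constant patch (SD 0) maps to all zeros with the `degenerate`
#' flag raised. Pixels outside the mask are set to 0, the post-
#' normalization mean, so they carry no information into the wavelet
#' subbands.
#'
#' @param patch a `roi_patch`.
#' @return a normalized `roi_patch`; idempotent to 1e-9.
#' @export
normalize_patch <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  v <- masked_values(patch)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  px <- patch$pixels
  degenerate <- sigma == 0
  if (degenerate) {
    px[] <- 0
  } else {
    px <- (px - mu) / sigma
    px[!patch$mask] <- 0
  }
  new_roi_patch(px, patch$mask, normalized = TRUE, degenerate = degenerate)
}

# ---- gray-level quantization ------------------------------------------------

#' Quantize masked patch intensities into G equal-width gray levels
#'
#' Masked intensities are clipped to the given percentile range (computed
#' over masked pixels only) and binned into 1..G equal-width bins; the
#' clipped minimum maps to bin 1 and the maximum to bin G. Unmasked
#' pixels carry NA, a sentinel no texture-matrix builder counts.
#'
#' @param patch a normalized `roi_patch`.
#' @param levels number of gray levels G (default 32, must be >= 2).
#' @param clip length-2 percentile pair in \[0, 100\] (default c(1, 99));
#'   NULL disables clipping.
#' @return a `quantized_patch`: list with `pixels` (integer matrix with
#'   NA outside the mask), `mask`, and `levels`.
#' @export
quantize <- function(patch, levels = 32L, clip = c(1, 99)) {
  stopifnot(inherits(patch, "roi_patch"))
  if (levels < 2L) stop("levels must be >= 2")
  v <- masked_values(patch)
  if (is.null(clip)) {
    lo <- min(v); hi <- max(v)
  } else {
    q <- stats::quantile(v, clip / 100, names = FALSE)
    lo <- q[1L]; hi <- q[2L]
  }
  px <- patch$pixels
  px[px < lo] <- lo
  px[px > hi] <- hi
  if (hi > lo) {
    bins <- floor((px - lo) / (hi - lo) * levels) + 1L
    bins[bins > levels] <- levels
  } else {
    bins <- px
    bins[] <- 1L
  }
  bins[!patch$mask] <- NA_integer_
  storage.mode(bins) <- "integer"
  structure(list(pixels = bins, mask = patch$mask, levels = as.integer(levels)),
            class = "quantized_patch")
}

# ---- cohort manifests -------------------------------------------------------

#' Read a cohort manifest CSV
#'
#' The manifest maps patients to image/mask files, outcome labels, cohort
#' membership and clinical covariates. Required columns: `patient_id`,
#' `image`, `mask`, `label`, `cohort`; any further columns are carried
#' along as covariates. Paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param path manifest CSV path.
#' @return a data.frame with resolved file paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "image", "mask", "label", "cohort")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$patient_id)) stop("duplicate patient_id in manifest")
  if (!all(man$label %in% c(0L, 1L))) stop("labels must be 0/1")
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man$image <- rel(man$image)
  man$mask <- rel(man$mask)
  man
}
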