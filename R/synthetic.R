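# Synthetic two-class ultrasound-like cohorts. Speckle is modeled as
# smoothed unit-mean multiplicative Gamma noise on a smooth base
# intensity field; the class signal enters through the correlation
# length (Gaussian blur width) of the speckle, which co-occurrence and
# run-length features are sensitive to. Covariates emulate a thyroid
# carcinoma cohort but carry no image signal.

#' Configuration for a synthetic speckle cohort
#'
#' Defaults emulate a two-class lymph-node-metastasis cohort: class
#' prevalence 0.21 (training convention; use 0.27 for a validation-style
#' cohort), 128 x 128 8-bit images, elliptical tumor masks with
#' semi-axes of 8-20 px, speckle smoothness 1 px for the negative class
#' plus `delta` for positives, and Gamma shape 4 for the multiplicative
#' noise. `delta = 0` is the null configuration.
#'
#' @param n_patients cohort size.
#' @param prevalence P(label = 1), in (0, 1).
#' @param image_size image side length in pixels.
#' @param axes_range range of ellipse semi-axes in pixels (min >= 4).
#' @param smooth_neg Gaussian blur sigma (px) of the pre-speckle field
#'   for the negative class.
#' @param delta texture effect size: blur sigma added for positives.
#' @param gamma_shape shape k of the unit-mean multiplicative Gamma
#'   speckle.
#' @param couple_central_lnm give the central-LNM covariate the odds
#'   direction seen in real cohorts (default FALSE: covariates carry no
#'   signal).
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 400L, prevalence = 0.21,
                             image_size = 128L, axes_range = c(8, 20),
                             smooth_neg = 1, delta = 0, gamma_shape = 4,
                             couple_central_lnm = FALSE, seed = 0L) {
  stopifnot(prevalence > 0, prevalence < 1, axes_range[1L] >= 4,
            image_size >= 2 * (ceiling(axes_range[2L]) + 4))
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 image_size = as.integer(image_size), axes_range = axes_range,
                 smooth_neg = smooth_neg, delta = delta,
                 gamma_shape = gamma_shape,
                 couple_central_lnm = couple_central_lnm,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# separable Gaussian blur with edge replication; sigma = 0 is identity
.gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {
    padded <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_along(k))
      out <- out + k[t] * padded[(t - 1L) + seq_len(nrow(m)), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(x))))
}

#' Generate one synthetic patient (image, mask, covariates)
#'
#' image = clip_0_255(round(blur_s(U) * M)) with U i.i.d. unit-mean
#' Gamma(k) speckle, s = smooth_neg + delta * label, and M a smooth base
#' intensity field. The tumor mask is a uniform-random ellipse kept
#' strictly inside the image. Draws consume the current RNG state, so
#' results are reproducible from a seeded caller.
#'
#' @param config a `synthetic_config`.
#' @param label 0/1 class of this patient.
#' @param patient_id identifier string.
#' @return a `synthetic_patient`: list with `patient_id`, `image`
#'   (`gray_image`), `mask` (`roi_mask`), `label`, `covariates`.
#' @export
generate_image <- function(config, label, patient_id = "p1") {
  n <- config$image_size
  # smooth base field: mean brightness with a gentle random gradient
  gx <- matrix(rep(seq(-1, 1, length.out = n), each = n), n)
  gy <- t(gx)
  ang <- stats::runif(1, 0, 2 * pi)
  M <- 140 * (1 + 0.15 * (cos(ang) * gx + sin(ang) * gy))
  k <- config$gamma_shape
  U <- matrix(stats::rgamma(n * n, shape = k, rate = k), n)
  s <- config$smooth_neg + config$delta * label
  img <- .gaussian_blur(U, s) * M
  img <- round(pmin(pmax(img, 0), 255))

  # uniform-random ellipse strictly inside the frame
  ax <- stats::runif(2, config$axes_range[1L], config$axes_range[2L])
  margin <- ceiling(max(ax)) + 2
  if (2 * margin >= n) stop("ellipse cannot fit inside the image")
  ctr <- stats::runif(2, margin + 1, n - margin)
  th <- stats::runif(1, 0, pi)
  rr <- matrix(rep(seq_len(n), n), n) - ctr[1L]
  cc <- t(matrix(rep(seq_len(n), n), n)) - ctr[2L]
  u <- cos(th) * rr + sin(th) * cc
  v <- -sin(th) * rr + cos(th) * cc
  mask <- (u / ax[1L])^2 + (v / ax[2L])^2 <= 1

  age <- round(min(max(stats::rnorm(1, 45, 13), 17), 80))
  sex <- if (stats::runif(1) < 0.15) "M" else "F"
  size_mm <- round(exp(stats::rnorm(1, log(17), 0.42)), 1)
  p_central <- if (config$couple_central_lnm) {
    if (label == 1) 0.90 else 0.49
  } else 0.57
  central <- as.integer(stats::runif(1) < p_central)

  structure(list(
    patient_id = patient_id,
    image = gray_image(img),
    mask = roi_mask(mask, check_connectivity = FALSE),  # ellipses are convex
    label = as.integer(label),
    covariates = list(age = age, sex = sex, size_mm = size_mm,
                      central_lnm = central)
  ), class = "synthetic_patient")
}

#' Generate a full synthetic cohort
#'
#' Labels are Bernoulli(prevalence); every other draw flows from the
#' same seeded stream, so the cohort is reproducible from
#' (config, seed). Optionally writes PNG images/masks plus a manifest
#' CSV compatible with [read_manifest()].
#'
#' @param config a `synthetic_config`.
#' @param dir optional output directory; when given, images and masks
#'   are written as PNG and a `manifest.csv` and `config.json` are
#'   created there.
#' @param cohort_tag value for the manifest's cohort column (default
#'   "training").
#' @return a `synthetic_cohort`: list with `patients` (list of
#'   `synthetic_patient`), `table` (data.frame of patient_id, label,
#'   covariates), `config`, and `dir` (NULL if not written).
#' @export
generate_cohort <- function(config, dir = NULL, cohort_tag = "training") {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_patients < 20L) stop("cohort must have at least 20 patients")
  if (config$n_patients * config$prevalence < 2)
    stop("expected positives < 2; prevalence too low for this cohort size")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  labels <- stats::rbinom(n, 1L, config$prevalence)
  ids <- sprintf("%s_%04d", substr(cohort_tag, 1L, 1L), seq_len(n))
  patients <- vector("list", n)
  for (k in seq_len(n))
    patients[[k]] <- generate_image(config, labels[k], ids[k])

  tab <- data.frame(
    patient_id = ids,
    label = labels,
    cohort = cohort_tag,
    age = vapply(patients, function(p) p$covariates$age, 0),
    sex = vapply(patients, function(p) p$covariates$sex, ""),
    size_mm = vapply(patients, function(p) p$covariates$size_mm, 0),
    central_lnm = vapply(patients, function(p) p$covariates$central_lnm, 0L),
    stringsAsFactors = FALSE
  )

  out_dir <- NULL
  if (!is.null(dir)) {
    out_dir <- dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- tab
    man$image <- file.path(dir, paste0(ids, ".png"))
    man$mask <- file.path(dir, paste0(ids, "_mask.png"))
    for (k in seq_len(n)) {
      png::writePNG(unclass(patients[[k]]$image) / 255, man$image[k])
      png::writePNG(unclass(patients[[k]]$mask) * 1, man$mask[k])
    }
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE)
  }
  structure(list(patients = patients, table = tab, config = config,
                 dir = out_dir),
            class = "synthetic_cohort")
}
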