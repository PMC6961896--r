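# Statistic sets for each feature family. All definitions use population
# moments; entropies are in bits (log base 2). Degenerate statistics
# (zero-variance denominators) return 0 rather than NaN so that constant
# patches survive the pipeline; extract_all_features() records the
# replacement.

#' First-order (histogram) features of a patch
#'
#' Fourteen statistics over the masked pixels only: mean, variance
#' (population), standard deviation, skewness, kurtosis (Pearson, not
#' excess), energy (sum of squares), Shannon entropy over a fixed-bin
#' histogram, minimum, maximum, median, range, root-mean-square, mean
#' absolute deviation (about the mean), and uniformity (sum of squared
#' histogram probabilities).
#'
#' @param patch a `roi_patch` with at least 2 masked pixels.
#' @param hist_bins number of histogram bins for entropy/uniformity
#'   (default 32).
#' @return named numeric vector of length 14.
#' @export
first_order_features <- function(patch, hist_bins = 32L) {
  v <- if (inherits(patch, "roi_patch")) masked_values(patch) else as.numeric(patch)
  if (length(v) < 2L) stop("need at least 2 masked pixels")
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  sdv <- sqrt(m2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  rng <- range(v)
  # fixed equal-width histogram over the observed range
  if (rng[2L] > rng[1L]) {
    b <- floor((v - rng[1L]) / (rng[2L] - rng[1L]) * hist_bins) + 1L
    b[b > hist_bins] <- hist_bins
    p <- tabulate(b, hist_bins) / n
  } else {
    p <- 1
  }
  p <- p[p > 0]
  c(mean = mu,
    variance = m2,
    sd = sdv,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    min = rng[1L],
    max = rng[2L],
    median = stats::median(v),
    range = rng[2L] - rng[1L],
    rms = sqrt(mean(v^2)),
    mad = mean(abs(v - mu)),
    uniformity = sum(p^2))
}

#' GLCM texture statistics
#'
#' The 22-statistic second-order set computed from a normalized symmetric
#' co-occurrence matrix: autocorrelation, contrast, correlation, cluster
#' prominence, cluster shade, dissimilarity, energy (angular second
#' moment), entropy, homogeneity (inverse difference), inverse difference
#' moment, maximum probability, sum of squares (variance), sum average,
#' sum variance, sum entropy, difference variance, difference entropy,
#' the two information measures of correlation, inverse difference
#' normalized, inverse difference moment normalized, and the marginal
#' mean gray level.
#'
#' @param g a `glcm` from [compute_glcm()].
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm"))
  G <- g$levels
  P <- as.vector(g$matrix)
  zero <- g$degenerate
  if (!zero && abs(sum(P) - 1) > 1e-8) stop("GLCM is not normalized")
  gm <- .glcm_geometry(G)
  px <- rowSums(g$matrix)                # = colSums by symmetry
  lev <- seq_len(G)
  mu <- sum(lev * px)
  sig2 <- sum((lev - mu)^2 * px)
  ent2 <- function(p) { p <- p[p > 0]; if (length(p)) -sum(p * log2(p)) else 0 }

  # sum and difference distributions p_{x+y}, p_{x-y}
  psum <- as.vector(rowsum(P, gm$sum_grp))          # k = 2..2G
  pdiff <- as.vector(rowsum(P, gm$absdiff))         # k = 0..G-1
  ks <- 2:(2 * G)
  kd <- 0:(G - 1)

  sa <- sum(ks * psum)
  dmu <- sum(kd * pdiff)

  hxy <- ent2(P)
  hx <- ent2(px)
  pp <- as.vector(outer(px, px))
  hxy1 <- { ok <- P > 0 & pp > 0; -sum(P[ok] * log2(pp[ok])) }
  hxy2 <- ent2(pp)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- { e <- 1 - exp(-2 * (hxy2 - hxy)); if (e > 0) sqrt(e) else 0 }

  out <- c(
    autocorrelation = sum(gm$ij * P),
    contrast = sum(gm$d2 * P),
    correlation = if (sig2 > 0) (sum(gm$ij * P) - mu^2) / sig2 else 0,
    cluster_prominence = sum((gm$sum_grp - 2 * mu)^4 * P),
    cluster_shade = sum((gm$sum_grp - 2 * mu)^3 * P),
    dissimilarity = sum(gm$absdiff * P),
    energy = sum(P^2),
    entropy = hxy,
    homogeneity = sum(P * gm$inv_d),
    idm = sum(P * gm$inv_d2),
    max_probability = max(P),
    sum_of_squares = sum((gm$i - mu)^2 * P),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psum),
    sum_entropy = ent2(psum),
    difference_variance = sum((kd - dmu)^2 * pdiff),
    difference_entropy = ent2(pdiff),
    imc1 = imc1,
    imc2 = imc2,
    idn = sum(P * gm$inv_dn),
    idmn = sum(P * gm$inv_d2n),
    marginal_mean = mu
  )
  if (zero) out[] <- 0
  out
}

# cached per-G geometry vectors for the GLCM statistic set
.glcm_geom_cache <- new.env(parent = emptyenv())
.glcm_geometry <- function(G) {
  key <- as.character(G)
  hit <- .glcm_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep.int(seq_len(G), G)
  j <- rep(seq_len(G), each = G)
  ad <- abs(i - j)
  gm <- list(i = i, j = j, ij = i * j, d2 = (i - j)^2, absdiff = ad,
             sum_grp = i + j,
             inv_d = 1 / (1 + ad), inv_d2 = 1 / (1 + (i - j)^2),
             inv_dn = 1 / (1 + ad / G), inv_d2n = 1 / (1 + (i - j)^2 / G^2))
  .glcm_geom_cache[[key]] <- gm
  gm
}

#' GLRLM run-length statistics
#'
#' The 11-statistic run-emphasis set: short/long run emphasis (SRE, LRE),
#' gray-level and run-length non-uniformity (GLN, RLN), run percentage
#' (RP), low/high gray-level run emphasis (LGRE, HGRE), and the four
#' joint emphases (SRLGE, SRHGE, LRLGE, LRHGE). All but RP are
#' normalized by the number of runs; RP = runs / masked pixels.
#'
#' @param g a `glrlm` from [compute_glrlm()].
#' @return named numeric vector of length 11.
#' @export
glrlm_features <- function(g) {
  stopifnot(inherits(g, "glrlm"))
  if (g$n_runs < 1L) stop("run-length matrix has no runs")
  R <- g$matrix
  nr <- g$n_runs
  i2 <- matrix(rep((seq_len(nrow(R)))^2, ncol(R)), nrow(R))
  j2 <- matrix(rep((seq_len(ncol(R)))^2, each = nrow(R)), nrow(R))
  c(sre = sum(R / j2) / nr,
    lre = sum(R * j2) / nr,
    gln = sum(rowSums(R)^2) / nr,
    rln = sum(colSums(R)^2) / nr,
    rp = nr / g$n_pixels,
    lgre = sum(R / i2) / nr,
    hgre = sum(R * i2) / nr,
    srlge = sum(R / (i2 * j2)) / nr,
    srhge = sum(R * i2 / j2) / nr,
    lrlge = sum(R * j2 / i2) / nr,
    lrhge = sum(R * i2 * j2) / nr)
}
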