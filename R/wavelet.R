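# Single-level 2-D Haar discrete wavelet transform. With the orthonormal
# Haar pair and even-length input the analysis reduces to a 2x2 block
# transform, which gives exact perfect reconstruction; odd dimensions
# are extended by edge replication (symmetric half-point padding) first.

#' Single-level 2-D Haar wavelet decomposition of a patch
#'
#' Decomposes the (normalized) patch into approximation (LL) and
#' horizontal/vertical/diagonal detail (LH, HL, HH) subbands at half
#' resolution. The ROI mask is downsampled with a 2x2 block-any rule so
#' a subband coefficient is masked-in when any of its four source pixels
#' was.
#'
#' @param patch a `roi_patch`, at least 2 x 2.
#' @return a `wavelet_subbands` object: list with `LL`, `LH`, `HL`, `HH`
#'   numeric matrices, `mask` (downsampled logical matrix), and `padded`
#'   dimensions of the edge-extended input.
#' @export
wavelet_decompose <- function(patch) {
  stopifnot(inherits(patch, "roi_patch"))
  x <- patch$pixels
  m <- patch$mask
  if (nrow(x) < 2L || ncol(x) < 2L) stop("patch smaller than filter support")
  if (nrow(x) %% 2L) { x <- rbind(x, x[nrow(x), ]); m <- rbind(m, m[nrow(m), ]) }
  if (ncol(x) %% 2L) { x <- cbind(x, x[, ncol(x)]); m <- cbind(m, m[, ncol(m)]) }
  ri <- seq(1L, nrow(x), by = 2L)
  ci <- seq(1L, ncol(x), by = 2L)
  a <- x[ri, ci, drop = FALSE]        # top-left of each 2x2 block
  b <- x[ri, ci + 1L, drop = FALSE]   # top-right
  d <- x[ri + 1L, ci, drop = FALSE]   # bottom-left
  e <- x[ri + 1L, ci + 1L, drop = FALSE]
  structure(list(
    LL = (a + b + d + e) / 2,
    LH = (a - b + d - e) / 2,   # horizontal detail (column differences)
    HL = (a + b - d - e) / 2,   # vertical detail (row differences)
    HH = (a - b - d + e) / 2,
    mask = m[ri, ci, drop = FALSE] | m[ri, ci + 1L, drop = FALSE] |
           m[ri + 1L, ci, drop = FALSE] | m[ri + 1L, ci + 1L, drop = FALSE],
    padded = dim(x)
  ), class = "wavelet_subbands")
}

#' Inverse of [wavelet_decompose()]
#'
#' Reconstructs the edge-extended patch from its four Haar subbands.
#'
#' @param w a `wavelet_subbands` object.
#' @return numeric matrix with the padded dimensions recorded in `w`.
#' @export
wavelet_reconstruct <- function(w) {
  stopifnot(inherits(w, "wavelet_subbands"))
  a <- (w$LL + w$LH + w$HL + w$HH) / 2
  b <- (w$LL - w$LH + w$HL - w$HH) / 2
  d <- (w$LL + w$LH - w$HL - w$HH) / 2
  e <- (w$LL - w$LH - w$HL + w$HH) / 2
  out <- matrix(0, w$padded[1L], w$padded[2L])
  ri <- seq(1L, w$padded[1L], by = 2L)
  ci <- seq(1L, w$padded[2L], by = 2L)
  out[ri, ci] <- a; out[ri, ci + 1L] <- b
  out[ri + 1L, ci] <- d; out[ri + 1L, ci + 1L] <- e
  out
}

# A subband viewed as an unnormalized roi_patch, ready for quantization
# and texture-matrix extraction.
.subband_patch <- function(w, band) {
  new_roi_patch(w[[band]], w$mask, normalized = TRUE, degenerate = FALSE)
}
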