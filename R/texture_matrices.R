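# Texture matrices on quantized patches. Angle convention (image rows
# grow downward): 0 deg = horizontal, 45 deg = up-right, 90 deg =
# vertical, 135 deg = up-left. GLCM accumulates each offset and its
# negation, so the matrix is symmetric by construction.

.angle_offset <- function(angle, distance = 1L) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("angle must be one of 0, 45, 90, 135")
  )
}

#' Gray-level co-occurrence matrix of a quantized patch
#'
#' Counts pairs of gray levels at the given offset where both endpoints
#' are masked-in, symmetrizes (the offset and its negation), and
#' normalizes to sum 1.
#'
#' @param q a `quantized_patch`.
#' @param distance pixel offset distance (default 1).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return a `glcm`: list with `matrix` (G x G, sums to 1 unless
#'   degenerate), `levels`, `distance`, `angle`, `n_pairs`, and a
#'   `degenerate` flag set when the offset admits no valid pixel pair.
#' @export
compute_glcm <- function(q, distance = 1L, angle = 0) {
  stopifnot(inherits(q, "quantized_patch"))
  if (distance < 1L) stop("distance must be >= 1")
  off <- .angle_offset(angle, as.integer(distance))
  G <- q$levels
  px <- q$pixels
  nr <- nrow(px); nc <- ncol(px)
  dr <- off[1L]; dc <- off[2L]
  rng <- function(lo, hi) if (lo <= hi) lo:hi else integer(0)
  r1 <- rng(max(1L, 1L - dr), min(nr, nr - dr))
  c1 <- rng(max(1L, 1L - dc), min(nc, nc - dc))
  counts <- matrix(0, G, G)
  n_pairs <- 0L
  if (length(r1) > 0L && length(c1) > 0L) {
    a <- px[r1, c1, drop = FALSE]
    b <- px[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      ai <- a[ok]; bi <- b[ok]
      n_pairs <- length(ai)
      # symmetric accumulation: count (a,b) and (b,a)
      tab <- tabulate(ai + G * (bi - 1L), nbins = G * G) +
             tabulate(bi + G * (ai - 1L), nbins = G * G)
      counts <- matrix(tab, G, G)
    }
  }
  degenerate <- n_pairs == 0L
  if (!degenerate) counts <- counts / sum(counts)
  structure(list(matrix = counts, levels = G, distance = as.integer(distance),
                 angle = angle, n_pairs = n_pairs, degenerate = degenerate),
            class = "glcm")
}

# Cached linearization of a matrix into scan lines for one direction:
# element order `ord`, and positions `pos` inside a buffer of length
# `len` where consecutive lines are separated by an NA sentinel, so a
# single rle() call yields all runs with breaks at line ends.
.lin_cache <- new.env(parent = emptyenv())

.get_linearization <- function(nr, nc, angle) {
  key <- paste(nr, nc, angle, sep = "x")
  hit <- .lin_cache[[key]]
  if (!is.null(hit)) return(hit)
  ri <- rep.int(seq_len(nr), nc)
  ci <- rep(seq_len(nc), each = nr)
  grp <- switch(as.character(angle),
    "0"   = ri,            # scan along rows
    "90"  = ci,            # scan along columns
    "45"  = ri + ci,       # anti-diagonals (up-right)
    "135" = ci - ri,       # main diagonals (down-right)
    stop("angle must be one of 0, 45, 90, 135"))
  ord <- order(grp, ci)
  g <- grp[ord]
  pos <- seq_along(ord) + cumsum(c(0L, as.integer(diff(g) != 0)))
  lin <- list(ord = ord, pos = pos, len = length(ord) + sum(diff(g) != 0))
  .lin_cache[[key]] <- lin
  lin
}

#' Gray-level run-length matrix of a quantized patch
#'
#' r(i, j) counts maximal runs of gray level i and length j along the
#' given direction; runs break at masked-out pixels and patch edges.
#'
#' @param q a `quantized_patch`.
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return a `glrlm`: list with `matrix` (G x R run counts), `levels`,
#'   `angle`, `n_runs`, `n_pixels` (masked pixels traversed).
#' @export
compute_glrlm <- function(q, angle = 0) {
  stopifnot(inherits(q, "quantized_patch"))
  px <- q$pixels
  G <- q$levels
  lin <- .get_linearization(nrow(px), ncol(px), angle)
  buf <- rep(NA_integer_, lin$len)
  buf[lin$pos] <- px[lin$ord]
  r <- rle(buf)
  keep <- !is.na(r$values)
  lv <- r$values[keep]
  ln <- r$lengths[keep]
  n_runs <- length(lv)
  R <- if (n_runs) max(ln) else 1L
  mat <- matrix(0L, G, R)
  if (n_runs) {
    tab <- tabulate(lv + G * (ln - 1L), nbins = G * R)
    mat <- matrix(tab, G, R)
  }
  structure(list(matrix = mat, levels = G, angle = angle,
                 n_runs = n_runs, n_pixels = sum(ln)),
            class = "glrlm")
}
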