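# Shared fixtures: tiny hand-built patches and quantized patches.

# roi_patch straight from a matrix (full mask unless given)
make_patch <- function(m, mask = NULL, normalized = FALSE) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  usradiomics:::new_roi_patch(m, mask, normalized = normalized)
}

# quantized_patch straight from an integer matrix of bin indices
make_qpatch <- function(m, levels, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
  px <- m
  px[!mask] <- NA_integer_
  storage.mode(px) <- "integer"
  structure(list(pixels = px, mask = mask, levels = as.integer(levels)),
            class = "quantized_patch")
}

# independent loop-based GLCM oracle: enumerate every pixel pair at the
# offset (and its negation), both endpoints masked-in
oracle_glcm <- function(px, mask, G, dr, dc) {
  counts <- matrix(0, G, G)
  nr <- nrow(px); nc <- ncol(px)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        mask[r, c] && mask[r2, c2]) {
      a <- px[r, c]; b <- px[r2, c2]
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# independent loop-based GLRLM oracle: walk each scan line pixel by
# pixel, breaking runs at mask-outs and line ends
oracle_glrlm <- function(px, mask, G, angle) {
  nr <- nrow(px); nc <- ncol(px)
  step <- switch(as.character(angle),
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  # starting cells: those with no masked predecessor on the same line
  runs_lv <- integer(0); runs_ln <- integer(0)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    pr <- r0 - step[1]; pc <- c0 - step[2]
    if (inside(pr, pc)) next  # not a line start
    r <- r0; c <- c0
    cur <- NA_integer_; len <- 0L
    while (inside(r, c)) {
      v <- if (mask[r, c]) px[r, c] else NA_integer_
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) { runs_lv <- c(runs_lv, cur); runs_ln <- c(runs_ln, len) }
        cur <- v; len <- 1L
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur)) { runs_lv <- c(runs_lv, cur); runs_ln <- c(runs_ln, len) }
  }
  R <- max(c(runs_ln, 1L))
  m <- matrix(0L, G, R)
  for (k in seq_along(runs_lv))
    m[runs_lv[k], runs_ln[k]] <- m[runs_lv[k], runs_ln[k]] + 1L
  list(matrix = m, n_runs = length(runs_lv), n_pixels = sum(runs_ln))
}

# small deterministic random patch
random_patch <- function(nr, nc, seed = 1) {
  set.seed(seed)
  make_patch(matrix(runif(nr * nc, 0, 255), nr, nc))
}
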