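# Drivers comparing the texture-matrix builders with the loop-based
# enumeration oracles, shared by the unit and acceptance suites.

all_patches <- function(nr, nc) {
  n <- nr * nc
  lapply(0:(2^n - 1), function(code) {
    matrix(as.integer(bitwAnd(code %/% 2^(0:(n - 1)), 1L)) + 1L, nr, nc)
  })
}

glcm_offsets <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                     "135" = c(-1, -1))

# number of angle-matrices where builder and oracle disagree
count_glcm_mismatch <- function(px, mask) {
  q <- make_qpatch(px, 2, mask = mask)
  bad <- 0L
  for (a in names(glcm_offsets)) {
    g <- compute_glcm(q, angle = as.numeric(a))
    o <- oracle_glcm(px, mask, 2, glcm_offsets[[a]][1], glcm_offsets[[a]][2])
    if (max(abs(g$matrix - o)) > 1e-12) bad <- bad + 1L
  }
  bad
}

count_glrlm_mismatch <- function(px, mask) {
  q <- make_qpatch(px, 2, mask = mask)
  bad <- 0L
  for (a in c(0, 45, 90, 135)) {
    g <- compute_glrlm(q, angle = a)
    o <- oracle_glrlm(px, mask, 2, a)
    R <- max(ncol(g$matrix), ncol(o$matrix))
    pad <- function(m) cbind(m, matrix(0L, nrow(m), R - ncol(m)))
    if (g$n_runs != o$n_runs || g$n_pixels != o$n_pixels ||
        any(pad(g$matrix) != pad(o$matrix))) bad <- bad + 1L
  }
  bad
}
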