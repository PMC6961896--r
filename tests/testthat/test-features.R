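test_that("first-order statistics match hand arithmetic", {
  p <- make_patch(matrix(c(1, 2, 3, 4), 2))
  f <- first_order_features(p)
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)        # population variance
  expect_equal(f[["energy"]], 30)            # 1 + 4 + 9 + 16
  expect_equal(f[["range"]], 3)
  expect_equal(f[["rms"]], sqrt(30 / 4))
  expect_equal(f[["mad"]], 1)
  expect_equal(f[["median"]], 2.5)

  # constant patch: degenerate distribution
  fc <- first_order_features(make_patch(matrix(5, 3, 3)))
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["uniformity"]], 1)
  expect_equal(fc[["range"]], 0)

  # two equal-mass histogram bins give exactly 1 bit of entropy
  f2 <- first_order_features(make_patch(matrix(rep(c(0, 1), 8), 4)), hist_bins = 2)
  expect_equal(f2[["entropy"]], 1)
  expect_equal(f2[["uniformity"]], 0.5)

  expect_error(first_order_features(make_patch(matrix(1, 1, 1))), "2 masked")
})

test_that("GLCM construction matches the enumerated examples", {
  # [[1,2],[1,2]]: two horizontal pairs, symmetrized
  q <- make_qpatch(matrix(c(1, 1, 2, 2), 2), levels = 2)
  g <- compute_glcm(q, distance = 1, angle = 0)
  expect_equal(g$matrix, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(sum(g$matrix), 1)
  expect_equal(g$matrix, t(g$matrix))

  # constant patch: single nonzero entry on the diagonal
  qc <- make_qpatch(matrix(2L, 3, 3), levels = 3)
  gc <- compute_glcm(qc, angle = 90)
  expect_equal(gc$matrix[2, 2], 1)
  expect_equal(sum(gc$matrix), 1)

  # no valid pair: degenerate flag
  q1 <- make_qpatch(matrix(1L, 1, 5), levels = 2)
  expect_true(compute_glcm(q1, angle = 90)$degenerate)

  # symmetry and unit mass on random masked patches
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(runif(48) > 0.3, 6, 8)
    qp <- make_qpatch(matrix(sample(1:4, 48, TRUE), 6, 8), levels = 4, mask = m)
    for (a in c(0, 45, 90, 135)) {
      gg <- compute_glcm(qp, angle = a)
      if (!gg$degenerate) {
        expect_equal(sum(gg$matrix), 1, tolerance = 1e-9)
        expect_equal(gg$matrix, t(gg$matrix))
      }
    }
  }
})

test_that("GLCM statistics match closed-form cases", {
  q <- make_qpatch(matrix(c(1, 1, 2, 2), 2), levels = 2)
  f <- glcm_features(compute_glcm(q, angle = 0))
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["energy"]], 0.5)
  expect_equal(f[["dissimilarity"]], 1)
  expect_equal(f[["entropy"]], 1)  # two cells of 1/2
  expect_equal(f[["marginal_mean"]], 1.5)

  # checkerboard of two levels: every horizontal pair is discordant by 1
  ch <- matrix(rep(c(1L, 2L), 8), 4)
  ch[, c(2, 4)] <- 3L - ch[, c(2, 4)]
  fch <- glcm_features(compute_glcm(make_qpatch(ch, 2), angle = 0))
  expect_equal(fch[["contrast"]], 1)

  # constant patch: point mass
  fc <- glcm_features(compute_glcm(make_qpatch(matrix(1L, 4, 4), 2), angle = 0))
  expect_equal(fc[["energy"]], 1)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["contrast"]], 0)
  expect_equal(fc[["max_probability"]], 1)
  expect_equal(fc[["correlation"]], 0)  # degenerate marginal variance -> 0
  expect_equal(length(fc), 22L)
})

test_that("GLRLM construction matches run-length encoding by hand", {
  # 4x4 constant: one run of length 4 per row
  g <- compute_glrlm(make_qpatch(matrix(2L, 4, 4), 2), angle = 0)
  expect_equal(g$n_runs, 4L)
  expect_equal(g$matrix[2, 4], 4L)
  expect_equal(sum(g$matrix), 4L)

  # 1-D sequence 1,1,2,2,2,1
  g1 <- compute_glrlm(make_qpatch(matrix(c(1L, 1L, 2L, 2L, 2L, 1L), 1), 2),
                      angle = 0)
  expect_equal(g1$matrix[1, 2], 1L)
  expect_equal(g1$matrix[2, 3], 1L)
  expect_equal(g1$matrix[1, 1], 1L)
  expect_equal(g1$n_runs, 3L)

  # pixel-count conservation on random masked patches, all angles
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(35) > 0.25, 5, 7)
    qp <- make_qpatch(matrix(sample(1:3, 35, TRUE), 5, 7), 3, mask = m)
    for (a in c(0, 45, 90, 135)) {
      gg <- compute_glrlm(qp, angle = a)
      expect_equal(gg$n_pixels, sum(m))
      j <- matrix(rep(seq_len(ncol(gg$matrix)), each = nrow(gg$matrix)),
                  nrow(gg$matrix))
      expect_equal(sum(j * gg$matrix), sum(m))
    }
  }

  # runs never cross masked-out pixels
  m <- matrix(TRUE, 1, 5); m[1, 3] <- FALSE
  gm <- compute_glrlm(make_qpatch(matrix(1L, 1, 5), 2, mask = m), angle = 0)
  expect_equal(gm$matrix[1, 2], 2L)  # two runs of length 2
  expect_equal(gm$n_runs, 2L)
})

test_that("GLRLM statistics match the plug-in examples", {
  f <- glrlm_features(compute_glrlm(make_qpatch(matrix(2L, 4, 4), 4), angle = 0))
  expect_equal(f[["rp"]], 0.25)
  expect_equal(f[["sre"]], 1 / 16)
  expect_equal(f[["rln"]], 4)
  expect_equal(f[["lre"]], 16)
  expect_equal(f[["gln"]], 4)  # = n_runs when one gray level

  # alternating pixels: all runs have length 1
  alt <- matrix(rep(c(1L, 2L), 8), 4)
  alt[, c(2, 4)] <- 3L - alt[, c(2, 4)]
  fa <- glrlm_features(compute_glrlm(make_qpatch(alt, 2), angle = 0))
  expect_equal(fa[["sre"]], 1)
  expect_equal(fa[["lre"]], 1)
  expect_equal(fa[["rp"]], 1)
})

test_that("Haar decomposition reconstructs and localizes detail energy", {
  # constant patch: all detail subbands vanish
  w <- wavelet_decompose(make_patch(matrix(3, 6, 6), normalized = TRUE))
  expect_true(all(w$LH == 0) && all(w$HL == 0) && all(w$HH == 0))
  expect_true(all(w$LL == 6))  # 2 * constant for orthonormal Haar

  # perfect reconstruction, even and odd sizes
  for (dims in list(c(8, 8), c(7, 9), c(5, 4))) {
    p <- random_patch(dims[1], dims[2], seed = dims[1] * 10 + dims[2])
    w <- wavelet_decompose(p)
    rec <- wavelet_reconstruct(w)
    padded <- p$pixels
    if (nrow(padded) %% 2) padded <- rbind(padded, padded[nrow(padded), ])
    if (ncol(padded) %% 2) padded <- cbind(padded, padded[, ncol(padded)])
    expect_equal(rec, padded, tolerance = 1e-6)
  }

  # horizontal step edge crossing a block interior: energy in the
  # row-difference (vertical-detail) subband dominates the other details
  step <- matrix(0, 8, 8); step[4:8, ] <- 1
  ws <- wavelet_decompose(make_patch(step, normalized = TRUE))
  expect_gt(sum(ws$HL^2), sum(ws$LH^2))
  expect_gt(sum(ws$HL^2), sum(ws$HH^2))

  # mask downsampling: block-any rule
  m <- matrix(FALSE, 4, 4); m[1, 2] <- TRUE; m[3:4, 3:4] <- TRUE
  wm <- wavelet_decompose(make_patch(matrix(1, 4, 4), mask = m, normalized = TRUE))
  expect_equal(wm$mask, matrix(c(TRUE, FALSE, FALSE, TRUE), 2))

  expect_error(wavelet_decompose(make_patch(matrix(1, 1, 3))), "filter support")
})

test_that("the registry defines exactly 730 unique ordered names", {
  reg <- feature_registry()
  expect_length(reg, 730L)
  expect_false(anyDuplicated(reg) > 0)
  expect_length(feature_registry("orig"), 146L)
  expect_equal(sum(grepl("^orig_fo_", reg)), 14L)
  expect_equal(sum(grepl("^LL_glcm_", reg)), 88L)
  expect_equal(sum(grepl("^HH_glrlm_", reg)), 44L)
})

test_that("extract_all_features returns 730 finite values deterministically", {
  p <- normalize_patch(random_patch(20, 24, seed = 5))
  f <- extract_all_features(p)
  expect_length(f, 730L)
  expect_identical(names(f), feature_registry())
  expect_true(all(is.finite(f)))

  # determinism: identical vectors on repeated runs
  expect_identical(f, extract_all_features(p))

  # constant patch survives with flagged degenerate statistics
  pc <- normalize_patch(make_patch(matrix(9, 8, 8)))
  fc <- extract_all_features(pc)
  expect_length(fc, 730L)
  expect_true(all(is.finite(fc)))
  expect_equal(fc[["orig_fo_variance"]], 0)
  expect_equal(fc[["orig_glcm_energy_0"]], 1)
})

test_that("features are invariant to affine intensity rescaling", {
  p <- random_patch(16, 16, seed = 9)
  f1 <- extract_all_features(normalize_patch(p))
  p2 <- make_patch(0.4 * p$pixels + 80)
  f2 <- extract_all_features(normalize_patch(p2))
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("rotating a patch by 90 degrees permutes the angle blocks", {
  p <- normalize_patch(random_patch(14, 14, seed = 13))
  pr <- usradiomics:::new_roi_patch(
    t(p$pixels)[ncol(p$pixels):1, ], t(p$mask)[ncol(p$mask):1, ],
    normalized = TRUE)
  f <- extract_all_features(p)
  fr <- extract_all_features(pr)

  # first-order features of the original channel unchanged (the LH/HL
  # subbands themselves swap under rotation)
  fo <- grepl("^orig_fo_", names(f))
  expect_equal(f[fo], fr[fo], tolerance = 1e-9)

  # 0 <-> 90 and 45 <-> 135 swap for the original channel's texture stats
  swap <- function(nms) {
    out <- sub("_0$", "_XX", nms)
    out <- sub("_90$", "_0", out)
    out <- sub("_XX$", "_90", out)
    out2 <- sub("_45$", "_YY", out)
    out2 <- sub("_135$", "_45", out2)
    sub("_YY$", "_135", out2)
  }
  tex <- which(grepl("^orig_(glcm|glrlm)_", names(f)))
  expect_equal(unname(f[tex]), unname(fr[swap(names(f)[tex])]),
               tolerance = 1e-9)
})
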