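brute_force_recall <- function(A, B, d_max) {
  hits <- 0
  for (i in seq_len(nrow(A))) {
    dmin <- Inf
    for (j in seq_len(nrow(B))) {
      dmin <- min(dmin, mean(abs(A[i, ] - B[j, ])))
    }
    hits <- hits + (dmin < d_max)
  }
  hits / nrow(A)
}

test_that("spectral MAE distance has its exact closed-form values", {
  expect_equal(spectral_mae(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)), 0)
  expect_equal(spectral_mae(rep(0.4, 5), rep(0.45, 5)), 0.05)
  expect_equal(spectral_mae(c(0, 1), c(1, 0)), 1)
  expect_equal(spectral_mae(c(0.2, 0.8), c(0.5, 0.6)), 0.25)
  expect_error(spectral_mae(1:3 / 10, 1:4 / 10), "grids")
})

test_that("spectral recall equals the brute-force double loop exactly", {
  set.seed(21)
  A <- matrix(runif(50 * 8), 50, 8)
  B <- matrix(runif(70 * 8), 70, 8)
  for (d_max in c(0.05, 0.1, 0.2)) {
    expect_identical(spectral_recall(A, B, d_max),
                     brute_force_recall(A, B, d_max))
  }
  # larger random sets, still bit-equivalent
  A2 <- matrix(runif(300 * 10), 300, 10)
  B2 <- matrix(runif(400 * 10), 400, 10)
  expect_identical(spectral_recall(A2, B2, 0.12),
                   brute_force_recall(A2, B2, 0.12))
})

test_that("recall limits, monotonicity, and strict-threshold semantics hold", {
  set.seed(22)
  A <- matrix(runif(40 * 6), 40, 6)
  expect_equal(spectral_recall(A, A, 1e-9), 1)
  # B containing A gives recall 1
  B <- rbind(matrix(runif(10 * 6), 10, 6), A)
  expect_equal(spectral_recall(A, B, 0.001), 1)
  # all distances above the threshold gives 0
  far <- A + 0.5
  expect_equal(spectral_recall(A, far, 0.1), 0)
  # monotone nondecreasing in d_max and under candidate-set extension
  Bsub <- B[1:15, ]
  grid <- c(0.01, 0.05, 0.1, 0.3)
  r_sub <- sapply(grid, function(t) spectral_recall(A, Bsub, t))
  expect_true(all(diff(r_sub) >= 0))
  expect_gte(spectral_recall(A, B, 0.05), spectral_recall(A, Bsub, 0.05))
  # ties at exactly d_max are misses (strict inequality)
  a <- matrix(0.5, 1, 4)
  b <- matrix(0.5 + 0.02, 1, 4)   # distance exactly 0.02
  expect_equal(spectral_recall(a, b, 0.02), 0)
  expect_equal(spectral_recall(a, b, 0.02 + 1e-9), 1)
})

test_that("hierarchical recall aggregates subject-then-class correctly", {
  # hand-built example: 2 subjects x 2 classes with known per-pixel hits
  bands <- 4
  mk <- function(v) matrix(v, ncol = bands, nrow = length(v))
  # library contains only the value 0.5; spectra at 0.5 hit, at 0.9 miss
  B <- matrix(0.5, 1, bands)
  A <- spectra_set(
    rbind(mk(c(0.5, 0.5)),        # s1 c1: hits 2/2 -> 1.0
          mk(c(0.5, 0.9, 0.9)),   # s1 c2: hits 1/3 -> 1/3
          mk(c(0.9, 0.9)),        # s2 c1: 0/2 -> 0
          mk(c(0.5))),            # s2 c2: 1/1 -> 1
    wavelengths = 1:bands,
    subject_id = c("s1", "s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    class_label = c("c1", "c1", "c2", "c2", "c2", "c1", "c1", "c2"))
  res <- hierarchical_recall(A, B, d_max = 0.05)
  res <- res[order(res$class), ]
  expect_equal(res$recall[res$class == "c1"], mean(c(1, 0)))
  expect_equal(res$recall[res$class == "c2"], mean(c(1 / 3, 1)))
  expect_equal(res$n_subjects, c(2, 2))
  # unweighted subject mean: subject sizes do not matter
  A2 <- spectra_set(rbind(mk(rep(0.5, 9)), mk(0.9)), 1:bands,
                    subject_id = c(rep("s1", 9), "s2"),
                    class_label = rep("c1", 10))
  expect_equal(hierarchical_recall(A2, B, 0.05)$recall, 0.5)
  # degenerate hierarchy reduces to plain recall
  A3 <- spectra_set(mk(c(0.5, 0.9, 0.5)), 1:bands,
                    subject_id = rep("s", 3), class_label = rep("c", 3))
  expect_equal(hierarchical_recall(A3, B, 0.05)$recall,
               spectral_recall(A3, B, 0.05))
  expect_error(hierarchical_recall(
    spectra_set(mk(0.5), 1:bands), B, 0.05), "annotations")
})

test_that("threshold selection finds the steepest recall increase", {
  set.seed(23)
  grid <- 10^seq(-3, -1, length.out = 50)
  A <- matrix(runif(30 * 5, 0.3, 0.7), 30, 5)
  # candidate 1: noisy copies at a known perturbation scale
  B1 <- A + matrix(rnorm(length(A), 0, 0.012), nrow(A))
  # expected min distance ~ E|N(0, 0.012)| = 0.012 * sqrt(2/pi) ~ 0.0096
  t1 <- select_threshold(A, list(B1), grid)
  expect_gt(t1, 0.004)
  expect_lt(t1, 0.03)
  # two models: returns the lowest of the per-model steepest points
  B2 <- A + matrix(rnorm(length(A), 0, 0.05), nrow(A))
  t12 <- select_threshold(A, list(B1, B2), grid)
  per <- attr(t12, "per_model")
  expect_equal(as.numeric(t12), min(per))
  expect_lt(per[1], per[2])
  # flat curve warns and contributes the smallest grid point
  Bfar <- A + 10
  expect_warning(tf <- select_threshold(A, list(Bfar), grid), "flat")
  expect_equal(as.numeric(tf), grid[1])
})

test_that("PCA realism freezes loadings on image/class-averaged reference", {
  set.seed(24)
  # rank-2 reference: two components must explain ~everything
  base1 <- sin(seq(0, pi, length.out = 12))
  base2 <- seq(0, 1, length.out = 12)
  coef1 <- runif(60); coef2 <- runif(60)
  spectra <- 0.3 + 0.2 * outer(coef1, base1) + 0.1 * outer(coef2, base2)
  ref <- spectra_set(spectra, 1:12,
                     subject_id = rep(1:3, each = 20),
                     class_label = rep(c("a", "b"), 30),
                     image_id = rep(1:6, each = 10))
  out <- pca_realism(ref, list(spectra))
  expect_gte(sum(out$explained), 0.999)
  # candidate identical to reference projects onto the same cloud
  expect_equal(out$candidate_scores[[1]], out$reference_scores,
               ignore_attr = TRUE)
  expect_equal(out$coverage[[1]], 1)
  # constant shift in spectrum space shifts the embedding by its projection
  shift <- rep(0.05, 12)
  out2 <- pca_realism(ref, list(sweep(spectra, 2, -shift)))
  delta <- out2$candidate_scores[[1]] - out$reference_scores
  expected <- as.numeric(shift %*% out$rotation)
  expect_equal(delta[1, ], expected, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(abs(sweep(delta, 2, expected))), 0, tolerance = 1e-10)
  expect_error(pca_realism(spectra_set(spectra, 1:12), list()), "annotations")
})

test_that("equal-size subsampling is seeded and size-correct", {
  set.seed(25)
  s <- spectra_set(matrix(runif(200), 20, 10), 1:10,
                   subject_id = rep(1:4, 5), class_label = rep("x", 20))
  sub1 <- subsample_spectra(s, 8, seed = 1)
  sub2 <- subsample_spectra(s, 8, seed = 1)
  expect_identical(sub1, sub2)
  expect_equal(nrow(sub1$spectra), 8)
  expect_error(subsample_spectra(s, 25, seed = 1))
})
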