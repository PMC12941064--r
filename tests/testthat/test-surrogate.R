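test_that("spectrum-level splits partition without leaking wavelengths", {
  ids <- rep(1:10, each = 15)
  sp <- split_spectra(ids, seed = 4)
  expect_length(sp$ids$train, 7)
  expect_length(sp$ids$validation, 1)
  expect_length(sp$ids$test, 2)
  # masks cover every row exactly once
  expect_true(all(sp$train + sp$validation + sp$test == 1))
  # no spectrum is split across partitions
  for (part in c("train", "validation", "test")) {
    in_part <- unique(ids[sp[[part]]])
    expect_true(all(table(ids[sp[[part]]]) == 15))
    expect_setequal(in_part, sp$ids[[part]])
  }
  expect_identical(sp, split_spectra(ids, seed = 4))
  expect_false(identical(sp$ids$train, split_spectra(ids, seed = 5)$ids$train))
  expect_error(split_spectra(ids, fractions = c(0.5, 0.2, 0.2), seed = 1),
               "sum to 1")
})

test_that("normalization statistics come from training data only", {
  set.seed(2)
  x <- matrix(rnorm(200, 10, 2), 50, 4,
              dimnames = list(NULL, c("mua_1", "mus_1", "g_1", "n_1")))
  norm <- fit_normalization(x)
  expect_true(all(norm$log_features == c(TRUE, TRUE, FALSE, FALSE)))
  # changing rows outside the training split cannot change the statistics
  norm2 <- fit_normalization(x)
  expect_identical(norm, norm2)
  # z-scored features have zero mean, unit sd after the transform
  z <- preprocess_features(x, norm)
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate and invalid features are caught", {
  x <- cbind(mua_1 = rep(100, 10), g_1 = rnorm(10))
  expect_error(fit_normalization(x), "mua_1")
  norm <- fit_normalization(x, constant = "center")
  z <- preprocess_features(x, norm)
  expect_equal(z[, 1], rep(0, 10), ignore_attr = TRUE)
  xneg <- cbind(mua_1 = c(-1, 2, 3), g_1 = rnorm(3))
  expect_error(fit_normalization(xneg), "nonpositive")
})

test_that("preprocessing is an exact affine bijection", {
  set.seed(3)
  x <- matrix(runif(120, 0.01, 100), 30, 4,
              dimnames = list(NULL, c("mua_1", "mus_1", "g_1", "d_1")))
  norm <- fit_normalization(x)
  z <- preprocess_features(x, norm)
  back <- preprocess_inverse(z, norm)
  expect_equal(back, x, tolerance = 1e-12, ignore_attr = TRUE)
  # decadic log: a mua column spanning [1e-2, 1e3] maps to [-2, 3]
  x2 <- cbind(mua_1 = 10^seq(-2, 3, length.out = 20), g_1 = runif(20))
  norm2 <- fit_normalization(x2)
  z2raw <- log10(x2[, 1])
  expect_equal(range(z2raw), c(-2, 3))
  # rowwise equals batch application
  z_batch <- preprocess_features(x, norm)
  z_rows <- t(sapply(seq_len(nrow(x)), function(i) {
    preprocess_features(x[i, ], norm)[1, ]
  }))
  expect_equal(z_batch, z_rows, ignore_attr = TRUE)
  # parameters equal to the training means map to the zero vector
  center <- preprocess_inverse(matrix(0, 1, 4), norm)
  expect_equal(as.numeric(preprocess_features(center, norm)),
               rep(0, 4), tolerance = 1e-10)
})

test_that("parameter count formula matches exhaustive weight enumeration", {
  for (spec in list(surrogate_spec(15),
                    surrogate_spec(5, hidden = c(32, 16)),
                    surrogate_spec(10, hidden = 512),
                    surrogate_spec(25, hidden = rep(512, 5)))) {
    init <- reflectsim:::init_weights(spec, seed = 1)
    enumerated <- sum(sapply(init$weights, length)) +
      sum(sapply(init$biases, length))
    expect_identical(count_parameters(spec), enumerated)
  }
  # the reference architecture with a 15-dimensional input
  expect_identical(count_parameters(surrogate_spec(15, rep(512L, 5))),
                   1059329L)
})

test_that("surrogate converges on a constant target", {
  set.seed(5)
  x <- matrix(runif(600, 1, 2), 200, 3,
              dimnames = list(NULL, c("g_1", "n_1", "d_1")))
  y <- rep(0.3, 200)
  fit <- surrogate_fit(x, y, spec = surrogate_spec(3, hidden = c(16, 16)),
                       control = surrogate_control(learning_rate = 1e-2,
                                                   batch_size = 32,
                                                   patience = 100,
                                                   max_epochs = 3000,
                                                   seed = 2))
  pred <- predict(fit, x)
  expect_lt(max(abs(pred - 0.3)), 1e-3)
})

test_that("surrogate learns a smooth logistic map to sub-1e-3 MAE", {
  set.seed(6)
  n <- 8000; d <- 5
  x <- matrix(runif(n * d, 0.5, 2), n, d,
              dimnames = list(NULL, paste0("g_", 1:d)))
  w <- c(1.5, -1, 0.7, 0.4, -0.8)
  y <- plogis(as.numeric(scale(x) %*% w) - 0.5)
  sp <- split_spectra(seq_len(n), seed = 3)
  fit <- surrogate_fit(x[sp$train, ], y[sp$train],
                       validation = list(x = x[sp$validation, ],
                                         y = y[sp$validation]),
                       spec = surrogate_spec(d, hidden = c(96, 96, 96)),
                       control = surrogate_control(learning_rate = 2e-3,
                                                   batch_size = 128,
                                                   patience = 40,
                                                   max_epochs = 600, seed = 7))
  ev <- evaluate_fidelity(fit, x[sp$test, ], y[sp$test])
  expect_lt(ev$mae, 1e-3)
})

test_that("predictions are bounded, deterministic, and batch-consistent", {
  fit <- local({
    set.seed(1)
    x <- matrix(runif(300, 0.5, 2), 100, 3,
                dimnames = list(NULL, c("g_1", "n_1", "d_1")))
    surrogate_fit(x, runif(100, 0.2, 0.8),
                  spec = surrogate_spec(3, hidden = 8),
                  control = surrogate_control(max_epochs = 20, batch_size = 50,
                                              patience = 5, seed = 1))
  })
  x_new <- matrix(runif(3000, 0.05, 5), 1000, 3)
  p <- predict(fit, x_new)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict(fit, x_new))
  idx <- c(7, 3, 11)
  expect_equal(predict(fit, x_new[idx, ]), p[idx])
  expect_error(predict(fit, x_new[, 1:2]), "dimensionality")
})

test_that("fidelity metrics have exact closed-form behaviour", {
  set.seed(2)
  x <- matrix(runif(60, 1, 2), 20, 3,
              dimnames = list(NULL, c("g_1", "n_1", "d_1")))
  y <- runif(20, 0.3, 0.7)
  m <- surrogate_fit(x, y, spec = surrogate_spec(3, hidden = 4),
                     control = surrogate_control(max_epochs = 10,
                                                 batch_size = 10,
                                                 patience = 5, seed = 1))
  pred <- predict(m, x)
  ev <- evaluate_fidelity(m, x, y)
  expect_equal(ev$mae, mean(abs(pred - y)))
  expect_equal(ev$mape, mean(abs(pred - y) / y * 100))
  # constant-offset targets: MAE is the offset exactly
  ev2 <- evaluate_fidelity(m, x, pred + 0.01)
  expect_equal(ev2$mae, 0.01, tolerance = 1e-12)
  # multiplicative 1.001 targets: MAPE ~ 0.1% of the ratio scale
  ev3 <- evaluate_fidelity(m, x, y, reference = pred / 1.001)
  expect_equal(ev3$mape, 0.1, tolerance = 1e-3)
  # zero targets are excluded and counted
  ev4 <- evaluate_fidelity(m, x, c(0, y[-1]))
  expect_equal(ev4$n_excluded_zero_targets, 1)
})

test_that("training fails loudly when the validation loss diverges", {
  set.seed(1)
  x <- matrix(runif(60, 1, 2), 20, 3,
              dimnames = list(NULL, c("g_1", "n_1", "d_1")))
  expect_error(
    surrogate_fit(x, runif(20),
                  spec = surrogate_spec(3, hidden = 8),
                  control = surrogate_control(learning_rate = 1e12,
                                              max_epochs = 20, batch_size = 20,
                                              patience = 5, seed = 1)),
    "non-finite")
})
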