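# Neural data-scaling experiment: nested subsampling of the training pool,
# per-size retraining, and power-law fitting of test error vs. dataset size.

#' Nested subsampling of training spectra
#'
#' Selects a fraction of the training pool at the spectrum level. Subsets are
#' nested: under the same seed, the subset at a smaller fraction is contained
#' in the subset at any larger fraction (samples are only ever added, the
#' validation and test splits stay fixed). Subset sizes are floored to whole
#' spectra with a minimum of one.
#'
#' @param spectrum_ids spectrum ids of the training pool rows.
#' @param fraction fraction in (0, 1\].
#' @param seed integer seed shared across fractions to obtain nesting.
#' @return Logical row mask selecting the subset.
#' @export
subsample_training <- function(spectrum_ids, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  ids <- unique(spectrum_ids)
  set.seed(seed)
  order_ids <- sample(ids)  # one fixed ranking; prefixes give nesting
  n_take <- max(1L, floor(fraction * length(ids)))
  spectrum_ids %in% order_ids[seq_len(n_take)]
}

#' Run the data-scaling experiment
#'
#' Trains one surrogate per (fraction, fold) on nested subsets of the training
#' pool and evaluates every model on the same fixed test split. Folds
#' partition only the training pool (fivefold protocol with a fixed global
#' validation and test set); with `folds = 1` the whole pool is used once.
#' `n_data` counts training rows (spectra x wavelengths).
#'
#' @param dataset a `reflect_dataset`.
#' @param split a [split_spectra()] partition of the dataset.
#' @param fractions numeric vector of training-pool fractions in (0, 1\].
#' @param spec a [surrogate_spec()] (NULL = default for the input width).
#' @param control a [surrogate_control()].
#' @param folds number of training-pool folds.
#' @param seed integer seed for subsampling and fold assignment.
#' @return Data frame with columns `fraction`, `n_data`, `fold`, `mae`.
#'   Training failures are recorded as `NA` with a warning and excluded from
#'   downstream fits.
#' @export
run_scaling_experiment <- function(dataset, split, fractions, spec = NULL,
                                   control = surrogate_control(),
                                   folds = 1L, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  pool <- which(split$train)
  test <- which(split$test)
  val <- which(split$validation)
  xval <- dataset$params[val, , drop = FALSE]
  yval <- dataset$reflectance[val]
  xtest <- dataset$params[test, , drop = FALSE]
  ytest <- dataset$reflectance[test]

  pool_ids <- dataset$spectrum_id[pool]
  uids <- unique(pool_ids)
  set.seed(seed + 1L)
  fold_of <- sample(rep_len(seq_len(folds), length(uids)))
  names(fold_of) <- as.character(uids)

  rows <- list()
  for (f in sort(fractions)) {
    mask <- subsample_training(pool_ids, f, seed)
    for (k in seq_len(folds)) {
      keep <- mask & (folds == 1L | fold_of[as.character(pool_ids)] != k)
      idx <- pool[keep]
      mae <- tryCatch({
        fit <- surrogate_fit(dataset$params[idx, , drop = FALSE],
                             dataset$reflectance[idx],
                             validation = list(x = xval, y = yval),
                             spec = spec, control = control)
        evaluate_fidelity(fit, xtest, ytest)$mae
      }, error = function(e) {
        warning(sprintf("training failed at fraction %g fold %d: %s",
                        f, k, conditionMessage(e)))
        NA_real_
      })
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, n_data = length(idx), fold = k, mae = mae)
    }
  }
  do.call(rbind, rows)
}

#' Fit a power law to test error vs. training size
#'
#' Models test error as \eqn{a N^b + c} and fits by least squares of
#' `log10(a N^b + c)` against `log10(error)` with a bounded
#' Levenberg-Marquardt optimizer (bounds \[0, -5, 0\] to \[Inf, 5, 1e-2\]).
#' Parameter standard deviations come from the fit covariance.
#'
#' @param sizes training-set sizes N (>= 4 distinct values).
#' @param errors observed test errors (> 0), same length.
#' @param lower,upper parameter bounds, in order (a, b, c).
#' @return An object of class `power_law_fit` with `a`, `b`, `c`, `std_a`,
#'   `std_b`, `std_c`, `sizes`, `errors`, and the underlying `fit`.
#' @export
fit_power_law <- function(sizes, errors,
                          lower = c(0, -5, 0), upper = c(Inf, 5, 1e-2)) {
  keep <- is.finite(sizes) & is.finite(errors)
  sizes <- sizes[keep]; errors <- errors[keep]
  if (length(unique(sizes)) < 4) stop("need at least 4 distinct sizes")
  if (any(errors <= 0)) stop("errors must be positive")

  logN <- log10(sizes)
  logE <- log10(errors)
  # starting values from a straight-line fit in log-log space
  lm0 <- stats::lm(logE ~ logN)
  b0 <- min(max(stats::coef(lm0)[2], lower[2] + 0.1), upper[2] - 0.1)
  a0 <- max(10^stats::coef(lm0)[1], 1e-12)
  c0 <- min(max(min(errors) / 10, lower[3] + 1e-12), upper[3])

  resid_fn <- function(p) log10(p[1] * 10^(logN * p[2]) + p[3]) - logE
  fit <- minpack.lm::nls.lm(
    par = c(a = a0, b = unname(b0), c = c0), fn = resid_fn,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info == 0 || !all(is.finite(fit$par))) {
    stop("power-law fit did not converge; residual diagnostics: ",
         paste(signif(fit$fvec, 3), collapse = ", "))
  }
  est <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(est)))
  structure(
    list(a = unname(est["a"]), b = unname(est["b"]), c = unname(est["c"]),
         std_a = unname(se["a"]), std_b = unname(se["b"]),
         std_c = unname(se["c"]),
         sizes = sizes, errors = errors, fit = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Scaling-law fit: error(N) = a * N^b + c\n")
  cat(sprintf("  a = %.4g (sd %.2g)\n  b = %.4g (sd %.2g)\n  c = %.4g (sd %.2g)\n",
              x$a, x$std_a, x$b, x$std_b, x$c, x$std_c))
  invisible(x)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  pred <- predict(object, object$sizes)
  resid <- log10(object$errors) - log10(pred)
  out <- list(coefficients = coef(object),
              std = c(a = object$std_a, b = object$std_b, c = object$std_c),
              rms_log_residual = sqrt(mean(resid^2)),
              n_points = length(object$sizes))
  class(out) <- "summary.power_law_fit"
  out
}

#' @export
print.summary.power_law_fit <- function(x, ...) {
  cat("Scaling-law fit: error(N) = a * N^b + c\n")
  print(rbind(estimate = x$coefficients, std = x$std))
  cat(sprintf("  RMS log10 residual: %.3g over %d points\n",
              x$rms_log_residual, x$n_points))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
predict.power_law_fit <- function(object, newdata = NULL, ...) {
  N <- if (is.null(newdata)) object$sizes else as.numeric(newdata)
  object$a * N^object$b + object$c
}

#' @export
plot.power_law_fit <- function(x, ...) {
  graphics::plot(x$sizes, x$errors, log = "xy", xlab = "training rows N",
                 ylab = "test MAE", main = "Data-scaling law", ...)
  N <- 10^seq(log10(min(x$sizes)), log10(max(x$sizes)), length.out = 100)
  graphics::lines(N, predict(x, N))
  invisible(x)
}
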