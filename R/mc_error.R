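#' Maximum-likelihood reflectance estimate
#'
#' Under the Bernoulli photon model (each photon either returns through the
#' top surface or does not), the maximum-likelihood estimator of diffuse
#' reflectance is the success fraction `n_returned / n_total`.
#'
#' @param n_returned returned photon count, 0 <= n_returned <= n_total.
#' @param n_total launched photon count, >= 1.
#' @return The reflectance estimate r_hat.
#' @export
mle_reflectance <- function(n_returned, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1: estimate undefined")
  stopifnot(all(n_returned >= 0), all(n_returned <= n_total))
  n_returned / n_total
}

#' Binomial uncertainty of a Monte Carlo reflectance estimate
#'
#' Models the photon tally as binomial B(n_total, r_hat): the count-scale
#' standard deviation is \eqn{\hat\sigma = \sqrt{N r (1-r)}}, the
#' reflectance-scale standard deviation is \eqn{\hat\sigma / N}, and the
#' coefficient of variation (relative MC error) is
#' \eqn{CoV = \sqrt{(1-r)/(N r)}}. The identity
#' `cov * n_total * r_hat == sigma_counts` holds exactly.
#'
#' @param r_hat reflectance estimate; CoV requires 0 < r_hat < 1.
#' @param n_total photon count, >= 1.
#' @param pi_level prediction-interval level (see [prediction_interval()]).
#' @return An object of class `mc_error_estimate` with fields `r_hat`,
#'   `n_total`, `sigma_counts`, `sigma_reflectance`, `cov`, `pi_level`,
#'   `pi_low`, `pi_high`. For degenerate r_hat in {0, 1}, `cov` is `NaN` with
#'   a warning and `sigma_counts` is 0.
#' @export
reflectance_uncertainty <- function(r_hat, n_total, pi_level = 0.95) {
  stopifnot(all(r_hat >= 0), all(r_hat <= 1), all(n_total >= 1))
  sigma_counts <- sqrt(n_total * r_hat * (1 - r_hat))
  degenerate <- r_hat == 0 | r_hat == 1
  # computed as sigma/mu so the identity cov * N * r == sigma_counts is exact;
  # algebraically equal to sqrt((1 - r) / (N r))
  cov <- ifelse(degenerate, NaN, sigma_counts / (n_total * r_hat))
  if (any(degenerate)) {
    warning("coefficient of variation undefined for r_hat in {0, 1}")
  }
  pi <- prediction_interval(r_hat, n_total, pi_level)
  structure(
    list(r_hat = r_hat, n_total = n_total, sigma_counts = sigma_counts,
         sigma_reflectance = sigma_counts / n_total, cov = cov,
         pi_level = pi_level, pi_low = pi$pi_low, pi_high = pi$pi_high),
    class = "mc_error_estimate"
  )
}

#' @export
print.mc_error_estimate <- function(x, ...) {
  cat(sprintf(
    "MC error model: r_hat = %.6g, N = %g\n  sigma (counts) = %.6g, sigma (reflectance) = %.3g, CoV = %.3g\n  %g%% PI: [%.6g, %.6g]\n",
    x$r_hat[1], x$n_total[1], x$sigma_counts[1], x$sigma_reflectance[1],
    x$cov[1], 100 * x$pi_level, x$pi_low[1], x$pi_high[1]))
  invisible(x)
}

#' Prediction interval for a Monte Carlo reflectance estimate
#'
#' Normal approximation to the binomial error distribution:
#' `r_hat +/- z(level) * sigma_reflectance`, clipped to \[0, 1\]. An exact
#' Clopper-Pearson interval is available with `exact = TRUE`.
#'
#' @param r_hat reflectance estimate.
#' @param n_total photon count.
#' @param level interval level in (0, 1).
#' @param exact use the exact (Clopper-Pearson) interval instead of the
#'   normal approximation.
#' @return List with `pi_low` and `pi_high`.
#' @export
prediction_interval <- function(r_hat, n_total, level = 0.95, exact = FALSE) {
  stopifnot(level > 0, level < 1)
  if (exact) {
    k <- round(r_hat * n_total)
    alpha <- 1 - level
    lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n_total - k + 1))
    hi <- ifelse(k == n_total, 1,
                 stats::qbeta(1 - alpha / 2, k + 1, n_total - k))
    return(list(pi_low = lo, pi_high = hi))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd_r <- sqrt(r_hat * (1 - r_hat) / n_total)
  list(pi_low = pmax(0, r_hat - z * sd_r), pi_high = pmin(1, r_hat + z * sd_r))
}
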