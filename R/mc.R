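#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized Fresnel reflection coefficients at a
#' planar interface; beyond the critical angle the result is exactly 1 (total
#' internal reflection).
#'
#' @param n1 refractive index on the incidence side (>= 1).
#' @param n2 refractive index on the transmission side (>= 1).
#' @param cos_theta_i cosine of the incidence angle, in \[0, 1\].
#' @return Reflection probability in \[0, 1\].
#' @export
fresnel_reflectance <- function(n1, n2, cos_theta_i) {
  stopifnot(n1 >= 1, n2 >= 1, cos_theta_i >= 0, cos_theta_i <= 1)
  fresnel_cpp(n1, n2, cos_theta_i)
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Analytic inverse-CDF sampling of the Henyey-Greenstein phase function:
#' for g != 0,
#' \deqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1-g^2}{1-g+2gu}\right)^2\right],}
#' and for g = 0, \eqn{\cos\theta = 2u - 1}.
#'
#' @param g anisotropy, |g| < 1.
#' @param u uniform variate(s) in \[0, 1).
#' @return Deflection cosine(s) in \[-1, 1\].
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot(abs(g) < 1, all(u >= 0), all(u < 1))
  hg_cosine_cpp(g, u)
}

#' Monte Carlo diffuse reflectance of a layered slab
#'
#' Launches `n_photons` pencil-beam photons at normal incidence onto an
#' infinitely wide layered slab and tallies total diffuse reflectance. The
#' specular fraction at the top surface is removed at entry and reported
#' separately. Transport follows the weighted (implicit-capture) random walk:
#' step `s = -ln(u)/mu_t`, absorption deposit `W mu_a/mu_t` per interaction,
#' Henyey-Greenstein deflection, Fresnel-governed reflection/refraction at
#' every interface, and Russian roulette below `roulette_threshold` with
#' survival probability `1/roulette_m`. Results are reproducible bit-for-bit
#' under a fixed seed: every photon owns a counter-based random stream keyed
#' by `(seed, stream, photon index)`, independent of batching.
#'
#' @param column a [tissue_column()].
#' @param n_photons number of photons to launch (>= 1).
#' @param seed integer seed.
#' @param roulette_threshold photon weight below which roulette is played.
#' @param roulette_m roulette survival factor m (survive with probability 1/m,
#'   weight multiplied by m).
#' @param stream integer substream id, used by [simulate_spectrum()] to give
#'   each wavelength an independent stream under one seed.
#' @return An object of class `mc_result`: list with `r_hat`, `r_specular`,
#'   `transmitted_weight`, `absorbed_weight`, `n_total`,
#'   `n_returned_effective`, `seed`.
#' @export
simulate_reflectance <- function(column, n_photons, seed,
                                 roulette_threshold = 1e-4, roulette_m = 10,
                                 stream = 0L) {
  stopifnot(inherits(column, "tissue_column"), n_photons >= 1)
  ly <- column$layers
  mua <- vapply(ly, `[[`, numeric(1), "mu_a")
  mus <- vapply(ly, `[[`, numeric(1), "mu_s")
  g <- vapply(ly, `[[`, numeric(1), "g")
  n <- vapply(ly, `[[`, numeric(1), "n")
  d <- vapply(ly, `[[`, numeric(1), "d")
  if (any(!is.finite(c(mua, mus, g, n, d)))) {
    stop("non-finite optical properties in tissue column")
  }
  res <- mc_simulate_cpp(mua, mus, g, n, d, column$ambient_n,
                         column$ambient_n, as.numeric(n_photons),
                         as.integer(seed), as.integer(stream),
                         roulette_threshold, as.integer(roulette_m))
  res$n_returned_effective <- res$r_hat * res$n_total
  res$seed <- as.integer(seed)
  class(res) <- "mc_result"
  res
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "MC reflectance: r_hat = %.6f (specular %.4f, transmitted %.4f, absorbed %.4f)\n",
    x$r_hat, x$r_specular, x$transmitted_weight, x$absorbed_weight))
  cat(sprintf("  photons: %g, seed: %d\n", x$n_total, x$seed))
  invisible(x)
}

#' Energy bookkeeping of a simulation result
#'
#' Sum of specular, diffuse, transmitted and absorbed fractions; equals 1 up
#' to the (unbiased) variance added by Russian roulette.
#'
#' @param result an `mc_result`.
#' @return The energy sum.
#' @export
energy_closure <- function(result) {
  result$r_specular + result$r_hat + result$transmitted_weight +
    result$absorbed_weight
}

#' Simulate a reflectance spectrum
#'
#' One independent Monte Carlo simulation per wavelength; wavelength
#' dependence enters through the physical parameters (absorption and
#' scattering), converted from physiology with [physical_properties()]. Each
#' wavelength uses an independent substream derived from `seed`, so the
#' spectrum is reproducible as a whole.
#'
#' @param phys list of [layer_physiology()] objects (one tissue column).
#' @param wavelengths wavelength grid (nm).
#' @param table a [chromophore_table()].
#' @param n_photons photons per wavelength.
#' @param seed integer seed.
#' @param ambient_n ambient refractive index.
#' @param ... passed to [simulate_reflectance()].
#' @return List with `wavelengths`, `values` (the spectrum r_lambda) and
#'   `results` (per-wavelength `mc_result`s).
#' @export
simulate_spectrum <- function(phys, wavelengths, table, n_photons, seed,
                              ambient_n = 1.0, ...) {
  results <- vector("list", length(wavelengths))
  for (i in seq_along(wavelengths)) {
    col <- physical_properties(phys, wavelengths[i], table,
                               ambient_n = ambient_n)
    results[[i]] <- simulate_reflectance(col, n_photons, seed,
                                         stream = i, ...)
  }
  list(wavelengths = as.numeric(wavelengths),
       values = vapply(results, `[[`, numeric(1), "r_hat"),
       results = results)
}
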