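#' Chromophore extinction table
#'
#' Holds molar extinction coefficients of oxy- and deoxyhemoglobin on a strictly
#' increasing wavelength grid. Values are interpolated linearly inside the
#' tabulated range only; requests outside it are an error (no extrapolation).
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param eps_hbo2 molar extinction of oxyhemoglobin (L mol^-1 cm^-1), > 0.
#' @param eps_hb molar extinction of deoxyhemoglobin (L mol^-1 cm^-1), > 0.
#' @return An object of class `chromophore_table`.
#' @export
chromophore_table <- function(wavelength_nm, eps_hbo2, eps_hb) {
  wavelength_nm <- as.numeric(wavelength_nm)
  eps_hbo2 <- as.numeric(eps_hbo2)
  eps_hb <- as.numeric(eps_hb)
  if (length(wavelength_nm) < 2L) {
    stop("chromophore table needs at least two wavelengths")
  }
  if (length(eps_hbo2) != length(wavelength_nm) ||
      length(eps_hb) != length(wavelength_nm)) {
    stop("extinction columns must match the wavelength grid length")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(eps_hbo2)) || any(!is.finite(eps_hb)) ||
      any(eps_hbo2 <= 0) || any(eps_hb <= 0)) {
    stop("extinction coefficients must be finite and strictly positive")
  }
  structure(
    list(wavelength_nm = wavelength_nm, eps_hbo2 = eps_hbo2, eps_hb = eps_hb),
    class = "chromophore_table"
  )
}

#' Read a chromophore table from CSV
#'
#' Expects a header `wavelength_nm,eps_hbo2,eps_hb`.
#'
#' @param path path to the CSV file.
#' @return A [chromophore_table()].
#' @export
read_chromophore_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb")
  if (!all(need %in% names(df))) {
    stop("chromophore CSV must have columns: ", paste(need, collapse = ", "))
  }
  chromophore_table(df$wavelength_nm, df$eps_hbo2, df$eps_hb)
}

#' Default hemoglobin extinction table
#'
#' Loads the synthetic hemoglobin extinction table shipped with the package
#' (`inst/extdata/hemoglobin_extinction_synthetic.csv`). This table is a smooth
#' parametric stand-in reproducing the canonical qualitative features of whole
#' hemoglobin spectra -- the oxyhemoglobin Q-bands near 542 and 577 nm, the
#' deoxyhemoglobin band near 555 nm, the steep fall-off above 600 nm, the
#' deoxyhemoglobin shoulder near 760 nm and the near-infrared crossover around
#' 800 nm -- not a measured compilation. It covers 450 to 1050 nm in 2 nm steps.
#'
#' @return A [chromophore_table()].
#' @export
default_chromophore_table <- function() {
  path <- system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                      package = "reflectsim", mustWork = TRUE)
  read_chromophore_table(path)
}

#' Synthetic hemoglobin extinction spectra
#'
#' Generates the smooth synthetic extinction table used as the package default
#' (see [default_chromophore_table()]): sums of Gaussian bands on top of
#' exponential baselines, in units of L mol^-1 cm^-1.
#'
#' @param wavelength_nm wavelength grid (nm).
#' @return A data.frame with columns `wavelength_nm`, `eps_hbo2`, `eps_hb`.
#' @export
synthetic_hemoglobin_extinction <- function(wavelength_nm = seq(450, 1050, by = 2)) {
  lam <- as.numeric(wavelength_nm)
  gauss <- function(mu, sd, amp) amp * exp(-0.5 * ((lam - mu) / sd)^2)
  # oxyhemoglobin: Soret tail, Q-bands at 542/577, NIR rise
  hbo2 <- 300 +
    55000 * exp(-(lam - 450) / 28) +           # Soret band tail
    gauss(542, 11, 52000) +
    gauss(577, 9, 55000) +
    900 * exp(-0.5 * ((lam - 930) / 160)^2)    # broad NIR rise
  # deoxyhemoglobin: Soret tail, single band at 555, slow red decay, 760 bump
  hb <- 250 +
    80000 * exp(-(lam - 450) / 30) +
    gauss(555, 17, 50000) +
    14000 * exp(-(lam - 600) / 55) * (lam >= 600) +
    gauss(605, 40, 9000) * (lam < 600) +       # smooth red shoulder
    gauss(758, 28, 1250)
  data.frame(wavelength_nm = lam, eps_hbo2 = hbo2, eps_hb = hb)
}

# Linear interpolation inside the tabulated range; error outside.
interp_extinction <- function(table, lambda_nm) {
  rng <- range(table$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2])) {
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm",
                 rng[1], rng[2]))
  }
  list(
    eps_hbo2 = stats::approx(table$wavelength_nm, table$eps_hbo2,
                             xout = lambda_nm)$y,
    eps_hb = stats::approx(table$wavelength_nm, table$eps_hb,
                           xout = lambda_nm)$y
  )
}

#' @export
print.chromophore_table <- function(x, ...) {
  cat(sprintf("Chromophore table: %d wavelengths, %g-%g nm\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  invisible(x)
}
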