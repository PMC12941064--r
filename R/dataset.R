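# Dataset assembly: physiology -> flattened physical-parameter rows, plus the
# Monte Carlo simulation loop that produces training/evaluation records.

#' Flatten physiology to physical-parameter rows
#'
#' Converts a list of physiological tissue columns to the surrogate's input
#' encoding: one row per column, with the five physical parameters
#' (mu_a, mu_s, g, n, d) of every layer at the row's wavelength, flattened
#' layer by layer. Column names are `mua_l`, `mus_l`, `g_l`, `n_l`, `d_l` for
#' layer `l`.
#'
#' @param phys_list list of tissue columns (each a list of
#'   [layer_physiology()]).
#' @param lambda_nm wavelength per row (nm): scalar (shared) or vector of
#'   length `length(phys_list)`.
#' @param table a [chromophore_table()].
#' @return Numeric matrix, `length(phys_list)` x `5 * n_layers`.
#' @export
physical_parameter_matrix <- function(phys_list, lambda_nm, table) {
  n <- length(phys_list)
  if (length(lambda_nm) == 1L) lambda_nm <- rep(lambda_nm, n)
  stopifnot(length(lambda_nm) == n)
  L <- length(phys_list[[1]])
  eps <- interp_extinction(table, lambda_nm)
  out <- matrix(0, n, 5L * L)
  cn <- character(5L * L)
  get <- function(f, l) vapply(phys_list, function(p) p[[l]][[f]], numeric(1))
  for (l in seq_len(L)) {
    vhb <- get("vhb", l); sto2 <- get("sto2", l)
    a_mie <- get("a_mie", l); b_mie <- get("b_mie", l)
    g <- get("g", l); nn <- get("n", l); d <- get("d", l)
    mua <- vhb * log(10) * (150 / 64500) *
      (sto2 * eps$eps_hbo2 + (1 - sto2) * eps$eps_hb)
    mus <- a_mie * (lambda_nm / 500)^(-b_mie) / (1 - g)
    j <- (l - 1L) * 5L
    out[, j + 1L] <- mua; out[, j + 2L] <- mus
    out[, j + 3L] <- g; out[, j + 4L] <- nn; out[, j + 5L] <- d
    cn[j + seq_len(5L)] <- paste0(c("mua_", "mus_", "g_", "n_", "d_"), l)
  }
  colnames(out) <- cn
  out
}

#' Simulate a Monte Carlo reflectance dataset
#'
#' Runs one Monte Carlo simulation per (tissue column, wavelength) pair and
#' returns long-form records: physical-parameter rows plus the simulated
#' diffuse reflectance. With `per_sample_wavelength = TRUE` each column is
#' simulated at a single wavelength cycled from the grid (single-wavelength
#' samples); otherwise every column is simulated at the full grid, giving a
#' spectrum per column.
#'
#' @param phys_list list of tissue columns from [sample_physiology()].
#' @param wavelengths wavelength grid (nm).
#' @param table a [chromophore_table()].
#' @param n_photons photons per simulation.
#' @param seed integer seed; row `i` uses substream `i`.
#' @param per_sample_wavelength one wavelength per column instead of the full
#'   grid.
#' @param ambient_n ambient refractive index.
#' @param roulette_threshold,roulette_m roulette settings passed to
#'   [simulate_reflectance()]; bulk generation defaults to a higher threshold
#'   than single simulations (termination stays unbiased, bulk throughput
#'   roughly doubles at a small variance cost).
#' @return An object of class `reflect_dataset`: list with `params` (matrix),
#'   `reflectance`, `wavelength`, `spectrum_id`, and `meta` (photons, seed,
#'   model name).
#' @export
simulate_dataset <- function(phys_list, wavelengths, table, n_photons, seed,
                             per_sample_wavelength = FALSE, ambient_n = 1.0,
                             roulette_threshold = 0.05, roulette_m = 10) {
  n <- length(phys_list)
  if (per_sample_wavelength) {
    lam <- rep_len(wavelengths, n)
    sid <- seq_len(n)
    cols <- seq_len(n)
  } else {
    lam <- rep(wavelengths, times = n)
    sid <- rep(seq_len(n), each = length(wavelengths))
    cols <- rep(seq_len(n), each = length(wavelengths))
  }
  params <- physical_parameter_matrix(phys_list[cols], lam, table)
  L <- length(phys_list[[1]])
  refl <- numeric(length(lam))
  for (i in seq_along(lam)) {
    row <- params[i, ]
    layers <- lapply(seq_len(L), function(l) {
      j <- (l - 1L) * 5L
      list(mu_a = row[j + 1L], mu_s = row[j + 2L], g = row[j + 3L],
           n = row[j + 4L], d = row[j + 5L])
    })
    col <- tissue_column(layers, ambient_n = ambient_n)
    refl[i] <- simulate_reflectance(col, n_photons, seed, stream = i,
                                    roulette_threshold = roulette_threshold,
                                    roulette_m = roulette_m)$r_hat
  }
  structure(
    list(params = params, reflectance = refl, wavelength = lam,
         spectrum_id = sid,
         meta = list(n_photons = n_photons, seed = seed,
                     model = "three_layer_mc", n_layers = L)),
    class = "reflect_dataset"
  )
}

#' @export
print.reflect_dataset <- function(x, ...) {
  cat(sprintf(
    "Reflectance dataset: %d rows (%d spectra), %d features, %g photons\n",
    length(x$reflectance), length(unique(x$spectrum_id)), ncol(x$params),
    x$meta$n_photons))
  invisible(x)
}

subset_dataset <- function(dataset, rows) {
  structure(
    list(params = dataset$params[rows, , drop = FALSE],
         reflectance = dataset$reflectance[rows],
         wavelength = dataset$wavelength[rows],
         spectrum_id = dataset$spectrum_id[rows],
         meta = dataset$meta),
    class = "reflect_dataset"
  )
}
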