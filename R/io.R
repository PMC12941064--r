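# Dataset container I/O and the inference-timing harness. The container is a
# directory holding a 64-bit-lossless RDS payload plus a JSON manifest with
# provenance attributes and an md5 checksum for corruption detection; the
# same schema serves Monte Carlo and surrogate outputs interchangeably.

#' Write a dataset container
#'
#' @param path directory to create (overwritten if it exists).
#' @param dataset a `reflect_dataset` (see [simulate_dataset()]) or any list
#'   with `params`, `reflectance`, `wavelength`, `spectrum_id`, `meta`.
#' @return The path, invisibly.
#' @export
write_container <- function(path, dataset) {
  need <- c("params", "reflectance", "wavelength", "spectrum_id")
  missing <- setdiff(need, names(dataset))
  if (length(missing)) {
    stop("dataset is missing component(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(dataset$params) != length(dataset$reflectance)) {
    stop("params and reflectance row counts differ")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  payload <- file.path(path, "arrays.rds")
  saveRDS(dataset[need], payload, version = 3)
  manifest <- list(
    schema = "reflectsim-container-v1",
    checksum_md5 = unname(tools::md5sum(payload)),
    n_rows = length(dataset$reflectance),
    n_features = ncol(dataset$params),
    meta = dataset$meta,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dataset container
#'
#' Verifies the manifest checksum and schema before returning the dataset.
#'
#' @param path container directory written by [write_container()].
#' @return A `reflect_dataset`.
#' @export
read_container <- function(path) {
  mpath <- file.path(path, "manifest.json")
  payload <- file.path(path, "arrays.rds")
  if (!file.exists(mpath)) stop("not a container: missing manifest.json")
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$schema, "reflectsim-container-v1")) {
    stop("unknown container schema: ", manifest$schema)
  }
  if (!file.exists(payload)) stop("corrupt container: missing arrays.rds")
  if (!identical(unname(tools::md5sum(payload)), manifest$checksum_md5)) {
    stop("corrupt container: checksum mismatch")
  }
  arrays <- readRDS(payload)
  need <- c("params", "reflectance", "wavelength", "spectrum_id")
  missing <- setdiff(need, names(arrays))
  if (length(missing)) {
    stop("container payload missing dataset(s): ",
         paste(missing, collapse = ", "))
  }
  structure(c(arrays, list(meta = manifest$meta)), class = "reflect_dataset")
}

#' Inference-timing harness
#'
#' Measures the wall time to generate a batch of spectra with the surrogate
#' (physiological-parameter preprocessing plus network forward pass, end to
#' end) and, optionally, with the Monte Carlo engine at one or more photon
#' budgets. Each condition is repeated with freshly sampled, independent
#' parameter sets. Speedup ratios are reported descriptively; they are
#' machine-dependent.
#'
#' @param model a [surrogate_fit()] model.
#' @param space a [parameter_space()] to sample timing inputs from.
#' @param table a [chromophore_table()].
#' @param n_spectra spectra per batch (default 1000).
#' @param wavelengths wavelength grid (default the space's grid).
#' @param mc_photons numeric vector of MC photon budgets to time (NULL skips
#'   the MC arm).
#' @param mc_spectra spectra per MC batch (defaults to `n_spectra`; lower it
#'   to keep MC timing runs short and scale the per-spectrum time).
#' @param repeats repetitions per condition (default 30).
#' @param seed integer seed.
#' @return An object of class `inference_benchmark`: list with `surrogate`
#'   (data frame of wall times, seconds) and `mc` (per photon budget), plus
#'   per-spectrum medians and speedup ratios.
#' @export
benchmark_inference <- function(model, space, table, n_spectra = 1000,
                                wavelengths = space$wavelengths,
                                mc_photons = NULL, mc_spectra = n_spectra,
                                repeats = 30, seed = 1L) {
  fwd <- surrogate_forward(model, table)
  sur_times <- numeric(repeats)
  for (r in seq_len(repeats)) {
    phys <- sample_physiology(space, n_spectra, seed = seed + r)
    t0 <- proc.time()[["elapsed"]]
    invisible(fwd(phys, wavelengths))
    sur_times[r] <- proc.time()[["elapsed"]] - t0
  }
  out <- list(
    surrogate = data.frame(repeat_id = seq_len(repeats), seconds = sur_times),
    surrogate_median_per_spectrum = stats::median(sur_times) / n_spectra,
    n_spectra = n_spectra, n_wavelengths = length(wavelengths)
  )
  if (!is.null(mc_photons)) {
    mc <- list()
    for (np in mc_photons) {
      times <- numeric(repeats)
      for (r in seq_len(repeats)) {
        phys <- sample_physiology(space, mc_spectra, seed = seed + 100 + r)
        t0 <- proc.time()[["elapsed"]]
        for (i in seq_along(phys)) {
          simulate_spectrum(phys[[i]], wavelengths, table, np,
                            seed = seed + r + i)
        }
        times[r] <- proc.time()[["elapsed"]] - t0
      }
      mc[[as.character(np)]] <- data.frame(
        repeat_id = seq_len(repeats), seconds = times)
    }
    out$mc <- mc
    out$mc_median_per_spectrum <- vapply(
      mc, function(d) stats::median(d$seconds) / mc_spectra, numeric(1))
    out$speedup <- out$mc_median_per_spectrum /
      out$surrogate_median_per_spectrum
  }
  class(out) <- "inference_benchmark"
  out
}

#' @export
print.inference_benchmark <- function(x, ...) {
  cat(sprintf(
    "Inference benchmark (%d spectra x %d wavelengths per batch):\n",
    x$n_spectra, x$n_wavelengths))
  cat(sprintf("  surrogate: %.3g s/spectrum (median)\n",
              x$surrogate_median_per_spectrum))
  if (!is.null(x$mc)) {
    for (np in names(x$mc_median_per_spectrum)) {
      cat(sprintf("  MC @ %s photons: %.3g s/spectrum, speedup %.3gx\n",
                  np, x$mc_median_per_spectrum[[np]], x$speedup[[np]]))
    }
  }
  invisible(x)
}
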