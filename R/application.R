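# Camera spectral adaptation, nearest-neighbour stO2 estimation, per-organ
# trajectory aggregation, and the synthetic labelled-cube generator standing
# in for non-public in vivo hyperspectral datasets.

#' Hyperspectral camera model
#'
#' Band response matrix plus light-source irradiance on a fine wavelength
#' grid. Band values of an adapted spectrum are irradiance-weighted averages,
#' so a spectrally flat reflectance is preserved exactly.
#'
#' @param band_centers band-center wavelengths (nm), increasing.
#' @param fine_grid fine wavelength grid (nm) of the response/irradiance.
#' @param response band x fine-wavelength nonnegative weight matrix.
#' @param irradiance light-source spectrum on the fine grid (default flat).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(band_centers, fine_grid, response,
                         irradiance = rep(1, length(fine_grid))) {
  response <- as.matrix(response)
  stopifnot(length(band_centers) == nrow(response),
            length(fine_grid) == ncol(response),
            length(irradiance) == length(fine_grid),
            all(diff(band_centers) > 0), all(response >= 0),
            all(irradiance >= 0))
  wsum <- response %*% irradiance
  if (any(wsum <= 0)) stop("every band needs positive response x irradiance")
  structure(list(band_centers = as.numeric(band_centers),
                 fine_grid = as.numeric(fine_grid),
                 response = response, irradiance = as.numeric(irradiance)),
            class = "camera_model")
}

#' Default 100-band camera
#'
#' Gaussian bands with centers from 500 to 995 nm in 5 nm steps (100 bands;
#' the inclusive 1000 nm endpoint is dropped to keep 100 bands on a 5 nm
#' pitch) and 5 nm full width at half maximum, with flat irradiance.
#'
#' @param fine_step fine-grid step (nm).
#' @param fwhm_nm band full width at half maximum (nm).
#' @return A [camera_model()].
#' @export
default_camera <- function(fine_step = 2.5, fwhm_nm = 5) {
  centers <- seq(500, 995, by = 5)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  # pad by ~4.7 sigma; a 10 nm pad keeps grid points symmetric about every
  # band center for the default steps, so symmetric kernels stay unbiased
  fine <- seq(500 - 10, 995 + 10, by = fine_step)
  response <- outer(centers, fine,
                    function(c, l) exp(-0.5 * ((l - c) / sigma)^2))
  camera_model(centers, fine, response)
}

#' Adapt a fine-grid spectrum to camera bands
#'
#' Band value = sum(response * irradiance * r) / sum(response * irradiance)
#' per band: the irradiance-weighted average of the reflectance under each
#' band's response. Constant spectra are preserved and the map is linear in
#' the input. Input spectra are interpolated linearly onto the camera's fine
#' grid and must cover it.
#'
#' @param spectrum reflectance values on `wavelengths`.
#' @param wavelengths wavelength grid of the input spectrum (nm).
#' @param camera a [camera_model()].
#' @return Vector of band reflectances (one per band).
#' @export
adapt_to_camera <- function(spectrum, wavelengths, camera) {
  if (min(wavelengths) > min(camera$fine_grid) ||
      max(wavelengths) < max(camera$fine_grid)) {
    stop("spectrum does not cover the camera response support")
  }
  r <- stats::approx(wavelengths, spectrum, xout = camera$fine_grid)$y
  w <- sweep(camera$response, 2, camera$irradiance, "*")
  as.numeric((w %*% r) / rowSums(w))
}

# Matrix version: rows of `spectra` adapted at once.
adapt_matrix_to_camera <- function(spectra, wavelengths, camera) {
  if (min(wavelengths) > min(camera$fine_grid) ||
      max(wavelengths) < max(camera$fine_grid)) {
    stop("spectrum does not cover the camera response support")
  }
  interp <- apply(spectra, 1, function(s) {
    stats::approx(wavelengths, s, xout = camera$fine_grid)$y
  })  # fine x n
  w <- sweep(camera$response, 2, camera$irradiance, "*")
  t(w %*% interp / rowSums(w))
}

#' Spectrum library for stO2 lookup
#'
#' Simulated or surrogate-generated spectra on the camera band grid, each
#' carrying the tissue oxygenation that generated it.
#'
#' @param spectra matrix of band spectra (one per row).
#' @param sto2 generating oxygenation per spectrum, in \[0, 1\].
#' @param band_centers camera band grid (nm).
#' @param provenance `"mc"` or `"surrogate"`.
#' @return An object of class `spectrum_library`.
#' @export
spectrum_library <- function(spectra, sto2, band_centers,
                             provenance = c("surrogate", "mc")) {
  provenance <- match.arg(provenance)
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(sto2), all(sto2 >= 0), all(sto2 <= 1),
            ncol(spectra) == length(band_centers))
  structure(list(spectra = spectra, sto2 = as.numeric(sto2),
                 band_centers = as.numeric(band_centers),
                 provenance = provenance),
            class = "spectrum_library")
}

#' @export
print.spectrum_library <- function(x, ...) {
  cat(sprintf("Spectrum library: %d spectra x %d bands (%s)\n",
              nrow(x$spectra), ncol(x$spectra), x$provenance))
  invisible(x)
}

#' Nearest-neighbour stO2 estimation
#'
#' Estimates tissue oxygenation of each pixel spectrum as the stO2 of the
#' single most similar library spectrum under spectral MAE. Matches with
#' distance above `d_max` are discarded (no estimate); ties break to the
#' lowest library index.
#'
#' @param pixels band-spectrum matrix (or single spectrum vector).
#' @param library a [spectrum_library()] on the same band grid.
#' @param d_max rejection threshold on the match distance.
#' @return Data frame with `sto2` (NA where rejected), `distance`, `index`.
#' @export
estimate_sto2 <- function(pixels, library, d_max = 0.02) {
  stopifnot(inherits(library, "spectrum_library"))
  if (nrow(library$spectra) == 0) stop("empty spectrum library")
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1)
  if (ncol(pixels) != ncol(library$spectra)) {
    stop("pixel spectra and library are on different band grids")
  }
  nn <- nn_mae_cpp(as.matrix(pixels), library$spectra)
  sto2 <- library$sto2[nn$index]
  sto2[nn$distance > d_max] <- NA_real_
  data.frame(sto2 = sto2, distance = nn$distance, index = nn$index)
}

#' Labelled hyperspectral cube
#'
#' @param image height x width x bands reflectance array in \[0, 1\].
#' @param label_map height x width integer class indices into `class_names`.
#' @param class_names character vector of organ/tissue class names.
#' @param subject_id subject identifier.
#' @param timepoint acquisition time index.
#' @param phase `"baseline"`, `"ischemia"` or `"reperfusion"`.
#' @param band_centers band grid (nm).
#' @param sto2_truth optional height x width generating stO2 (synthetic cubes
#'   keep it as hidden ground truth for tests).
#' @return An object of class `hsi_cube`.
#' @export
hsi_cube <- function(image, label_map, class_names, subject_id, timepoint,
                     phase = c("baseline", "ischemia", "reperfusion"),
                     band_centers, sto2_truth = NULL) {
  phase <- match.arg(phase)
  stopifnot(length(dim(image)) == 3,
            all(dim(image)[1:2] == dim(label_map)),
            dim(image)[3] == length(band_centers),
            all(label_map >= 1), all(label_map <= length(class_names)))
  structure(list(image = image, label_map = label_map,
                 class_names = class_names, subject_id = subject_id,
                 timepoint = timepoint, phase = phase,
                 band_centers = as.numeric(band_centers),
                 sto2_truth = sto2_truth),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("HSI cube: %dx%d pixels x %d bands, subject %s, t=%s (%s)\n",
              d[1], d[2], d[3], x$subject_id, x$timepoint, x$phase))
  invisible(x)
}

#' Per-organ stO2 trajectories
#'
#' Applies [estimate_sto2()] to every pixel of a time-ordered cube sequence
#' and averages accepted estimates per (subject, organ, timepoint). Rejected
#' pixels are excluded from the mean and reflected in `valid_fraction`.
#'
#' @param cubes list of [hsi_cube()]s (consistent class names).
#' @param library a [spectrum_library()].
#' @param d_max rejection threshold.
#' @return Data frame with `subject`, `organ`, `timepoint`, `phase`,
#'   `mean_sto2` (NA when every pixel was rejected), `valid_fraction`,
#'   `n_pixels`.
#' @export
build_trajectories <- function(cubes, library, d_max = 0.02) {
  cls <- cubes[[1]]$class_names
  for (cb in cubes) {
    if (!identical(cb$class_names, cls)) {
      stop("inconsistent class names across cubes")
    }
  }
  rows <- list()
  for (cb in cubes) {
    d <- dim(cb$image)
    pix <- matrix(cb$image, d[1] * d[2], d[3])
    est <- estimate_sto2(pix, library, d_max)
    lab <- as.vector(cb$label_map)
    for (ci in sort(unique(lab))) {
      sel <- lab == ci
      vals <- est$sto2[sel]
      ok <- !is.na(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = cb$subject_id, organ = cls[ci], timepoint = cb$timepoint,
        phase = cb$phase,
        mean_sto2 = if (any(ok)) mean(vals[ok]) else NA_real_,
        valid_fraction = mean(ok), n_pixels = sum(sel))
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic labelled hyperspectral cube
#'
#' Emulates a labelled in vivo acquisition: the image is tiled into vertical
#' organ stripes; each pixel draws physiology from its organ's parameter
#' space (with the organ's stO2), renders a reflectance spectrum with the
#' supplied forward model on a fine grid, adapts it to the camera, and adds
#' independent Gaussian band noise clipped to \[0, 1\]. The generating stO2
#' per pixel is stored as hidden ground truth.
#'
#' @param organ_specs named list, one entry per organ:
#'   `list(space = parameter_space, sto2 = value)`.
#' @param camera a [camera_model()].
#' @param forward function `(phys_list, wavelengths) -> matrix` of
#'   reflectance rows; see [surrogate_forward()].
#' @param height,width cube dimensions in pixels.
#' @param noise_sd Gaussian band-noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param subject_id,timepoint,phase cube metadata.
#' @param fine_wavelengths rendering grid (nm); must cover the camera
#'   response support.
#' @return An [hsi_cube()].
#' @export
generate_synthetic_cube <- function(organ_specs, camera, forward,
                                    height = 24, width = 24, noise_sd = 0.005,
                                    seed = 1L, subject_id = "synthetic-1",
                                    timepoint = 1, phase = "baseline",
                                    fine_wavelengths = camera$fine_grid) {
  stopifnot(noise_sd >= 0, length(organ_specs) >= 1)
  n_org <- length(organ_specs)
  organ_names <- names(organ_specs)
  if (is.null(organ_names)) organ_names <- paste0("organ", seq_len(n_org))
  # vertical stripes of (nearly) equal width
  stripe <- rep(seq_len(n_org), each = ceiling(width / n_org))[seq_len(width)]
  label_map <- matrix(stripe, height, width, byrow = TRUE)

  n_pix <- height * width
  bands <- length(camera$band_centers)
  image <- array(0, dim = c(height, width, bands))
  sto2_truth <- matrix(0, height, width)

  for (oi in seq_len(n_org)) {
    os <- organ_specs[[oi]]
    sel <- which(label_map == oi)
    n_sel <- length(sel)
    space <- os$space
    # pin the organ's oxygenation: override the stO2 bounds with a point mass
    for (l in seq_along(space$layers)) {
      space$layers[[l]]$sto2 <- list(min = os$sto2, max = os$sto2,
                                     scale = "linear")
    }
    phys <- sample_physiology(space, n_sel, seed = seed + 1000L * oi)
    fine <- forward(phys, fine_wavelengths)
    adapted <- adapt_matrix_to_camera(fine, fine_wavelengths, camera)
    set.seed(seed + 7000L + oi)
    if (noise_sd > 0) {
      adapted <- adapted + matrix(stats::rnorm(length(adapted), sd = noise_sd),
                                  nrow(adapted), ncol(adapted))
      # matrix first: pmin/pmax take attributes from their first argument
      adapted <- pmax(pmin(adapted, 1), 0)
    }
    for (j in seq_len(n_sel)) {
      idx <- arrayInd(sel[j], c(height, width))
      image[idx[1], idx[2], ] <- adapted[j, ]
      sto2_truth[idx[1], idx[2]] <- os$sto2
    }
  }
  hsi_cube(image, label_map, organ_names, subject_id, timepoint, phase,
           camera$band_centers, sto2_truth = sto2_truth)
}

#' Surrogate forward model
#'
#' Wraps a trained surrogate as a forward model
#' `(phys_list, wavelengths) -> reflectance matrix` for cube generation and
#' library construction: physiology is converted to physical parameters at
#' every wavelength and pushed through the network in one batch.
#'
#' @param model a [surrogate_fit()] model.
#' @param table a [chromophore_table()].
#' @return A forward-model function.
#' @export
surrogate_forward <- function(model, table) {
  force(model); force(table)
  function(phys_list, wavelengths) {
    n <- length(phys_list)
    nl <- length(wavelengths)
    lam <- rep(wavelengths, times = n)
    cols <- rep(seq_len(n), each = nl)
    params <- physical_parameter_matrix(phys_list[cols], lam, table)
    matrix(predict(model, params), n, nl, byrow = TRUE)
  }
}

#' Monte Carlo forward model
#'
#' Forward model rendering spectra with the Monte Carlo engine (one
#' simulation per column and wavelength). Accurate but slow; intended for
#' small validation sets.
#'
#' @param table a [chromophore_table()].
#' @param n_photons photons per simulation.
#' @param seed integer seed.
#' @return A forward-model function.
#' @export
mc_forward <- function(table, n_photons, seed = 1L) {
  force(table); force(n_photons); force(seed)
  function(phys_list, wavelengths) {
    t(vapply(seq_along(phys_list), function(i) {
      simulate_spectrum(phys_list[[i]], wavelengths, table, n_photons,
                        seed = seed + i)$values
    }, numeric(length(wavelengths))))
  }
}

#' Build a surrogate spectrum library
#'
#' Samples physiology by Latin hypercube, renders fine-grid spectra with the
#' forward model, adapts them to the camera and returns a
#' [spectrum_library()] keyed by each column's (shared) stO2.
#'
#' @param space a [parameter_space()] with `constant_sto2 = TRUE`.
#' @param n library size.
#' @param camera a [camera_model()].
#' @param forward forward-model function.
#' @param seed integer seed.
#' @param fine_wavelengths rendering grid (nm).
#' @param provenance label stored in the library.
#' @return A [spectrum_library()].
#' @export
build_library <- function(space, n, camera, forward, seed = 1L,
                          fine_wavelengths = camera$fine_grid,
                          provenance = "surrogate") {
  phys <- sample_physiology(space, n, seed)
  fine <- forward(phys, fine_wavelengths)
  adapted <- adapt_matrix_to_camera(fine, fine_wavelengths, camera)
  sto2 <- vapply(phys, function(p) p[[1]]$sto2, numeric(1))
  spectrum_library(adapted, sto2, camera$band_centers,
                   provenance = provenance)
}
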