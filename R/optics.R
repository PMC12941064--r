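#' Physiological layer parameters
#'
#' One tissue layer described physiologically: blood volume fraction, oxygen
#' saturation, Mie-type reduced-scattering amplitude and power, anisotropy,
#' refractive index, and thickness.
#'
#' @param vhb blood volume fraction in \[0, 1\].
#' @param sto2 hemoglobin oxygen saturation in \[0, 1\].
#' @param a_mie reduced scattering amplitude at the reference wavelength
#'   (cm^-1), >= 0.
#' @param b_mie scattering power (dimensionless).
#' @param g scattering anisotropy, |g| < 1.
#' @param n refractive index, > 1.
#' @param d layer thickness (cm), > 0.
#' @return An object of class `layer_physiology`.
#' @export
layer_physiology <- function(vhb, sto2, a_mie, b_mie, g, n, d) {
  stopifnot(vhb >= 0, vhb <= 1, sto2 >= 0, sto2 <= 1, a_mie >= 0,
            abs(g) < 1, n > 1, d > 0)
  structure(list(vhb = vhb, sto2 = sto2, a_mie = a_mie, b_mie = b_mie,
                 g = g, n = n, d = d),
            class = "layer_physiology")
}

#' Hemoglobin absorption coefficient
#'
#' Computes the absorption coefficient of blood-perfused tissue with hemoglobin
#' as the sole chromophore:
#' \deqn{\mu_a = v_{hb} \ln(10) \frac{c_{hb}}{M_{hb}}
#'   [stO_2\,\varepsilon_{HbO_2}(\lambda) + (1-stO_2)\,\varepsilon_{Hb}(\lambda)]}
#' with whole-blood hemoglobin concentration `c_hb` = 150 g/L and molar mass
#' `M_hb` = 64500 g/mol. Extinctions are interpolated linearly inside the
#' table; wavelengths outside it are an error.
#'
#' @param lambda_nm wavelength (nm), scalar or vector.
#' @param vhb blood volume fraction in \[0, 1\].
#' @param sto2 oxygen saturation in \[0, 1\].
#' @param table a [chromophore_table()].
#' @param c_hb hemoglobin concentration in whole blood (g/L).
#' @param M_hb hemoglobin molar mass (g/mol).
#' @return Absorption coefficient mu_a (cm^-1), same length as `lambda_nm`.
#' @export
hemoglobin_absorption <- function(lambda_nm, vhb, sto2, table,
                                  c_hb = 150, M_hb = 64500) {
  stopifnot(all(vhb >= 0 & vhb <= 1), all(sto2 >= 0 & sto2 <= 1))
  eps <- interp_extinction(table, lambda_nm)
  vhb * log(10) * (c_hb / M_hb) *
    (sto2 * eps$eps_hbo2 + (1 - sto2) * eps$eps_hb)
}

#' Mie-type scattering coefficient
#'
#' Reduced scattering follows a power law in wavelength,
#' \deqn{\mu_s'(\lambda) = a_{mie} (\lambda / \lambda_{ref})^{-b_{mie}},}
#' anchored at `lambda_ref` = 500 nm; the (unreduced) scattering coefficient is
#' \eqn{\mu_s = \mu_s' / (1 - g)}.
#'
#' @param lambda_nm wavelength (nm), scalar or vector.
#' @param a_mie reduced scattering amplitude at `lambda_ref` (cm^-1), >= 0.
#' @param b_mie scattering power.
#' @param g anisotropy, |g| < 1 (g = 1 is a division by zero and an error).
#' @param lambda_ref reference wavelength (nm).
#' @return Scattering coefficient mu_s (cm^-1).
#' @export
mie_scattering <- function(lambda_nm, a_mie, b_mie, g, lambda_ref = 500) {
  stopifnot(all(a_mie >= 0))
  if (any(g >= 1)) stop("anisotropy g = 1 makes mu_s = mu_s'/(1-g) undefined")
  musp <- a_mie * (lambda_nm / lambda_ref)^(-b_mie)
  musp / (1 - g)
}

#' Tissue column of physical optical properties
#'
#' An ordered top-to-bottom stack of layers, each with wavelength-specific
#' absorption and scattering coefficients, anisotropy, refractive index and
#' thickness, plus the refractive index of the ambient medium above the tissue.
#'
#' @param layers list of lists/data rows with fields `mu_a`, `mu_s`, `g`, `n`,
#'   `d`.
#' @param ambient_n refractive index above (and below) the tissue.
#' @return An object of class `tissue_column`.
#' @export
tissue_column <- function(layers, ambient_n = 1.0) {
  stopifnot(length(layers) >= 1)
  for (ly in layers) {
    stopifnot(is.finite(ly$mu_a), is.finite(ly$mu_s), ly$mu_a >= 0,
              ly$mu_s >= 0, ly$d > 0, ly$n >= 1, abs(ly$g) <= 1)
  }
  structure(list(layers = layers, ambient_n = ambient_n),
            class = "tissue_column")
}

#' @export
print.tissue_column <- function(x, ...) {
  cat(sprintf("Tissue column: %d layer(s), ambient n = %g\n",
              length(x$layers), x$ambient_n))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    cat(sprintf("  [%d] mu_a=%.4g mu_s=%.4g g=%.3g n=%.3g d=%.4g cm\n",
                i, ly$mu_a, ly$mu_s, ly$g, ly$n, ly$d))
  }
  invisible(x)
}

#' Convert physiology to physical optical properties
#'
#' Maps per-layer physiological parameters to the five physical parameters per
#' layer at one wavelength: mu_a via [hemoglobin_absorption()], mu_s via
#' [mie_scattering()]; anisotropy, refractive index and thickness are copied
#' through.
#'
#' @param phys list of [layer_physiology()] objects, top to bottom.
#' @param lambda_nm wavelength (nm), scalar.
#' @param table a [chromophore_table()].
#' @param ambient_n ambient refractive index.
#' @return A [tissue_column()].
#' @export
physical_properties <- function(phys, lambda_nm, table, ambient_n = 1.0) {
  if (inherits(phys, "layer_physiology")) phys <- list(phys)
  layers <- lapply(phys, function(p) {
    list(
      mu_a = hemoglobin_absorption(lambda_nm, p$vhb, p$sto2, table),
      mu_s = mie_scattering(lambda_nm, p$a_mie, p$b_mie, p$g),
      g = p$g, n = p$n, d = p$d
    )
  })
  tissue_column(layers, ambient_n = ambient_n)
}

#' Physiological parameter space
#'
#' Per-layer sampling bounds for every physiological parameter, with a linear
#' or decadic-log sampling scale per dimension. The bottom layer can be flagged
#' semi-infinite, fixing its thickness at 20 cm; with `constant_sto2 = TRUE`
#' one arterial saturation value drawn per column sets the stO2 of all layers.
#'
#' @param layers list of per-layer bound lists; each bound is
#'   `c(min, max)` or `list(min =, max =, scale = "linear"|"log10")` for the
#'   fields `vhb`, `sto2`, `a_mie`, `b_mie`, `g`, `n`, `d`.
#' @param wavelengths wavelength grid (nm) associated with the space.
#' @param constant_sto2 draw one shared stO2 per column (the three-layer
#'   epithelial model convention).
#' @param semi_infinite_bottom fix the bottom layer thickness at
#'   `bottom_thickness_cm`.
#' @param bottom_thickness_cm thickness used for the semi-infinite bottom
#'   layer (cm).
#' @return An object of class `parameter_space`.
#' @export
parameter_space <- function(layers, wavelengths = seq(500, 1000, length.out = 15),
                            constant_sto2 = TRUE, semi_infinite_bottom = TRUE,
                            bottom_thickness_cm = 20) {
  norm_bound <- function(b, name) {
    if (is.numeric(b) && length(b) == 2) {
      b <- list(min = b[1], max = b[2], scale = "linear")
    }
    if (is.null(b$scale)) b$scale <- "linear"
    if (!(b$scale %in% c("linear", "log10"))) {
      stop("unknown sampling scale for ", name, ": ", b$scale)
    }
    if (b$min > b$max) stop("invalid bounds for ", name, ": min > max")
    if (b$scale == "log10" && b$min <= 0) {
      stop("log10 scale requires min > 0 for ", name)
    }
    b
  }
  fields <- c("vhb", "sto2", "a_mie", "b_mie", "g", "n", "d")
  layers <- lapply(layers, function(ly) {
    missing <- setdiff(fields, names(ly))
    if (length(missing)) {
      stop("layer bounds missing fields: ", paste(missing, collapse = ", "))
    }
    stats::setNames(lapply(fields, function(f) norm_bound(ly[[f]], f)), fields)
  })
  structure(list(layers = layers, wavelengths = as.numeric(wavelengths),
                 constant_sto2 = isTRUE(constant_sto2),
                 semi_infinite_bottom = isTRUE(semi_infinite_bottom),
                 bottom_thickness_cm = bottom_thickness_cm),
            class = "parameter_space")
}

#' Default three-layer physiological parameter space
#'
#' Configurable stand-in ranges spanning published tissue-optics values:
#' vhb in \[0.001, 0.30\] (log10), stO2 in \[0, 1\], a_mie in \[5, 50\] cm^-1,
#' b_mie in \[0.3, 3\], g in \[0.80, 0.95\], n in \[1.33, 1.54\], thicknesses of
#' the two upper layers in \[0.002, 0.1\] cm (log10), bottom layer
#' semi-infinite (20 cm).
#'
#' @param n_layers number of layers (>= 1).
#' @param wavelengths wavelength grid (nm).
#' @return A [parameter_space()].
#' @export
default_parameter_space <- function(n_layers = 3,
                                    wavelengths = seq(500, 1000, length.out = 15)) {
  one <- list(
    vhb = list(min = 0.001, max = 0.30, scale = "log10"),
    sto2 = c(0, 1),
    a_mie = c(5, 50),
    b_mie = c(0.3, 3),
    g = c(0.80, 0.95),
    n = c(1.33, 1.54),
    d = list(min = 0.002, max = 0.1, scale = "log10")
  )
  parameter_space(rep(list(one), n_layers), wavelengths = wavelengths)
}

# Enumerate the free scalar dimensions of a space, honouring the shared-stO2
# flag and the fixed bottom thickness. Returns a data.frame of
# (layer, field, min, max, scale); layer = 0 marks the shared stO2 dimension.
space_dimensions <- function(space) {
  L <- length(space$layers)
  dims <- list()
  if (space$constant_sto2) {
    b <- space$layers[[1]]$sto2
    dims[[length(dims) + 1L]] <- data.frame(
      layer = 0L, field = "sto2", min = b$min, max = b$max, scale = b$scale)
  }
  for (i in seq_len(L)) {
    for (f in c("vhb", "sto2", "a_mie", "b_mie", "g", "n", "d")) {
      if (f == "sto2" && space$constant_sto2) next
      if (f == "d" && i == L && space$semi_infinite_bottom) next
      b <- space$layers[[i]][[f]]
      dims[[length(dims) + 1L]] <- data.frame(
        layer = i, field = f, min = b$min, max = b$max, scale = b$scale)
    }
  }
  do.call(rbind, dims)
}

#' Latin hypercube sampling of physiological parameter sets
#'
#' Draws `n` tissue columns by Latin hypercube sampling over every free scalar
#' dimension of the space on its declared scale (linear or decadic log): the
#' `n` samples of each dimension occupy the `n` equal-probability strata
#' exactly once. Degenerate dimensions (min == max) are held constant.
#'
#' @param space a [parameter_space()].
#' @param n number of columns to draw (>= 1).
#' @param seed integer seed; same seed, same samples.
#' @return A list of `n` elements, each a list of [layer_physiology()] objects.
#' @export
sample_physiology <- function(space, n, seed) {
  stopifnot(inherits(space, "parameter_space"), n >= 1)
  dims <- space_dimensions(space)
  k <- nrow(dims)
  set.seed(seed)
  U <- lhs::randomLHS(n, k)
  L <- length(space$layers)
  out <- vector("list", n)
  vals <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lo <- dims$min[j]; hi <- dims$max[j]
    if (dims$scale[j] == "log10") {
      vals[, j] <- 10^(log10(lo) + U[, j] * (log10(hi) - log10(lo)))
    } else {
      vals[, j] <- lo + U[, j] * (hi - lo)
    }
  }
  for (i in seq_len(n)) {
    col_layers <- vector("list", L)
    shared_sto2 <- NA_real_
    for (j in seq_len(k)) {
      if (dims$layer[j] == 0L) shared_sto2 <- vals[i, j]
    }
    for (ly in seq_len(L)) {
      p <- list()
      for (j in seq_len(k)) {
        if (dims$layer[j] == ly) p[[dims$field[j]]] <- vals[i, j]
      }
      if (space$constant_sto2) p$sto2 <- shared_sto2
      if (is.null(p$d)) p$d <- space$bottom_thickness_cm
      col_layers[[ly]] <- layer_physiology(p$vhb, p$sto2, p$a_mie, p$b_mie,
                                           p$g, p$n, p$d)
    }
    out[[i]] <- col_layers
  }
  out
}
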