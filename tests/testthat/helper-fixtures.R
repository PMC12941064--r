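# Shared fixtures. Everything is generated in code; the only file fixture is
# the package's own synthetic extinction table.

# Small chromophore table with affine extinction curves so expected values of
# interpolation-based quantities can be computed by hand.
toy_table <- function() {
  lam <- seq(500, 700, by = 20)
  chromophore_table(lam, eps_hbo2 = 100 + 2 * (lam - 500),
                    eps_hb = 400 - 0.5 * (lam - 500))
}

# Single-layer parameter space with narrow, cheap-to-simulate optics.
tiny_space <- function(wavelengths = c(520, 560, 600)) {
  parameter_space(
    list(list(vhb = c(0.01, 0.1), sto2 = c(0, 1), a_mie = c(5, 15),
              b_mie = c(0.5, 1.5), g = c(0.6, 0.8), n = c(1.33, 1.4),
              d = c(0.5, 0.5))),
    wavelengths = wavelengths, constant_sto2 = TRUE,
    semi_infinite_bottom = TRUE
  )
}

# --- scaled study conditions shared by the acceptance tests ------------------
# Desk-scale stand-ins for the full-corpus protocol; the same values are used
# by scripts/acceptance.R. See the methods vignette for the rationale.
ACC <- list(
  n_spectra = 4000,        # single-wavelength parameter sets
  n_photons = 2000,        # photons per simulation
  seed = 101,
  hidden = c(128L, 128L, 128L),
  fractions = c(0.04, 0.08, 0.15, 0.3, 0.55, 1.0),
  library_size = 10000,
  cube_side = 24,
  noise_sd = 0.005
)

acc_control <- function(seed = ACC$seed, max_epochs = 1500) {
  surrogate_control(learning_rate = 2e-3, weight_decay = 0.001,
                    batch_size = 128, patience = 80, max_epochs = max_epochs,
                    seed = seed)
}

# Heavy shared objects are built lazily once per test run.
.acc_cache <- new.env(parent = emptyenv())

acc_get <- function(name, build) {
  if (!exists(name, envir = .acc_cache)) {
    assign(name, build(), envir = .acc_cache)
  }
  get(name, envir = .acc_cache)
}

acc_table <- function() acc_get("table", default_chromophore_table)
acc_space <- function() acc_get("space", default_parameter_space)

acc_dataset <- function() acc_get("dataset", function() {
  phys <- sample_physiology(acc_space(), ACC$n_spectra, seed = ACC$seed)
  simulate_dataset(phys, acc_space()$wavelengths, acc_table(),
                   n_photons = ACC$n_photons, seed = ACC$seed,
                   per_sample_wavelength = TRUE)
})

acc_split <- function() acc_get("split", function() {
  split_spectra(acc_dataset()$spectrum_id, seed = ACC$seed)
})

acc_model <- function() acc_get("model", function() {
  ds <- acc_dataset(); sp <- acc_split()
  surrogate_fit(ds$params[sp$train, ], ds$reflectance[sp$train],
                validation = list(x = ds$params[sp$validation, ],
                                  y = ds$reflectance[sp$validation]),
                spec = surrogate_spec(ncol(ds$params), hidden = ACC$hidden),
                control = acc_control())
})

acc_library <- function() acc_get("library", function() {
  build_library(acc_space(), ACC$library_size, default_camera(fine_step = 5),
                surrogate_forward(acc_model(), acc_table()),
                seed = ACC$seed + 1)
})
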