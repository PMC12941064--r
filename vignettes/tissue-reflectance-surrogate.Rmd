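---
title: "Simulating and emulating tissue diffuse reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and emulating tissue diffuse reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`reflectsim` models how light diffuses through layered biological tissue and
how much of it re-emerges from the surface — the diffuse reflectance spectrum
that a hyperspectral camera observes during surgery. The package chains five
stages: a physiological tissue model, a multilayer Monte Carlo (MC) photon
transport engine, a neural surrogate that replaces the engine at a fraction of
its cost, statistical tooling around both (error models, data-scaling laws,
realism metrics), and a nearest-neighbour estimator of tissue oxygenation
(stO2) on labelled hyperspectral cubes.

## The tissue model

A tissue column is an ordered stack of laterally infinite layers. Each layer
is described physiologically by seven parameters: blood volume fraction
`vhb` (–), oxygen saturation `sto2` (–), reduced-scattering amplitude `a_mie`
(cm⁻¹ at 500 nm), scattering power `b_mie` (–), scattering anisotropy `g` (–),
refractive index `n` (–), and thickness `d` (cm). At a wavelength λ these map
to the five physical parameters the transport engine consumes:

* absorption, with hemoglobin as the sole chromophore,
  μa = vhb · ln 10 · (c_hb / M_hb) · [stO2 · εHbO2(λ) + (1 − stO2) · εHb(λ)],
  with whole-blood hemoglobin concentration c_hb = 150 g/L and molar mass
  M_hb = 64 500 g/mol — the de-facto convention in tissue optics;
* scattering, via the Mie-type power law μs′(λ) = a_mie (λ/500 nm)^(−b_mie)
  and μs = μs′/(1 − g);
* `g`, `n`, `d` copied through.

The canonical configuration is the three-layer epithelial model: one arterial
saturation drawn per column sets the stO2 of all layers (`constant_sto2`),
and the bottom layer is 20 cm thick, approximating a semi-infinite medium so
no photon escapes through the base.

The extinction tables ship as CSV
(`inst/extdata/hemoglobin_extinction_synthetic.csv`). This table is a
**synthetic** smooth stand-in built from parametric peaks that reproduce the
canonical features of hemoglobin spectra (Q-bands at 542/577 nm for HbO2,
555 nm for Hb, the steep fall-off above 600 nm, the deoxy shoulder near
760 nm, the near-infrared crossover around 800 nm). It is not a measured
compilation; any measured table with the same three-column layout can be
dropped in via `read_chromophore_table()`.

Parameter spaces are sampled by Latin hypercube (`sample_physiology()`): each
free dimension is stratified into n equal-probability bins on its declared
scale (linear or decadic log), so even small designs cover the space evenly.
The default three-layer space — vhb ∈ [0.001, 0.30] (log), stO2 ∈ [0, 1],
a_mie ∈ [5, 50] cm⁻¹, b_mie ∈ [0.3, 3], g ∈ [0.80, 0.95], n ∈ [1.33, 1.54],
upper-layer thicknesses ∈ [0.002, 0.1] cm (log) — spans published
tissue-optics ranges; every bound is a configuration field.

## The Monte Carlo engine

`simulate_reflectance()` implements the standard weighted (implicit-capture)
multilayer walk: pencil-beam photons enter at normal incidence; the specular
fraction ((n0 − n1)/(n0 + n1))² is removed at entry and reported separately;
step lengths are s = −ln ξ/μt; at each interaction the packet deposits
W·μa/μt and deflects by a Henyey-Greenstein cosine (analytic inverse CDF);
every interface applies unpolarized Fresnel reflection/refraction, with total
internal reflection beyond the critical angle; packets below a weight
threshold play Russian roulette (survive with probability 1/m, weight × m,
unbiased). Diffuse reflectance is the summed weight escaping the top surface
divided by the launched count.

Numerical choices worth knowing:

* **Counter-based streams.** Every photon owns a splitmix64 stream keyed by
  (seed, substream, photon index), so results are bit-reproducible and
  independent of batching or evaluation order. Wavelengths of one spectrum
  use distinct substreams derived from one seed.
* **Boundary crossings resample the step.** Because the exponential
  distribution is memoryless, redrawing a full step in the new medium is
  statistically identical to carrying the dimensionless remainder.
* **Roulette defaults.** Single simulations default to threshold 1e-4 with
  m = 10 (common MCML practice). Bulk dataset generation
  (`simulate_dataset()`) defaults to threshold 0.05: a low threshold makes
  low-albedo packets take ~ln(1/θ)·μt/μa steps before termination, which is
  an order of magnitude more work than an analog walk for an imperceptible
  variance benefit in aggregate statistics. Both settings are unbiased.
* **Glass-like layers** (μt = 0) are traversed ballistically with Fresnel
  events only; a packet travelling exactly parallel inside one is terminated
  into the absorbed tally (measure-zero event).
* **Energy bookkeeping.** specular + diffuse + transmitted + absorbed = 1
  within 1e-3 per run; roulette adds variance but no bias.

The engine is validated against the published semi-infinite isotropic slab
values: albedo 0.9 with a matched boundary gives 0.415, and with a
tissue-like relative index of 1.37 gives 0.2600, both reproduced within
three standard deviations of the binomial error model. A deliberately
simple analog oracle (exponential steps, survival probability = albedo,
isotropic cosines) is kept in the test suite as an independent
cross-implementation.

## The binomial error model

Treating each photon as a Bernoulli trial (returns through the top surface or
not), the maximum-likelihood reflectance is r̂ = Nreturned/Ntotal, the
count-scale standard deviation is σ̂ = √(N·r̂·(1−r̂)), and the coefficient of
variation is CoV = √((1−r̂)/(N·r̂)). The CoV is computed as σ̂/(N·r̂) so the
identity CoV·N·r̂ = σ̂ holds to machine precision. Prediction intervals use
the normal approximation r̂ ± z·σ̂/N clipped to [0, 1] (photon counts are
large enough that the approximation is excellent); an exact Clopper–Pearson
interval is available behind `exact = TRUE`. Weighted transport with roulette
is not exactly Bernoulli, so the model is used as a floor/calibration device:
the empirical spread of repeated simulations agrees with it within a factor
of two, which the tests assert.

## The neural surrogate

`surrogate_fit()` trains a fully connected regressor from the flattened
per-layer physical parameters (5 per layer; wavelength itself is *not* an
input — all wavelength dependence lives in μa and μs) to one diffuse
reflectance value. The reference architecture is five hidden layers of 512
units, leaky-ReLU slope 0.2, a single sigmoid output unit (predictions are
confined to (0, 1) by construction), Kaiming-normal initial weights and zero
biases — 1 059 329 trainable parameters at 15 inputs.

Preprocessing: μa, μs and d are decadic-log transformed (wide dynamic
ranges), then all features are z-scored with statistics computed from the
training split only; reflectance targets are used raw (naturally bounded).
A layer held constant across the corpus — the 20 cm semi-infinite bottom
thickness — has zero variance, so `fit_normalization()` errors by default
and offers `constant = "center"`, which centres the feature and leaves unit
scale; the canonical pipeline needs this.

Training: mean-squared-error loss, AdamW (first-order adaptive optimizer
with decoupled weight decay — the package's optimizer default; the
approximate-second-order alternative is a possible plug-in, not shipped),
learning rate 1e-4, weight decay 0.001, halve-on-plateau scheduling down to
1e-8, 32-bit floats, no dropout or batch normalization, and the final-epoch
checkpoint is returned. The scheduler patience defaults to 20 epochs for
pools of ≥1e5 spectra and 50 otherwise, with total epochs 25 × patience
(floor 500).

A practical note the tests exposed: with very small datasets an epoch is only
a handful of optimizer steps, so epoch-denominated patience can collapse the
learning rate before the weights have moved far enough, freezing training at
a spurious floor. Small-data configurations should raise the patience (and
learning rate) rather than the epoch count alone; the desk-scale runs below
use lr 2e-3, batch 128, patience 80, 1500 epochs.

Splits are made at the spectrum level (`split_spectra()`): all wavelengths of
one parameter set land in the same partition (70/10/20), preventing leakage
across wavelengths of the same spectrum.

## Data-scaling experiments

`run_scaling_experiment()` retrains the surrogate on nested subsets of the
training pool — `subsample_training()` ranks spectra once per seed, so the
subset at a smaller fraction is always contained in larger ones; validation
and test splits stay fixed — and `fit_power_law()` fits

error(N) = a·N^b + c

by least squares of log10(model) against log10(observed MAE), using bounded
Levenberg–Marquardt (minpack.lm) with bounds [0, −5, 0] to [∞, 5, 1e-2].
Fitting in log space equalizes relative error across decades; `N` counts
training rows (spectra × wavelengths). Subset sizes floor to whole spectra
with a minimum of one. Parameter standard deviations come from the fit
covariance.

## Realism metrics

`spectral_recall()` measures manifold coverage: the fraction of reference
spectra with at least one candidate spectrum strictly within d_max = 0.02
under the per-wavelength MAE distance (ties at exactly d_max are misses).
Nearest-neighbour search is exact; the compiled path is tested for bit
equality against a double loop. `hierarchical_recall()` aggregates the binary
decision per spectrum → per (subject, class) → across subjects, so large
subjects do not dominate; subjects lacking a class are skipped, not
zero-filled. `select_threshold()` scans a grid (default 50 log-spaced points
on [1e-3, 1e-1]), takes each candidate model's point of steepest recall
increase (maximal forward difference) and returns the lowest across models.
`pca_realism()` fits principal components to image-level class-averaged
reference spectra and projects candidates with the frozen loadings; the
bounding-box coverage number it reports is descriptive, not a test statistic.

## Camera adaptation and stO2 estimation

`camera_model()` holds band responses and source irradiance on a fine
wavelength grid; `adapt_to_camera()` computes irradiance-weighted band
averages, so a spectrally flat reflectance is preserved exactly and the map
is linear. The default camera has 100 Gaussian bands, centers 500–995 nm in
5 nm steps, 5 nm FWHM (the inclusive 1000 nm endpoint is dropped to keep 100
bands on a 5 nm pitch), flat irradiance; the fine grid is padded by 10 nm so
its points sit symmetrically around every band center, keeping symmetric
kernels unbiased on locally linear spectra.

`estimate_sto2()` assigns each pixel the stO2 of its exactly nearest library
spectrum under spectral MAE, discarding matches with distance above 0.02;
ties break to the lowest library index. Pixel spectra are matched as raw band
reflectances (no ℓ1 or other normalization) — the choice is isolated behind
the distance function. `build_trajectories()` averages accepted estimates per
(subject, organ, timepoint) and reports the accepted fraction.

`generate_synthetic_cube()` stands in for in vivo acquisitions that are not
publicly available: organs tile the image as stripes, each pixel draws
physiology from its organ's parameter space at the organ's stO2, renders a
spectrum through a forward model (MC or surrogate), adapts it to the camera
and adds independent Gaussian band noise (default sd 0.005, clipped to
[0, 1]; an additive model — shot-noise-like scaling is a straightforward
extension). The generating stO2 is stored as hidden ground truth. What
passing closed-loop tests show is that the estimator inverts *its own
forward model* under noise; they cannot show robustness to real-tissue
effects the generator does not emulate — specular highlights, spatially
correlated noise, chromophores beyond hemoglobin, partial-volume mixtures at
organ boundaries, or camera miscalibration.

## Desk-scale study conditions

The full-scale protocol (millions of Latin-hypercube spectra at 1e5–1e8
photons, a 5×512 network, nine subsample fractions, 1e5-spectrum libraries)
is far beyond a single CPU. The package's test suite and acceptance script
run a scaled-down version chosen once as a realistic miniature:

* 4000 single-wavelength parameter sets at 2000 photons (15-wavelength grid
  on [500, 1000] nm, evenly spaced);
* a 3×128 surrogate (the architecture is a configuration object; the 5×512
  reference spec is the default elsewhere), AdamW at lr 2e-3, batch 128,
  patience 80, 1500 epochs — one fixed protocol across all training-set
  sizes, so the smallest subsets are mildly optimization-limited;
* six nested fractions (4–100%) for the scaling law;
* a 10 000-spectrum surrogate library, 24×24-pixel cubes, three organs at
  stO2 {0.2, 0.5, 0.8} permuted across a baseline/ischemia/reperfusion
  sequence, band noise sd 0.005; library and cube spectra are rendered on a
  5 nm fine grid (the camera's own band pitch) — the adaptation step
  normalizes per band, so the coarser quadrature does not bias it, and
  library and pixels share the same discretization.

At 2000 photons the binomial floor (σ ≈ 0.01 on the reflectance scale) keeps
the irreducible term inside the power-law fit's stated c bound while leaving
the noise clearly dominant at the largest training sizes, which is the regime
the scaling law describes.

## Known limitations

* Hemoglobin is the only implemented chromophore (the table type admits more
  columns, but nothing generates them); g and n are wavelength-independent.
* The transport engine tallies total diffuse reflectance only — no radial or
  angular resolution, fluence maps, or time of flight.
* The Bernoulli error model treats weighted-with-roulette transport as
  analog; it is a calibrated approximation, not an exact variance model.
* The similarity relation (equal μs′ ⇒ equal reflectance) is asymptotic in
  the albedo: it holds to ~2% at μa/μs′ ≈ 0.02 but degrades past 5% for
  strongly absorbing media — a property of the physics, not an engine
  artifact.
* Recall, PCA coverage and the stO2 estimator inherit the spectral-MAE
  metric's insensitivity to which wavelengths disagree.
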