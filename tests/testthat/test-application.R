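nn_brute <- function(pixels, lib) {
  t(apply(pixels, 1, function(p) {
    d <- apply(lib, 1, function(s) mean(abs(p - s)))
    c(which.min(d), min(d))
  }))
}

test_that("camera adaptation preserves constants and is linear", {
  cam <- default_camera()
  expect_length(cam$band_centers, 100)
  expect_equal(cam$band_centers[1], 500)
  expect_equal(cam$band_centers[100], 995)
  fine <- cam$fine_grid
  flat <- rep(0.3, length(fine))
  expect_equal(adapt_to_camera(flat, fine, cam), rep(0.3, 100))
  # linearity: adapt(a x + b y) = a adapt(x) + b adapt(y)
  set.seed(31)
  x <- runif(length(fine)); y <- runif(length(fine))
  lhs_comb <- adapt_to_camera(0.3 * x + 0.5 * y, fine, cam)
  rhs_comb <- 0.3 * adapt_to_camera(x, fine, cam) +
    0.5 * adapt_to_camera(y, fine, cam)
  expect_equal(lhs_comb, rhs_comb, tolerance = 1e-12)
  # Gaussian bands on a linear-in-wavelength spectrum return band centers
  lin <- 0.1 + 0.0005 * (fine - 500)
  adapted <- adapt_to_camera(lin, fine, cam)
  expected <- 0.1 + 0.0005 * (cam$band_centers - 500)
  expect_equal(adapted, expected, tolerance = 1e-6)
  expect_error(adapt_to_camera(rep(0.3, 10), seq(600, 700, length.out = 10),
                               cam), "cover")
})

test_that("delta-like response rows act as pure resampling", {
  fine <- seq(500, 600, by = 10)
  resp <- diag(length(fine))[c(2, 5, 8), ]
  cam <- camera_model(fine[c(2, 5, 8)], fine, resp)
  s <- runif(length(fine))
  expect_equal(adapt_to_camera(s, fine, cam), s[c(2, 5, 8)])
})

test_that("matrix adaptation equals per-spectrum adaptation", {
  cam <- default_camera(fine_step = 5)
  fine <- cam$fine_grid
  set.seed(32)
  m <- matrix(runif(3 * length(fine)), 3)
  batch <- reflectsim:::adapt_matrix_to_camera(m, fine, cam)
  for (i in 1:3) {
    expect_equal(batch[i, ], adapt_to_camera(m[i, ], fine, cam))
  }
})

test_that("stO2 lookup is exact nearest neighbour with rejection", {
  set.seed(33)
  lib_m <- matrix(runif(200 * 12, 0.2, 0.8), 200, 12)
  lib <- spectrum_library(lib_m, runif(200), band_centers = 1:12)
  # a pixel equal to a library member returns that member exactly
  est <- estimate_sto2(lib_m[37, ], lib, d_max = 0.02)
  expect_equal(est$index, 37)
  expect_equal(est$distance, 0)
  expect_equal(est$sto2, lib$sto2[37])
  # far pixels are rejected
  est_far <- estimate_sto2(rep(5, 12), lib, d_max = 0.02)
  expect_true(is.na(est_far$sto2))
  # exact agreement with the brute-force double loop
  pixels <- matrix(runif(150 * 12, 0.2, 0.8), 150, 12)
  est_all <- estimate_sto2(pixels, lib, d_max = 1)
  ref <- nn_brute(pixels, lib_m)
  expect_equal(est_all$index, as.integer(ref[, 1]))
  expect_equal(est_all$distance, ref[, 2])
  # deterministic tie-break to the lowest index
  lib2 <- spectrum_library(rbind(lib_m[1, ], lib_m), runif(201), 1:12)
  est_tie <- estimate_sto2(lib_m[1, ], lib2, 0.02)
  expect_equal(est_tie$index, 1)
  expect_error(estimate_sto2(pixels[, 1:5], lib), "band grids")
})

test_that("raising d_max never lowers the valid-pixel fraction", {
  set.seed(34)
  lib <- spectrum_library(matrix(runif(100 * 8), 100, 8), runif(100), 1:8)
  pixels <- matrix(runif(60 * 8), 60, 8)
  fracs <- sapply(c(0.01, 0.05, 0.1, 0.5), function(d) {
    mean(!is.na(estimate_sto2(pixels, lib, d)$sto2))
  })
  expect_true(all(diff(fracs) >= 0))
})

test_that("trajectories average accepted pixels per subject/organ/timepoint", {
  bands <- 6
  lib <- spectrum_library(rbind(rep(0.2, bands), rep(0.6, bands)),
                          c(0.25, 0.75), 1:bands)
  img <- array(0, dim = c(2, 2, bands))
  img[1, 1, ] <- 0.2; img[1, 2, ] <- 0.2    # organ A pixels
  img[2, 1, ] <- 0.6; img[2, 2, ] <- 5      # organ B: one accepted, one absurd
  labels <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)
  cube <- hsi_cube(img, labels, c("A", "B"), "pig1", 1, "baseline", 1:bands)
  tr <- build_trajectories(list(cube), lib, d_max = 0.02)
  a <- tr[tr$organ == "A", ]
  b <- tr[tr$organ == "B", ]
  expect_equal(a$mean_sto2, 0.25)
  expect_equal(a$valid_fraction, 1)
  expect_equal(b$mean_sto2, 0.75)
  expect_equal(b$valid_fraction, 0.5)
  # all-rejected organ: NA mean, zero valid fraction
  img2 <- img; img2[1, 1, ] <- 3; img2[1, 2, ] <- 3
  cube2 <- hsi_cube(img2, labels, c("A", "B"), "pig1", 2, "ischemia", 1:bands)
  tr2 <- build_trajectories(list(cube2), lib, d_max = 0.02)
  expect_true(is.na(tr2$mean_sto2[tr2$organ == "A"]))
  expect_equal(tr2$valid_fraction[tr2$organ == "A"], 0)
  # pixel permutation cannot change the aggregate
  imgp <- img
  imgp[1, 1, ] <- img[1, 2, ]; imgp[1, 2, ] <- img[1, 1, ]
  cubep <- hsi_cube(imgp, labels, c("A", "B"), "pig1", 1, "baseline", 1:bands)
  trp <- build_trajectories(list(cubep), lib, d_max = 0.02)
  expect_equal(trp$mean_sto2, tr$mean_sto2)
})

test_that("synthetic cubes are deterministic and degenerate cases collapse", {
  cam <- default_camera(fine_step = 10)
  tab <- toy_table()
  # point-mass physiology: identical pixels at zero noise
  space <- parameter_space(
    list(list(vhb = c(0.05, 0.05), sto2 = c(0.6, 0.6), a_mie = c(10, 10),
              b_mie = c(1, 1), g = c(0.7, 0.7), n = c(1.37, 1.37),
              d = c(0.5, 0.5))),
    wavelengths = cam$band_centers)
  # analytic stand-in forward model: cheap, smooth, deterministic
  forward <- function(phys_list, wavelengths) {
    t(vapply(phys_list, function(p) {
      mua <- hemoglobin_absorption(pmin(pmax(wavelengths, 500), 700),
                                   p[[1]]$vhb, p[[1]]$sto2, tab)
      1 / (1 + mua)
    }, numeric(length(wavelengths))))
  }
  cube <- generate_synthetic_cube(list(o = list(space = space, sto2 = 0.6)),
                                  cam, forward, height = 4, width = 4,
                                  noise_sd = 0, seed = 3)
  pix <- matrix(cube$image, 16, length(cam$band_centers))
  expect_equal(max(apply(pix, 2, function(col) diff(range(col)))), 0)
  cube2 <- generate_synthetic_cube(list(o = list(space = space, sto2 = 0.6)),
                                   cam, forward, height = 4, width = 4,
                                   noise_sd = 0, seed = 3)
  expect_identical(cube$image, cube2$image)
  expect_equal(unique(as.vector(cube$sto2_truth)), 0.6)
  # three organs tile into three stripes with their own labels
  specs <- list(a = list(space = space, sto2 = 0.2),
                b = list(space = space, sto2 = 0.5),
                c = list(space = space, sto2 = 0.8))
  cube3 <- generate_synthetic_cube(specs, cam, forward, height = 6, width = 6,
                                   noise_sd = 0.002, seed = 4)
  expect_setequal(unique(as.vector(cube3$label_map)), 1:3)
  expect_true(all(cube3$image >= 0 & cube3$image <= 1))
  expect_setequal(unique(as.vector(cube3$sto2_truth)), c(0.2, 0.5, 0.8))
})
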