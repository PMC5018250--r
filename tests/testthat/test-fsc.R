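test_that("FSC has the exact limits for identical and negated maps", {
  curve <- fsc(fx_vol48, fx_vol48)
  expect_true(all(abs(curve$fsc - 1) < 1e-10))
  neg <- density_volume(-fx_vol48$data, fx_vol48$voxel_A)
  curve_n <- fsc(fx_vol48, neg)
  expect_true(all(abs(curve_n$fsc + 1) < 1e-10))
  expect_true(all(diff(curve$freq) > 0))
  expect_lte(max(curve$freq), 0.5 / fx_vol48$voxel_A + 1e-12)
  other <- density_volume(array(0, c(32, 32, 32)), 2.5)
  expect_error(fsc(fx_vol48, other), "grid")
})

test_that("independent noise maps decorrelate as 3/sqrt(n)", {
  set.seed(11)
  a <- density_volume(array(rnorm(48^3), c(48, 48, 48)), 2)
  b <- density_volume(array(rnorm(48^3), c(48, 48, 48)), 2)
  curve <- fsc(a, b)
  frac <- mean(abs(curve$fsc) < 3 / sqrt(curve$n_vox))
  expect_gte(frac, 0.95)
  # symmetry of the correlation
  expect_equal(fsc(a, b)$fsc, fsc(b, a)$fsc, tolerance = 1e-12)
})

test_that("adding noise to one half-map monotonically lowers mean FSC", {
  set.seed(3)
  base <- fx_vol48
  means <- vapply(c(0, 0.05, 0.15, 0.4), function(s) {
    noisy <- density_volume(base$data + array(rnorm(48^3, sd = s * sd(base$data)),
                                              c(48, 48, 48)), base$voxel_A)
    mean(fsc(base, noisy)$fsc)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("threshold crossings interpolate linearly between shells", {
  curve <- data.frame(freq = c(1 / 4.0, 1 / 3.5),
                      fsc = c(0.2, 0.1), n_vox = c(100L, 120L))
  class(curve) <- c("fsc_curve", "data.frame")
  # hand interpolation: 0.143 crossing between the two shells
  f_exp <- 0.25 + (0.2 - 0.143) / (0.2 - 0.1) * (1 / 3.5 - 0.25)
  r <- resolution_at_threshold(curve, 0.143)
  expect_equal(as.numeric(r), 1 / f_exp, tolerance = 1e-12)
  expect_true(attr(r, "crossed"))
  # all-1 curve never crosses: Nyquist with a flag
  c1 <- data.frame(freq = c(0.1, 0.2, 0.25), fsc = c(1, 1, 1), n_vox = 1:3)
  class(c1) <- c("fsc_curve", "data.frame")
  r1 <- resolution_at_threshold(c1, 0.143)
  expect_equal(as.numeric(r1), 4)
  expect_false(attr(r1, "crossed"))
  # named presets and threshold validation
  expect_equal(as.numeric(resolution_at_threshold(curve, "half-map")),
               as.numeric(resolution_at_threshold(curve, 0.143)))
  expect_equal(as.numeric(resolution_at_threshold(curve, "model-map")),
               as.numeric(resolution_at_threshold(curve, 0.4)))
  expect_error(resolution_at_threshold(curve, 1.5), "threshold")
})

test_that("model rendering integrates to the total atomic number", {
  empty <- atomic_model(fx_pilin$atoms[0, ])
  expect_equal(sum(model_to_density(empty, 2, 32)$data), 0)
  v <- model_to_density(fx_pilin, 2.0, 96, bfactor = 150)
  z_sum <- sum(helifil:::atomic_number(fx_pilin$atoms$element))
  expect_equal(sum(v$data), z_sum, tolerance = 0.01)
  # identical renderings agree exactly in every shell
  curve <- fsc(v, model_to_density(fx_pilin, 2.0, 96, bfactor = 150))
  expect_true(all(abs(curve$fsc - 1) < 1e-9))
  expect_error(model_to_density(fx_pilin, 2.0, 16), "outside the box")
  bad <- fx_pilin
  bad$atoms$element[1] <- "Xx"
  expect_error(model_to_density(bad, 2, 96), "unknown element")
})

test_that("half-map and model:map resolutions of a reconstruction agree", {
  # small synthetic reconstruction from ground-truth alignments: the two
  # half-set maps carry independent noise, so the 0.143 half-map resolution
  # and the 0.4 map:model resolution must agree within one shell
  vx <- 2.5
  vol <- render_volume(fx_template, fx_sym, ceiling(64 * vx / 12.1) + 4,
                       64, vx, clip_z = TRUE)
  sigma <- noise_sigma_for_snr(vol, 0.1, acquisition_params())
  st <- phase_flip(simulate_segment_stack(vol, 120, noise_sigma = sigma,
                                          seed = 4, rise_A = 12.1))
  par <- data.frame(segment = 1:120, azimuth = st$meta$azimuth %% 360,
                    psi = st$meta$psi, sx_px = st$meta$sx_px,
                    sy_px = st$meta$sy_px, score = 1)
  ie <- seq(1, 120, 2)
  io <- seq(2, 120, 2)
  half_e <- symmetrize(backproject(st[ie], par[ie, ]), fx_sym)
  half_o <- symmetrize(backproject(st[io], par[io, ]), fx_sym)
  full <- symmetrize(backproject(st, par), fx_sym)
  curve_h <- fsc(half_e, half_o)
  curve_m <- fsc(full, vol)
  res_h <- resolution_at_threshold(curve_h, 0.143)
  res_m <- resolution_at_threshold(curve_m, 0.4)
  expect_true(attr(res_h, "crossed"))
  expect_true(attr(res_m, "crossed"))
  shell <- diff(curve_h$freq[1:2])
  expect_lte(abs(1 / res_h - 1 / res_m), shell + 1e-12)
})
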