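test_that("test subunit is deterministic and asymmetric", {
  expect_identical(make_test_subunit(1), make_test_subunit(1))
  expect_false(isTRUE(all.equal(make_test_subunit(1)$atoms,
                                make_test_subunit(2)$atoms)))
  expect_error(make_test_subunit(1, n_atoms = 9), "n_atoms")
  # no internal rotational symmetry: best nontrivial self-superposition
  # (exhaustive rotation grid) stays above 2 A RMSD
  expect_gt(template_self_symmetry_rmsd(fx_template), 2)
})

test_that("rendered filament carries the imposed lattice", {
  # integrated density = number of copies x per-subunit integral
  vol <- render_volume(fx_template, fx_sym, 10, 64, 3.0)
  n_atoms <- nrow(fx_template$atoms)
  expect_equal(sum(vol$data), 10 * 5 * n_atoms, tolerance = 0.01)
  # C5: rotating by 72 degrees reproduces the volume
  expect_gt(cor(as.numeric(fx_vol48$data),
                as.numeric(rotate_volume_z(fx_vol48, 72)$data)), 0.99)
  # 0 layers -> empty volume
  expect_equal(sum(render_volume(fx_template, fx_sym, 0, 32, 3)$data), 0)
  # an assembly that does not fit the box is refused with the extent named
  expect_error(render_volume(fx_template, fx_sym, 40, 48, 2.5),
               "exceeds box")
})

test_that("projection is linear, mass-conserving and azimuth-consistent", {
  va <- fx_vol48
  vb <- density_volume(va$data[rev(seq_len(48)), , ], va$voxel_A)
  sum_ab <- density_volume(va$data + vb$data, va$voxel_A)
  expect_equal(project_volume(sum_ab, 33),
               project_volume(va, 33) + project_volume(vb, 33),
               tolerance = 1e-10)
  img <- project_volume(va, 0)
  expect_equal(sum(img), sum(va$data), tolerance = 0.01)
  # rotating the volume by phi about z shifts all azimuths by phi
  rot <- rotate_volume_z(fx_vol96, 33)
  expect_gt(cor(as.numeric(project_volume(rot, 33)),
                as.numeric(project_volume(fx_vol96, 0))), 0.999)
})

test_that("CTF has the analytic limits and zero positions", {
  acq <- acquisition_params(voltage_kV = 300, spherical_aberration_mm = 2.0,
                            amplitude_contrast = 0.1)
  expect_equal(ctf_function(0, 1.5e4, acq), -0.1)
  s <- seq(0, 0.4, by = 1e-3)
  expect_true(all(abs(ctf_function(s, 2.5e4, acq)) <= 1 + 1e-12))
  # independent oracle for the first zero: solve gamma(s) = pi - phi0
  # (the first root of sqrt(1-A^2) sin g + A cos g = 0) directly
  lambda <- electron_wavelength(300)
  cs <- 2.0e7
  phi0 <- atan(0.1 / sqrt(1 - 0.01))
  g <- function(s) pi * lambda * 1.5e4 * s^2 - pi / 2 * cs * lambda^3 * s^4 -
    (pi - phi0)
  oracle <- uniroot(g, c(1e-4, 0.1), tol = 1e-12)$root
  expect_equal(ctf_first_zero(1.5e4, acq), oracle, tolerance = 1e-6)
})

test_that("segment simulation is reproducible and honors its forward model", {
  st <- simulate_segment_stack(fx_vol48, 50, noise_sigma = 0.2, seed = 9,
                               rise_A = 12.1)
  expect_equal(n_segments(st), 50)
  expect_equal(nrow(st$meta), 50)
  expect_identical(st$images,
                   simulate_segment_stack(fx_vol48, 50, noise_sigma = 0.2,
                                          seed = 9, rise_A = 12.1)$images)
  expect_error(simulate_segment_stack(fx_vol48, 0), "n_seg")

  # noiseless, jitter-free segments equal the CTF-filtered projection
  st0 <- simulate_segment_stack(fx_vol48, 3, noise_sigma = 0, seed = 4,
                                defocus_range_um = c(1.5, 1.5),
                                tilt_jitter_deg = 0, psi_jitter_deg = 0,
                                shift_jitter_px = 0)
  acq <- st0$acq
  for (i in 1:3) {
    ref <- project_volume(fx_vol48, st0$meta$azimuth[i])
    ref <- helifil:::apply_ctf_image(ref, st0$meta$defocus_A[i], acq)
    expect_equal(st0$images[, , i], ref, tolerance = 1e-10)
  }
})

test_that("empirical SNR matches the request within 20 percent", {
  sigma <- noise_sigma_for_snr(fx_vol96, 0.1, acquisition_params())
  st <- simulate_segment_stack(fx_vol96, 100, noise_sigma = sigma, seed = 3,
                               rise_A = 12.1)
  vr <- apply(st$images, 3, function(m) var(as.numeric(m)))
  snr_emp <- mean((vr - sigma^2) / sigma^2)
  expect_gt(snr_emp, 0.08)
  expect_lt(snr_emp, 0.12)
})

test_that("mixtures are stratified with the two F-pilus rises by default", {
  st <- simulate_mixture(fx_template, n_seg = 40, box_px = 48, voxel_A = 2.5,
                         seed = 2)
  expect_equal(as.numeric(table(st$meta$class)), c(20, 20))
  expect_equal(formals(simulate_mixture)$sym_a[[3]], 12.5)
  expect_equal(formals(simulate_mixture)$sym_b[[3]], 13.2)
  expect_error(simulate_mixture(fx_template, fraction_a = 0), "fraction_a")
})

test_that("noiseless projections show layer lines at the lattice positions", {
  img <- project_volume(fx_vol96, 13)
  pz <- colSums(Mod(fft(img))^2)
  n <- ncol(img)
  freq <- (seq_len(n) - 1) / (n * fx_vol96$voxel_A)   # 1/A
  # helical selection: z-frequencies (n_bessel * twist/360 + m) / rise with
  # n_bessel a multiple of the cyclic order
  # the two dominant lines allowed by the C5 selection rule in this band:
  # Bessel order 5 (m = 0) and order -5 (m = 1)
  pred <- c(5 * 28.2 / 360, 1 - 5 * 28.2 / 360) / 12.1
  band <- freq > 0.01 & freq < 0.11
  base <- stats::median(pz[band])
  for (f in pred) {
    k <- which.min(abs(freq - f))
    peak <- max(pz[(k - 1):(k + 1)])
    expect_gt(peak, 5 * base)
  }
})

test_that("Fourier cropping preserves the low-frequency content", {
  st <- simulate_segment_stack(fx_vol96, 2, noise_sigma = 0, seed = 1)
  ds <- downsample_stack(st, 2L)
  expect_equal(dim(ds$images)[1:2], c(48, 48))
  expect_equal(ds$pixel_size_A, 4.0)
  # total intensity is preserved by Fourier cropping (DC term)
  expect_equal(mean(ds$images[, , 1]), mean(st$images[, , 1]),
               tolerance = 1e-10)
})
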