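test_that("overlapping boxes follow the helical boxing count", {
  long <- matrix(rnorm(48 * 402), 48, 402)
  expect_equal(n_segments(extract_overlapping_boxes(long[, 1:384], 48, 18)),
               floor((384 - 48) / 18) + 1)
  # the counts of the published boxing scheme
  long384 <- matrix(0, 384, 384)
  expect_equal(n_segments(extract_overlapping_boxes(long384, 384, 18,
                                                    pixel_size_A = 1.1)), 1)
  long402 <- matrix(0, 384, 402)
  expect_equal(n_segments(extract_overlapping_boxes(long402, 384, 18)), 2)
  long564 <- matrix(0, 384, 384 + 10 * 18)
  expect_equal(n_segments(extract_overlapping_boxes(long564, 384, 18)), 11)
  expect_error(extract_overlapping_boxes(matrix(0, 384, 100), 384, 18),
               "shorter")
  # boxes are ordered along the filament with provenance
  st <- extract_overlapping_boxes(long, 48, 20, filament_id = 3L)
  expect_equal(st$meta$offset_px, seq(0, by = 20, length.out = n_segments(st)))
  expect_true(all(st$meta$filament_id == 3L))
  expect_equal(st$images[, , 2], long[1:48, 21:68])
})

test_that("phase flipping multiplies by the CTF and records the weighting", {
  st <- simulate_segment_stack(fx_vol48, 2, noise_sigma = 0, seed = 5,
                               defocus_range_um = c(2, 2),
                               tilt_jitter_deg = 0, psi_jitter_deg = 0,
                               shift_jitter_px = 0)
  # zero image stays zero
  z <- st
  z$images[] <- 0
  expect_equal(max(abs(phase_flip(z)$images)), 0)
  # one application of the flip = one CTF multiplication; applying it to the
  # already CTF-carrying simulated image leaves the CTF^2-weighted image
  clean <- st
  for (i in 1:2)
    clean$images[, , i] <- project_volume(fx_vol48, st$meta$azimuth[i])
  flipped <- phase_flip(clean)
  expect_true(flipped$ctf_weighted)
  acq <- st$acq
  for (i in 1:2) {
    ref <- project_volume(fx_vol48, st$meta$azimuth[i])
    ctf1 <- helifil:::apply_ctf_image(ref, st$meta$defocus_A[i], acq)
    expect_gt(cor(as.numeric(flipped$images[, , i]), as.numeric(ctf1)),
              0.9999)
    # double application = multiplication by CTF^2 (checked in Fourier space)
    twice <- phase_flip(flipped)$images[, , i]
    h <- helifil:::ctf_image(48, st$meta$defocus_A[i], acq)
    ref_f2 <- fft(ref) * h * h
    expect_equal(as.numeric(Mod(fft(twice))), as.numeric(Mod(ref_f2)),
                 tolerance = 1e-6)
  }
  bad <- st
  bad$meta$defocus_A <- NULL
  expect_error(phase_flip(bad), "defocus")
})

test_that("reference sets cover one asymmetric unit", {
  refs <- make_references(fx_vol48, fx_sym, 4)
  expect_equal(dim(refs$images)[3], 18)      # 72 / 4
  expect_equal(refs$azimuths, seq(0, 68, by = 4))
  c1 <- make_references(fx_vol48, helical_symmetry(28.2, 12.1, 1), 90)
  expect_equal(dim(c1$images)[3], 4)
  expect_error(make_references(fx_vol48, fx_sym, 0), "angular_step")
  # C5 volume: references at phi and phi + 72 coincide
  a <- project_volume(fx_vol48, 13)
  b <- project_volume(fx_vol48, 85)
  expect_gt(cor(as.numeric(a), as.numeric(b)), 0.999)
})

test_that("noiseless segments align to within the search grid", {
  st <- simulate_segment_stack(fx_vol96, 40, noise_sigma = 0, seed = 3,
                               rise_A = 12.1)
  stf <- phase_flip(st)
  refs <- make_references(symmetrize(fx_vol96, fx_sym), fx_sym, 4)
  al <- align_segments(stf, refs, c(4, 10))
  err <- alignment_error(stf, al, fx_sym)
  expect_gte(mean(err$d_azimuth_deg <= 2.001), 0.95)
  expect_gte(mean(err$d_axial_px <= 1.2), 0.95)
  expect_gte(mean(abs(err$d_sx_px) <= 1.2), 0.95)
  expect_true(all(abs(err$d_psi_deg) <= 2.001))
  expect_error(align_segments(stf[integer(0)], refs), "empty")
})

test_that("a segment identical to a reference scores 1 at zero shift", {
  refs <- make_references(symmetrize(fx_vol48, fx_sym), fx_sym, 8)
  img <- refs$images[, , 3]
  st <- segment_stack(array(img, c(dim(img), 1)),
                      data.frame(segment = 1), 2.5)
  al <- align_segments(st, refs, c(3, 3), psi_grid_deg = 0)
  expect_equal(al$score, 1, tolerance = 1e-6)
  expect_equal(al$azimuth, refs$azimuths[3])
  expect_equal(c(al$sx_px, al$sy_px), c(0, 0))
})

test_that("noisy segments still align within one angular step", {
  sigma <- noise_sigma_for_snr(fx_vol96, 0.1, acquisition_params())
  st <- simulate_segment_stack(fx_vol96, 40, noise_sigma = sigma, seed = 8,
                               rise_A = 12.1)
  stf <- phase_flip(st)
  refs <- make_references(symmetrize(fx_vol96, fx_sym), fx_sym, 4)
  al <- align_segments(stf, refs, c(4, 10))
  err <- alignment_error(stf, al, fx_sym)
  expect_gte(mean(err$d_azimuth_deg <= 4.001), 0.9)
})

test_that("filtered back-projection inverts projection to half-Nyquist", {
  az <- seq(0, 359, by = 3)
  imgs <- array(0, c(96, 96, length(az)))
  for (i in seq_along(az)) imgs[, , i] <- project_volume(fx_vol96, az[i])
  st <- segment_stack(imgs, data.frame(segment = seq_along(az)), 2.0)
  par <- data.frame(segment = seq_along(az), azimuth = az, psi = 0,
                    sx_px = 0, sy_px = 0, score = 1)
  rec <- backproject(st, par, ctf_correct = FALSE, filter = "ramp")
  curve <- fsc(rec, fx_vol96)
  expect_gt(min(curve$fsc[curve$freq <= 0.125]), 0.95)
  # all-zero images give an all-zero volume
  z <- st
  z$images[] <- 0
  expect_equal(max(abs(backproject(z, par, ctf_correct = FALSE)$data)), 0)
})

test_that("CTF^2 division restores low-frequency amplitudes", {
  sigma <- 0
  st <- simulate_segment_stack(fx_vol96, 30, noise_sigma = sigma, seed = 2,
                               rise_A = 12.1, tilt_jitter_deg = 0,
                               psi_jitter_deg = 0, shift_jitter_px = 0)
  stf <- phase_flip(st)
  par <- data.frame(segment = 1:30, azimuth = st$meta$azimuth %% 360,
                    psi = 0, sx_px = 0, sy_px = st$meta$sy_px, score = 1)
  rec_off <- backproject(stf, par, ctf_correct = FALSE)
  rec_on <- backproject(stf, par, ctf_correct = TRUE)
  radial_amp <- function(v) {
    f <- Mod(fft(v$data))
    d <- dim(v$data)
    fr <- lapply(d, function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n)
    s <- sqrt(outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")) * d[1]
    tapply(as.numeric(f), floor(as.numeric(s)), mean)
  }
  a_off <- radial_amp(rec_off)
  a_on <- radial_amp(rec_on)
  # inside the first CTF lobe the uncorrected map is suppressed
  lobe <- 3:10
  expect_true(all(a_off[lobe] / a_on[lobe] < 1))
})

test_that("alignment transfer reproduces and improves reconstructions", {
  sym <- fx_sym
  # paired acquisitions at the two dose levels: same geometry (same seed),
  # the low-dose partner with half the dose and hence double the noise
  # power; 48-px boxes, where alignment quality responds to dose
  fxs <- render_volume(fx_template, sym, ceiling(48 * 2.5 / 12.1) + 4,
                       48, 2.5, clip_z = TRUE)
  sigma_hi <- noise_sigma_for_snr(fxs, 0.1, acquisition_params())
  st_hi <- phase_flip(simulate_segment_stack(fxs, 60, noise_sigma = sigma_hi,
                                             seed = 12, rise_A = 12.1))
  st_lo <- phase_flip(simulate_segment_stack(fxs, 60,
                                             noise_sigma = sigma_hi * sqrt(2),
                                             seed = 12, rise_A = 12.1))
  fit_hi <- ihrsr(st_hi, sym, max_iter = 3, search_symmetry = FALSE,
                  auto_flip = FALSE)
  fit_lo <- ihrsr(st_lo, sym, max_iter = 3, search_symmetry = FALSE,
                  auto_flip = FALSE)
  # identical transfer: same stack, same params -> same volume
  v1 <- backproject(st_lo, fit_hi$alignment)
  v2 <- transfer_alignment(fit_hi$alignment, st_lo)
  expect_equal(v1$data, v2$data, tolerance = 1e-12)
  expect_error(transfer_alignment(fit_hi$alignment[1:10, ], st_lo),
               "differ in length")
  # transferring the better-aligned high-dose parameters onto the low-dose
  # images beats aligning the low-dose stack directly at the same iteration
  # count
  fsc_truth <- function(v) {
    a <- align_volumes(v, fxs, sym)
    curve <- fsc(a, fxs)
    mean(curve$fsc[curve$freq > 0.03 & curve$freq < 0.15])
  }
  v_tr <- symmetrize(transfer_alignment(fit_hi$alignment, st_lo), sym)
  expect_gt(fsc_truth(v_tr), fsc_truth(fit_lo$volume))
})

test_that("symmetry search recovers lattice parameters from clean maps", {
  az <- seq(0, 357, by = 3)
  imgs <- array(0, c(96, 96, length(az)))
  for (i in seq_along(az)) imgs[, , i] <- project_volume(fx_vol96, az[i])
  st <- segment_stack(imgs, data.frame(segment = seq_along(az)), 2.0)
  par <- data.frame(segment = seq_along(az), azimuth = az, psi = 0,
                    sx_px = 0, sy_px = 0, score = 1)
  rec <- backproject(st, par, ctf_correct = FALSE, filter = "ramp")
  found <- symmetry_search(rec, helical_symmetry(27, 11.5, 5),
                           twist_range = 2, rise_range = 1)
  expect_lt(abs(found$twist_deg - 28.2), 0.1)
  expect_lt(abs(found$rise_A - 12.1), 0.05)
  expect_false(attr(found, "degenerate"))
  # featureless volume -> degeneracy flag
  flat <- density_volume(array(1, c(32, 32, 32)), 2.5)
  deg <- symmetry_search(flat, fx_sym)
  expect_true(attr(deg, "degenerate"))
  # the wrong cyclic order symmetrizes worse than the right one
  res <- compare_cyclic_orders(fx_vol96, 4:6)
  expect_lt(res$residual[res$cyclic_order == 5],
            min(res$residual[res$cyclic_order != 5]) / 10)
})

test_that("symmetrization is idempotent and invariant", {
  s1 <- symmetrize(fx_vol96, fx_sym)
  # already-symmetric volume is essentially unchanged
  expect_gt(cor(as.numeric(s1$data), as.numeric(fx_vol96$data)), 0.999)
  s2 <- symmetrize(s1, fx_sym)
  expect_gt(cor(as.numeric(s1$data), as.numeric(s2$data)), 0.999)
  # invariance under the imposed operations
  expect_gt(screw_self_correlation(s1, 28.2, 12.1, c(4, 80)), 0.999)
  expect_gt(screw_self_correlation(s1, 72, 0, c(4, 80)), 0.999)
})

test_that("symmetrizing noise creates the imposed symmetry", {
  set.seed(7)
  noise <- density_volume(array(rnorm(64^3), c(64, 64, 64)), 2.0)
  before <- screw_self_correlation(noise, 72, 0, c(4, 56),
                                   lowpass_sigma_vox = 1)
  after <- screw_self_correlation(symmetrize(noise, fx_sym), 72, 0, c(4, 56),
                                  lowpass_sigma_vox = 1)
  expect_lt(abs(before), 0.05)
  expect_gt(after, 0.99)
})

test_that("ihrsr with max_iter = 0 returns the initial state", {
  st <- simulate_segment_stack(fx_vol48, 3, noise_sigma = 0, seed = 1)
  fit <- ihrsr(st, fx_sym, max_iter = 0)
  expect_false(fit$converged)
  expect_equal(fit$iterations, 0L)
  expect_equal(coef(fit), c(twist_deg = 28.2, rise_A = 12.1))
  expect_equal(nrow(fit$history), 1L)
})

test_that("ihrsr converges quickly on noiseless data", {
  st <- simulate_segment_stack(fx_vol96, 60, noise_sigma = 0, seed = 2,
                               rise_A = 12.1)
  fit <- ihrsr(st, helical_symmetry(27.5, 11.7, 5), max_iter = 6)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 5)
  expect_lt(abs(coef(fit)[1] - 28.2), 0.5)
  expect_lt(abs(coef(fit)[2] - 12.1), 0.2)
})

test_that("sorting errors when one class empties (identical candidates)", {
  st <- simulate_mixture(fx_template, n_seg = 16, box_px = 48, voxel_A = 2.5,
                         seed = 2, noise_sigma = 0.1)
  expect_error(
    suppressWarnings(sort_segments(st, fx_sym, fx_sym, n_cycles = 1,
                                   n_init_iter = 1)),
    "emptied at sorting cycle")
})
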