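test_that("Kabsch superposition is exact and validated", {
  set.seed(2)
  a <- matrix(rnorm(45, sd = 6), 15, 3)
  fit0 <- kabsch_superpose(a, a)
  expect_equal(fit0$rmsd_A, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  for (seed in 1:10) {
    set.seed(seed)
    rot <- screw_compose_axis(rnorm(3), runif(1, 10, 170), 0)$rotation
    tr <- rnorm(3, sd = 5)
    b <- a %*% t(rot) + rep(tr, each = nrow(a))
    fit <- kabsch_superpose(a, b)
    expect_lt(max(abs(fit$rotation - rot)), 1e-8)
    expect_lt(max(abs(fit$translation - tr)), 1e-8)
    expect_lt(fit$rmsd_A, 1e-8)
  }
  expect_error(kabsch_superpose(a, a[1:10, ]), "differ in size")
  line <- cbind(1:10, 2 * (1:10), -(1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches the bio3d fit as an independent oracle", {
  set.seed(5)
  a <- matrix(rnorm(60, sd = 8), 20, 3)
  rot <- screw_compose_axis(c(1, 2, 3), 37, 0)$rotation
  b <- a %*% t(rot) + rep(c(1, -2, 3), each = 20) +
    matrix(rnorm(60, sd = 0.4), 20, 3)
  ours <- kabsch_superpose(a, b)$rmsd_A
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a))))
  theirs <- sqrt(mean(colSums(matrix((fitted - as.numeric(t(b)))^2, 3))))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("the screw between adjacent chains recovers the lattice", {
  screw <- screw_from_chain_pair(fx_filament, "C.A05", "C.A06")
  expect_equal(screw$angle_deg, 28.2, tolerance = 1e-6)
  expect_equal(abs(screw$axial_shift_A), 12.1, tolerance = 1e-6)
  expect_lt(attr(screw, "rmsd_A"), 1e-6)
  # chain against itself is degenerate
  self <- screw_from_chain_pair(fx_filament, "C.A05", "C.A05")
  expect_true(self$degenerate)
  # atom mismatches are reported, and too few matches are an error
  one_res <- atomic_model(fx_pilin$atoms[fx_pilin$atoms$resno <= 3, ])
  two <- propagate_strand(one_res, screw_transform(helifil:::rot_z(28.2),
                                                   c(0, 0, 12.1)), 2)
  expect_error(screw_from_chain_pair(two, "A01", "A02", elety = "NZ"),
               "no atoms matching")
})

test_that("strand propagation applies successive screw powers", {
  screw <- screw_transform(helifil:::rot_z(28.2), c(0, 0, 12.1))
  strand <- propagate_strand(fx_pilin, screw, 16)
  expect_equal(length(unique(strand$atoms$unit)), 16)
  expect_equal(nrow(strand$atoms), 16 * nrow(fx_pilin$atoms))
  # count 1 is the unit itself (identity power)
  one <- propagate_strand(fx_pilin, screw, 1)
  expect_equal(model_coords(one), model_coords(fx_pilin), tolerance = 1e-12)
  # self-consistency: the screw between units 3 and 4 is the input screw
  back <- screw_from_chain_pair(strand, "A03", "A04")
  expect_equal(back$angle_deg, 28.2, tolerance = 1e-6)
  expect_equal(abs(back$axial_shift_A), 12.1, tolerance = 1e-6)
  expect_error(propagate_strand(fx_pilin, screw, 0), "count")
})

test_that("the full pilus is the Cn replication of one strand", {
  n_unit_atoms <- nrow(fx_pilin$atoms)
  expect_equal(nrow(fx_filament$atoms), 5 * 10 * n_unit_atoms)
  expect_equal(length(unique(fx_filament$atoms$strand)), 5)
  # C1 returns the strand unchanged
  screw <- screw_transform(helifil:::rot_z(28.2), c(0, 0, 12.1))
  strand <- propagate_strand(fx_pilin, screw, 3)
  c1 <- build_full_pilus(strand, 1L)
  expect_equal(model_coords(c1), model_coords(strand), tolerance = 1e-12)
  # exact C5: rotating strand k by 72 degrees gives strand k+1
  rot <- helifil:::rot_z(72)
  a <- model_coords(fx_filament)[fx_filament$atoms$strand == 1, ]
  b <- model_coords(fx_filament)[fx_filament$atoms$strand == 2, ]
  expect_lt(max(abs(a %*% t(rot) - b)), 1e-6)
  expect_true(is.finite(attr(fx_filament, "min_interstrand_A")))
})

test_that("build-extract round trip reproduces the construction lattice", {
  for (p in list(c(28.2, 12.1), c(28.1, 12.5), c(27.9, 13.2))) {
    sym <- helical_symmetry(p[1], p[2], 5)
    fil <- suppressWarnings(build_filament_model(fx_pilin, sym, 5))
    got <- screw_from_chain_pair(fil, "A.A02", "A.A03")
    expect_equal(got$angle_deg, p[1], tolerance = 1e-6)
    expect_equal(abs(got$axial_shift_A), p[2], tolerance = 1e-6)
    expect_equal(abs(got$axis[3]), 1, tolerance = 1e-8)
  }
})

test_that("the synthetic pilin matches the modeled chain definition", {
  prot <- fx_pilin$atoms[fx_pilin$atoms$resid != "PG", ]
  expect_equal(length(unique(prot$resno)), 63)   # residues 2-64
  expect_equal(range(prot$resno), c(2, 64))
  expect_identical(make_test_pilin(3), make_test_pilin(3))
})
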