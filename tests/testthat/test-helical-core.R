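test_that("subunits per turn follows 360/|twist|", {
  expect_equal(round(subunits_per_turn(fx_sym), 1), 12.8)
  expect_equal(subunits_per_turn(fx_sym), 360 / 28.2)
  expect_equal(subunits_per_turn(helical_symmetry(90, 5, 1)), 4.0)
  expect_equal(subunits_per_turn(helical_symmetry(27.9, 13.2, 5)),
               360 / 27.9, tolerance = 1e-12)
  # scale invariance under rise changes
  for (rise in c(1, 12.1, 40))
    expect_equal(subunits_per_turn(helical_symmetry(28.2, rise, 5)),
                 subunits_per_turn(fx_sym))
  expect_error(helical_symmetry(0, 12.1, 5), "twist")
})

test_that("helical_symmetry validates its invariants", {
  expect_error(helical_symmetry(28.2, -1, 5), "rise")
  expect_error(helical_symmetry(400, 12.1, 5), "twist")
  expect_error(helical_symmetry(28.2, 12.1, 0), "cyclic_order")
})

test_that("layer transforms build the full lattice", {
  tr <- layer_transforms(fx_sym, 13)
  expect_length(tr, 65)  # 13 layers x C5, the depicted A-M per strand
  expect_equal(tr[[1]]$rotation, diag(3))
  expect_equal(tr[[1]]$translation, c(0, 0, 0))
  # transform(i=2,k=0) equals transform(i=1,k=0) applied twice
  get <- function(i, k) tr[[which(vapply(tr, attr, 0, "layer") == i &
                                    vapply(tr, attr, 0, "strand") == k)]]
  t1 <- get(1, 0)
  t2 <- get(2, 0)
  expect_equal(compose_screw(t1, t1)$rotation, t2$rotation, tolerance = 1e-12)
  expect_equal(compose_screw(t1, t1)$translation, t2$translation,
               tolerance = 1e-12)
  expect_error(layer_transforms(fx_sym, 0), "n_layers")
})

test_that("lattice transforms are closed under composition", {
  tr <- layer_transforms(fx_sym, 4)
  # product of two lattice transforms is the lattice transform with summed
  # layer and strand indices
  for (a in c(2, 7)) for (b in c(3, 9)) {
    comp <- compose_screw(tr[[a]], tr[[b]])
    i <- attr(tr[[a]], "layer") + attr(tr[[b]], "layer")
    k <- (attr(tr[[a]], "strand") + attr(tr[[b]], "strand")) %% 5
    # canonicalize the decomposition to the +z axis
    ang <- comp$angle_deg
    shift <- comp$axial_shift_A
    if (comp$axis[3] < 0) {
      ang <- 360 - ang
      shift <- -shift
    }
    expect_equal(ang %% 360, (i * 28.2 + k * 72) %% 360, tolerance = 1e-9)
    expect_equal(shift, i * 12.1, tolerance = 1e-9)
  }
})

test_that("layer-stack and n-start strand descriptions coincide", {
  expect_true(strand_lattice_equivalence(fx_sym, 13)$equivalent)
  # the two coexisting F-pilus lattices
  expect_true(strand_lattice_equivalence(helical_symmetry(27.9, 13.2, 5),
                                         10)$equivalent)
  expect_true(strand_lattice_equivalence(helical_symmetry(28.1, 12.5, 5),
                                         10)$equivalent)
  # perturbing one strand's azimuthal phase breaks the equivalence
  off <- c(0, 1, 0, 0, 0)
  expect_false(strand_lattice_equivalence(fx_sym, 10,
                                          phase_offsets_deg = off)$equivalent)
  # property over a grid of lattices
  for (tw in c(15, 28.2, 61)) for (ri in c(4, 12.1)) for (n in c(1, 3, 5)) {
    eq <- strand_lattice_equivalence(helical_symmetry(tw, ri, n), 7)
    expect_true(eq$equivalent, label = sprintf("(%g, %g, C%d)", tw, ri, n))
  }
})

test_that("screw decomposition recovers constructed screws", {
  sc <- screw_transform(helifil:::rot_z(28.2), c(0, 0, 12.1))
  expect_equal(sc$angle_deg, 28.2, tolerance = 1e-9)
  expect_equal(sc$axial_shift_A, 12.1, tolerance = 1e-9)
  expect_equal(abs(sc$axis[3]), 1, tolerance = 1e-9)
  expect_false(sc$degenerate)

  id <- screw_transform(diag(3), c(0, 0, 0))
  expect_true(id$degenerate)
  expect_match(id$degenerate_reason, "identity")

  tr <- screw_transform(diag(3), c(3, 0, 4))
  expect_true(tr$degenerate)
  expect_equal(tr$axial_shift_A, 5)
  expect_equal(tr$axis, c(3, 0, 4) / 5)
})

test_that("random screws survive a conjugation round trip", {
  for (seed in 1:20) {
    set.seed(seed)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- runif(1, 5, 175)
    shift <- runif(1, -20, 20)
    point <- rnorm(3, sd = 10)
    rt <- screw_compose_axis(axis, ang, shift, point)
    dec <- screw_decompose(rt$rotation, rt$translation)
    expect_equal(dec$angle_deg, ang, tolerance = 1e-6)
    expect_equal(abs(dec$axial_shift_A), abs(shift), tolerance = 1e-6)
    # recomposition reproduces the transform on test points
    rc <- screw_compose_axis(dec$axis, dec$angle_deg, dec$axial_shift_A,
                             dec$axis_point)
    pts <- matrix(rnorm(15, sd = 8), 5, 3)
    orig <- pts %*% t(rt$rotation) + rep(rt$translation, each = 5)
    back <- pts %*% t(rc$rotation) + rep(rc$translation, each = 5)
    expect_lt(max(abs(orig - back)), 1e-6)
  }
})

test_that("screw transforms validate orthonormality", {
  m <- diag(3); m[1, 1] <- 1.01
  expect_error(screw_transform(m), "orthonormal")
  expect_error(screw_transform(diag(c(1, -1, 1))), "proper")
})
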