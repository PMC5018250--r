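test_that("SASA reproduces closed-form sphere areas", {
  one <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                    element = "C", x = 0, y = 0, z = 0)
  a1 <- sasa(atomic_model(one))
  expect_equal(a1, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)
  # two atoms far apart: sum of isolated areas
  two <- rbind(one, within(one, {x <- 100; elety <- "CB"}))
  expect_equal(sum(sasa(atomic_model(two))), 2 * a1, tolerance = 0.01)
  # an atom enclosed by a shell of atoms is fully buried
  i <- seq_len(80) - 0.5
  z <- 1 - 2 * i / 80
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  cage <- data.frame(chain = "A", resno = 2, resid = "ALA",
                     elety = paste0("C", seq_len(80)), element = "C",
                     x = 3 * r * cos(th), y = 3 * r * sin(th), z = 3 * z)
  caged <- rbind(one, cage)
  expect_lt(sasa(atomic_model(caged))[1], 1)
  bad <- within(one, element <- "Q")
  expect_error(sasa(atomic_model(bad)), "unknown element")
})

test_that("SASA quadrature converges", {
  s1 <- sum(sasa(fx_pilin, n_sphere_points = 960))
  s2 <- sum(sasa(fx_pilin, n_sphere_points = 1920))
  expect_lt(abs(s1 - s2) / s2, 0.005)
})

test_that("buried areas behave like interfaces", {
  # isolated component (assembly = the component alone): nothing buried
  prot_only <- atomic_model(fx_pilin$atoms[fx_pilin$atoms$chain == "A", ])
  iso <- buried_fraction(prot_only, "A")
  expect_equal(iso$buried_A2, 0, tolerance = 1e-9)
  expect_equal(iso$fraction, 0)
  # pairwise buried areas are symmetric within quadrature tolerance
  pair_chains <- c("C.A05", "C.A06")
  sub <- atomic_model(fx_filament$atoms[fx_filament$atoms$chain %in%
                                          pair_chains, ])
  b_ij <- buried_fraction(sub, pair_chains[1])$buried_A2
  b_ji <- buried_fraction(sub, pair_chains[2])$buried_A2
  expect_lt(abs(b_ij - b_ji), 1)
  expect_error(buried_fraction(fx_filament, "nope"), "not present")
})

test_that("contact networks distinguish interior from terminal subunits", {
  nb_int <- neighbor_count(fx_filament, "C.A05", n_sphere_points = 480)
  nb_term <- neighbor_count(fx_filament, "C.A01", n_sphere_points = 480)
  expect_gt(nb_int$count, nb_term$count)
  # the 4-A distance criterion is stricter than buried-area contact
  nb_dist <- neighbor_count(fx_filament, "C.A05", criterion = "distance")
  expect_true(all(nb_dist$neighbors %in% nb_int$neighbors))
  expect_error(neighbor_count(fx_filament, "zz"), "absent")
})

test_that("interior subunits are helically equivalent", {
  # every interior subunit of an ideal filament sees the same environment
  stats_of <- function(ch) {
    tab <- pairwise_buried_table(fx_filament, ch, n_sphere_points = 480)
    c(tab$total_A2, tab$protein_buried_A2, tab$combined_buried_A2)
  }
  a <- stats_of("C.A05")
  b <- stats_of("D.A05")
  c3 <- stats_of("C.A06")
  expect_equal(a, b, tolerance = 0.01)
  expect_equal(a, c3, tolerance = 0.01)
  # non-touching components give no table entry
  tab <- pairwise_buried_table(fx_filament, "C.A05", n_sphere_points = 480)
  expect_false("A.A01" %in% tab$pairs$chain)
  expect_true(all(tab$pairs$buried_A2 > 0))
})

test_that("radial geometry measures lumen and outer diameters", {
  # ideal hollow cylinder of atoms at r = 30
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  cyl <- do.call(rbind, lapply(seq(-30, 30, by = 5), function(z)
    data.frame(chain = "A", resno = seq_along(th), resid = "GLY",
               elety = "CA", element = "C",
               x = 30 * cos(th), y = 30 * sin(th), z = z)))
  cyl$resno <- seq_len(nrow(cyl))
  g <- radial_geometry(atomic_model(cyl))
  expect_lt(g$lumen_diameter_A, 60)
  expect_equal(g$outer_diameter_A, 60, tolerance = 0.01)
  expect_equal(g$outer_diameter_padded_A, 60 + 2 * 1.7, tolerance = 0.01)
  # a single pentamer layer still has enough z-slices
  layer <- atomic_model(fx_filament$atoms[fx_filament$atoms$unit == 5, ])
  expect_s3_class(radial_geometry(layer), "radial_profile")
  # too-thin models are refused
  flat <- cyl[seq_along(th), ]
  expect_error(radial_geometry(atomic_model(flat)), "slices")
})

test_that("the synthetic filament has pilus-like dimensions", {
  g <- radial_geometry(fx_filament)
  expect_gt(g$outer_diameter_A, 80)
  expect_lt(g$outer_diameter_A, 100)
  expect_gt(g$lumen_diameter_A, 20)
  expect_lt(g$lumen_diameter_A, 34)
})

test_that("screened-Coulomb potential follows its charges", {
  # no charges: a lipid fragment without a phosphate
  frag <- atomic_model(data.frame(chain = "L", resno = 1, resid = "PG",
                                  elety = paste0("C", 1:4), element = "C",
                                  x = c(0, 2, 4, 6), y = 0, z = c(0, 1, 2, 3)))
  p0 <- lumen_potential(frag, include_lipids = TRUE)
  expect_equal(max(abs(p0$grid)), 0)
  # a single negative charge: everywhere negative, decaying with distance
  one <- atomic_model(data.frame(chain = "L", resno = 1, resid = "PG",
                                 elety = c("P", "C1", "C2"),
                                 element = c("P", "C", "C"),
                                 x = c(0, 3, 6), y = 0, z = c(0, 0.5, 1)))
  p1 <- lumen_potential(one, include_lipids = TRUE, grid_spacing_A = 1.5)
  expect_true(all(p1$grid <= 0))
  mid <- ceiling(dim(p1$grid)[2] / 2)
  ray <- p1$grid[, mid, 1]
  right <- ray[seq(which.min(ray), length(ray))]
  expect_true(all(diff(right) >= -1e-9))
  # unknown residues are refused by name
  bad <- fx_pilin
  bad$atoms$resid[1] <- "XXX"
  expect_error(lumen_potential(bad), "XXX")
})

test_that("lipid head groups flip the sign of the lumen potential", {
  with_l <- lumen_potential(fx_filament, include_lipids = TRUE)
  without <- lumen_potential(fx_filament, include_lipids = FALSE)
  expect_gt(without$mean_lumen_potential, 0)
  expect_lt(with_l$mean_lumen_potential, without$mean_lumen_potential)
  expect_lt(with_l$mean_lumen_potential, 0)
})
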