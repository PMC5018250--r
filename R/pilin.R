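# Synthetic pseudo-atomic pilin + lipid unit for assembly-level analyses.
# This is a SYNTHETIC stand-in constructed from the published architectural
# description of the conjugative pilus subunit (a small three-helix pilin
# spanning the filament wall, lysines near the lumen, acidic residues at
# the periphery, and a stoichiometric phosphatidylglycerol whose phosphate
# lines the lumen); it is not derived from deposited coordinates.

# CA trace of an ideal alpha-helix of n residues along a given axis
helix_ca <- function(n, start, dir, phase = 0) {
  dir <- dir / sqrt(sum(dir^2))
  # orthonormal frame around the axis
  up <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
          dir[3] * e1[1] - dir[1] * e1[3],
          dir[1] * e1[2] - dir[2] * e1[1])
  i <- seq_len(n) - 1
  ang <- phase + i * 100 * pi / 180   # 100 deg per residue
  t(vapply(seq_len(n), function(j) {
    start + i[j] * 1.5 * dir + 2.3 * (cos(ang[j]) * e1 + sin(ang[j]) * e2)
  }, numeric(3)))
}

#' Synthetic pilin + lipid unit in the canonical filament frame
#'
#' Builds a pseudo-atomic model of one repeating unit of the pilus: a
#' 63-residue (numbered 2-64) three-helix Cα-trace pilin spanning the
#' filament wall (radii ~15-43 A), with lysine side-chain charges placed on
#' lumen-proximal residues, aspartate/glutamate on peripheral residues and
#' charged chain termini, plus a phosphatidylglycerol-like lipid (residue
#' name "PG") whose phosphate head group sits at the lumen surface and whose
#' acyl tail is buried between subunits. Purely synthetic, deterministic
#' given the seed, intended for exercising assembly, interface and
#' electrostatics analyses at realistic dimensions.
#'
#' @param seed Integer seed (jitters atom positions by ~0.1 A).
#' @param protein_chain,lipid_chain Chain ids (defaults "A", "L").
#' @return An [atomic_model()] of one pilin + one lipid.
#' @export
make_test_pilin <- function(seed = 1, protein_chain = "A",
                            lipid_chain = "L") {
  # three-helix bundle oriented mostly along the filament axis and spanning
  # the filament wall (inner helix near the lumen, outer helix at the
  # periphery), with the loop between the inner helices bowing into the
  # lumen — the arrangement of the pilin fold in the assembled pilus
  d1 <- c(0.10, -0.30, -0.85); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- c(0.05, 0.50, -0.85); d2 <- d2 / sqrt(sum(d2^2))
  d3 <- c(0.55, -0.18, 0.77); d3 <- d3 / sqrt(sum(d3^2))
  ca1 <- helix_ca(14, c(39.5, 8, 8.5), d1)
  ca2 <- helix_ca(26, c(20, -10, 11.3), d2, phase = 1.2)
  ca3 <- helix_ca(13, c(16, 7, -11.3), d3, phase = 2.4)
  bow <- function(a, b, n, mid) {
    f <- seq(0, 1, length.out = n + 2)[2:(n + 1)]
    outer(1 - f, a) + outer(f, b) + outer(sin(pi * f), mid - (a + b) / 2)
  }
  loop1 <- bow(ca1[14, ], ca2[1, ], 5, c(31, 0, -12))      # h1 -> h2
  loop2 <- bow(ca2[26, ], ca3[1, ], 5, c(15, -2, -16))     # lumen-facing loop
  ca <- rbind(ca1, loop1, ca2, loop2, ca3)
  ca <- with_seed(seed, ca + matrix(stats::rnorm(length(ca), sd = 0.1),
                                    nrow(ca), 3))
  n_res <- nrow(ca)                   # 63 residues, numbered 2..64
  resno <- seq_len(n_res) + 1L
  r <- sqrt(ca[, 1]^2 + ca[, 2]^2)
  resid <- rep(c("ALA", "LEU", "VAL", "GLY", "ILE"), length.out = n_res)
  inner <- which(r > 15.5 & r < 19)
  outer_res <- which(r > 38)
  resid[inner[seq_along(inner) %% 3 == 1]] <- "LYS"
  resid[outer_res[seq_along(outer_res) %% 2 == 1]] <-
    rep(c("ASP", "GLU"), length.out = sum(seq_along(outer_res) %% 2 == 1))
  rows <- data.frame(chain = protein_chain, resno = resno, resid = resid,
                     elety = "CA", element = "C",
                     x = ca[, 1], y = ca[, 2], z = ca[, 3])
  # one side-chain pseudo-atom per charged residue, displaced radially
  side <- do.call(rbind, lapply(which(resid %in% c("LYS", "ASP", "GLU")), function(i) {
    u <- c(ca[i, 1], ca[i, 2], 0) / max(r[i], 1)
    inward <- resid[i] == "LYS"
    p <- ca[i, ] + (if (inward) -1.0 else 2.5) * u
    data.frame(chain = protein_chain, resno = resno[i], resid = resid[i],
               elety = if (inward) "NZ" else "OD1",
               element = if (inward) "N" else "O",
               x = p[1], y = p[2], z = p[3])
  }))
  # lipid: phosphatidylglycerol proxy. The phosphate head group sits at the
  # lumen surface (innermost species, solvent exposed toward the channel);
  # the acyl tail runs outward through the groove between helical strands.
  tt <- seq(0, 1, length.out = 9)
  lip_r <- c(13.2, 12.7, 14.0, 13.1, 15.6, 17.5 + tt * 17)
  lip_phi <- c(-30, -34, -27, -33, -28, -27 - tt * 12) * pi / 180
  lip <- data.frame(
    chain = lipid_chain, resno = 1L, resid = "PG",
    elety = c("P", "O11", "O12", "O13", "C1", paste0("C", 2:10)),
    element = c("P", "O", "O", "O", rep("C", 10)),
    x = lip_r * cos(lip_phi),
    y = lip_r * sin(lip_phi),
    z = c(-14, -13, -13.2, -15.4, -13.5, -12.5 + tt * 8))
  atomic_model(rbind(rows, side, lip))
}
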