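# Screened-Coulomb (Debye-Hueckel) lumen electrostatics. A deliberately
# simple uniform-dielectric model: the quantity of interest is the sign and
# rough magnitude of the lumen-surface potential with and without the
# phospholipid head groups, not APBS-grade energetics.

# simplified formal charges: one point charge per charged group
model_charges <- function(model, include_lipids = TRUE, lipid_resid = "PG") {
  a <- model$atoms
  known_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL")
  bad <- setdiff(unique(a$resid), c(known_aa, lipid_resid))
  if (length(bad))
    stop("unparameterized residue(s): ", paste(bad, collapse = ", "))
  is_lip <- a$resid %in% lipid_resid
  q <- list()
  # side-chain charges: prefer the terminal side-chain atom, else CA
  pick <- function(rows, prefer) {
    i <- rows[a$elety[rows] %in% prefer]
    if (length(i) == 0) i <- rows[a$elety[rows] == "CA"]
    i[1]
  }
  prot <- a[!is_lip, , drop = FALSE]
  if (nrow(prot)) {
    res <- split(which(!is_lip), paste(a$chain[!is_lip], a$resno[!is_lip]))
    for (rr in res) {
      rn <- a$resid[rr[1]]
      if (rn %in% c("LYS", "ARG"))
        q[[length(q) + 1]] <- c(pick(rr, c("NZ", "CZ", "NH1")), +1)
      else if (rn %in% c("ASP", "GLU"))
        q[[length(q) + 1]] <- c(pick(rr, c("OD1", "OE1", "CG", "CD")), -1)
    }
    # termini: +1 on the first residue, -1 on the last, per protein chain
    for (ch in unique(a$chain[!is_lip])) {
      rows <- which(a$chain == ch & !is_lip)
      first <- rows[a$resno[rows] == min(a$resno[rows])]
      last <- rows[a$resno[rows] == max(a$resno[rows])]
      q[[length(q) + 1]] <- c(pick(first, "N"), +1)
      q[[length(q) + 1]] <- c(pick(last, c("OXT", "C")), -1)
    }
  }
  if (include_lipids && any(is_lip)) {
    pr <- which(is_lip & a$elety == "P")
    for (i in pr) q[[length(q) + 1]] <- c(i, -1)
  }
  m <- do.call(rbind, q)
  data.frame(x = a$x[m[, 1]], y = a$y[m[, 1]], z = a$z[m[, 1]],
             charge = m[, 2])
}

#' Electrostatic potential of the filament lumen
#'
#' Debye-Hueckel screened-Coulomb potential on a regular grid from
#' simplified formal charges (+1 Lys/Arg side chains, -1 Asp/Glu, +/-1
#' chain termini, -1 per lipid phosphate), in kT/e units at 298 K with a
#' uniform dielectric of 80. The summary value is the mean potential over
#' the lumen-facing shell (grid points just inside the lumen radius, over
#' the central half of the filament length).
#'
#' @param model An [atomic_model()] in the canonical frame.
#' @param include_lipids Include lipid phosphate charges (default TRUE).
#' @param ionic_strength_M Ionic strength (default 0.15 M).
#' @param grid_spacing_A Grid spacing (default 2 A).
#' @param lipid_resid Residue name(s) identifying lipids.
#' @return Object of class `"potential_grid"`: list with `grid` (3D array,
#'   kT/e), `axes` (x/y/z coordinates), `mean_lumen_potential`,
#'   `lumen_radius_A`, `charges` (the charge table used).
#' @export
lumen_potential <- function(model, include_lipids = TRUE,
                            ionic_strength_M = 0.15, grid_spacing_A = 2,
                            lipid_resid = "PG") {
  ch <- model_charges(model, include_lipids, lipid_resid)
  bjerrum <- 7.00        # A, water at 298 K, eps 80
  kappa <- if (ionic_strength_M > 0) sqrt(ionic_strength_M) / 3.04 else 0
  a <- model$atoms
  rmax <- max(sqrt(a$x^2 + a$y^2))
  zr <- range(a$z)
  gx <- seq(-rmax, rmax, by = grid_spacing_A)
  gz <- seq(zr[1], zr[2], by = grid_spacing_A)
  grid <- array(0, c(length(gx), length(gx), length(gz)))
  if (nrow(ch)) {
    pts <- as.matrix(expand.grid(x = gx, y = gx, z = gz))
    pot <- numeric(nrow(pts))
    for (i in seq_len(nrow(ch))) {
      d <- sqrt((pts[, 1] - ch$x[i])^2 + (pts[, 2] - ch$y[i])^2 +
                  (pts[, 3] - ch$z[i])^2)
      d <- pmax(d, 1)      # cap the self-region divergence at 1 A
      pot <- pot + ch$charge[i] * bjerrum * exp(-kappa * d) / d
    }
    grid <- array(pot, dim(grid))
  }
  # lumen-facing shell: just inside the minimal radial atom distance,
  # central half of the filament length
  lum_r <- min(sqrt(a$x^2 + a$y^2))
  rr <- sqrt(outer(gx^2, gx^2, "+"))
  shell_xy <- rr <= lum_r & rr >= max(0, lum_r - 2 * grid_spacing_A)
  zc <- mean(zr) + c(-0.25, 0.25) * diff(zr)
  shell_z <- gz >= zc[1] & gz <= zc[2]
  sel <- outer(as.numeric(shell_xy), as.numeric(shell_z)) > 0
  vals <- grid[array(sel, dim(grid))]
  structure(list(grid = grid, axes = list(x = gx, y = gx, z = gz),
                 mean_lumen_potential = mean(vals),
                 lumen_radius_A = lum_r,
                 kappa_inv_A = if (kappa > 0) 1 / kappa else Inf,
                 charges = ch,
                 include_lipids = include_lipids),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("Lumen electrostatic potential (%s lipids)\n",
              if (x$include_lipids) "with" else "without"))
  cat(sprintf("  %d charges, Debye length %.1f A\n", nrow(x$charges),
              x$kappa_inv_A))
  cat(sprintf("  mean potential over the lumen shell (r <= %.1f A): %+.2f kT/e\n",
              x$lumen_radius_A, x$mean_lumen_potential))
  invisible(x)
}
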