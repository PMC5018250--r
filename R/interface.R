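# Solvent-accessible surface areas, buried-surface interface statistics and
# contact networks of filament assemblies.

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Numerical SASA with a probe rolled over van der Waals spheres
#' (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Angstrom), sampling
#' `n_sphere_points` quasi-uniform points per atom.
#'
#' @param model An [atomic_model()] (or a data.frame of atoms).
#' @param probe_radius Probe radius (default 1.4 A, water).
#' @param n_sphere_points Quadrature points per atom (default 960).
#' @return Numeric vector of per-atom areas (A^2); `sum()` gives the total.
#' @export
sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960) {
  a <- if (inherits(model, "atomic_model")) model$atoms else model
  if (nrow(a) == 0) return(numeric(0))
  cpp_sasa(as.matrix(a[, c("x", "y", "z")]), vdw_radius(a$element),
           probe_radius, as.integer(n_sphere_points))
}

# atoms of a component (chains) inside a model
component_atoms <- function(assembly, chains) {
  sel <- assembly$atoms$chain %in% chains
  if (!any(sel)) stop("selection not present in assembly: ",
                      paste(chains, collapse = ", "))
  sel
}

#' Surface area of a component buried by its assembly context
#'
#' `buried = SASA(component isolated) - SASA(component within assembly)`,
#' with the fraction taken against the isolated total. This is the quantity
#' behind statements like "70.3% of the lipid's surface is buried".
#'
#' @param assembly An [atomic_model()] of the full assembly.
#' @param chains Chain id(s) defining the component.
#' @param context_chains Chains forming the context (default: all chains);
#'   restrict e.g. to protein chains for protein-protein burial only.
#' @param ... Passed to [sasa()].
#' @return List with `total_A2`, `buried_A2`, `fraction`.
#' @export
buried_fraction <- function(assembly, chains, context_chains = NULL, ...) {
  sel <- component_atoms(assembly, chains)
  iso <- sum(sasa(assembly$atoms[sel, ], ...))
  ctx <- if (is.null(context_chains)) rep(TRUE, nrow(assembly$atoms))
         else assembly$atoms$chain %in% union(context_chains, chains)
  within <- sasa(assembly$atoms[ctx, ], ...)
  in_ctx <- sum(within[which(assembly$atoms$chain[ctx] %in% chains)])
  buried <- iso - in_ctx
  list(total_A2 = iso, buried_A2 = buried, fraction = buried / iso)
}

#' Contact neighbors of a component
#'
#' Components are chains. Two criteria are computed: buried-area (a neighbor
#' buries more than `min_buried_A2` of the reference surface; the default
#' definition of "makes contact") and distance (any heavy-atom pair closer
#' than `dist_cutoff_A`).
#'
#' @param assembly An [atomic_model()].
#' @param reference_chain Reference chain id.
#' @param candidate_chains Chains to test (default: all others).
#' @param criterion `"buried"` (default) or `"distance"`.
#' @param min_buried_A2 Buried-area threshold (default 1 A^2).
#' @param dist_cutoff_A Heavy-atom distance cutoff (default 4.0 A).
#' @param ... Passed to [sasa()].
#' @return List with `count`, `neighbors` (chain ids), and the per-chain
#'   `buried_A2` or `min_dist_A` table used.
#' @export
neighbor_count <- function(assembly, reference_chain, candidate_chains = NULL,
                           criterion = c("buried", "distance"),
                           min_buried_A2 = 1, dist_cutoff_A = 4.0, ...) {
  criterion <- match.arg(criterion)
  a <- assembly$atoms
  if (!reference_chain %in% a$chain)
    stop("reference chain absent: ", reference_chain)
  if (is.null(candidate_chains))
    candidate_chains <- setdiff(unique(a$chain), reference_chain)
  ref <- a[a$chain == reference_chain, ]
  ref_xyz <- as.matrix(ref[, c("x", "y", "z")])
  # cheap prefilter: bounding-sphere distance
  mind <- vapply(candidate_chains, function(ch) {
    b <- as.matrix(a[a$chain == ch, c("x", "y", "z")])
    cpp_min_pairdist(ref_xyz, b)[1]
  }, numeric(1))
  if (criterion == "distance") {
    heavy_ok <- mind < dist_cutoff_A
    nb <- candidate_chains[heavy_ok]
    return(list(count = length(nb), neighbors = nb,
                min_dist_A = stats::setNames(mind, candidate_chains)))
  }
  close_ch <- candidate_chains[mind < 12]   # beyond ~2 probe diameters: no burial
  iso <- sum(sasa(ref, ...))
  buried <- vapply(close_ch, function(ch) {
    pair <- a[a$chain %in% c(reference_chain, ch), ]
    s <- sasa(pair, ...)
    iso - sum(s[pair$chain == reference_chain])
  }, numeric(1))
  nb <- close_ch[buried > min_buried_A2]
  tab <- stats::setNames(numeric(length(candidate_chains)), candidate_chains)
  tab[close_ch] <- buried
  list(count = length(nb), neighbors = nb, buried_A2 = tab)
}

#' Per-neighbor buried-surface table for a reference subunit
#'
#' Buried area of the reference chain against each contacting chain, the
#' total buried in protein-protein contacts, and the combined buried
#' fraction of the reference surface once lipid contacts are included.
#' Lipid chains are recognized by residue name (`lipid_resid`).
#'
#' @param assembly An [atomic_model()].
#' @param reference_chain Reference (interior) chain id.
#' @param lipid_resid Residue name(s) identifying lipids (default "PG").
#' @param ... Passed to [sasa()].
#' @return Object of class `"interface_report"`: list with `pairs`
#'   (data.frame chain/type/buried_A2), `total_A2`,
#'   `protein_buried_A2`, `combined_buried_A2`, `combined_fraction`,
#'   `lipid_buried_A2`, `lipid_fraction`.
#' @export
pairwise_buried_table <- function(assembly, reference_chain,
                                  lipid_resid = "PG", ...) {
  a <- assembly$atoms
  nb <- neighbor_count(assembly, reference_chain, ...)
  is_lipid <- vapply(names(nb$buried_A2), function(ch)
    all(a$resid[a$chain == ch] %in% lipid_resid), logical(1))
  pairs <- data.frame(chain = names(nb$buried_A2),
                      type = ifelse(is_lipid, "lipid", "protein"),
                      buried_A2 = as.numeric(nb$buried_A2))
  pairs <- pairs[pairs$buried_A2 > 0, ]
  pairs <- pairs[order(-pairs$buried_A2), ]
  rownames(pairs) <- NULL
  ref_sel <- a$chain == reference_chain
  iso <- sum(sasa(a[ref_sel, ], ...))
  prot_chains <- unique(a$chain)[!vapply(unique(a$chain), function(ch)
    all(a$resid[a$chain == ch] %in% lipid_resid), logical(1))]
  in_prot <- sasa(a[a$chain %in% prot_chains, ], ...)
  prot_buried <- iso - sum(in_prot[a$chain[a$chain %in% prot_chains] ==
                                     reference_chain])
  all_s <- sasa(a, ...)
  comb_buried <- iso - sum(all_s[ref_sel])
  lip_chains <- unique(a$chain)[vapply(unique(a$chain), function(ch)
    all(a$resid[a$chain == ch] %in% lipid_resid), logical(1))]
  lip_ctx <- a$chain %in% c(reference_chain, lip_chains)
  in_lip <- sasa(a[lip_ctx, ], ...)
  lip_buried <- iso - sum(in_lip[a$chain[lip_ctx] == reference_chain])
  structure(list(pairs = pairs, total_A2 = iso,
                 protein_buried_A2 = prot_buried,
                 lipid_buried_A2 = lip_buried,
                 lipid_fraction = lip_buried / iso,
                 combined_buried_A2 = comb_buried,
                 combined_fraction = comb_buried / iso,
                 reference_chain = reference_chain),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface report for chain %s (surface %.0f A2)\n",
              x$reference_chain, x$total_A2))
  cat(sprintf("  buried in protein-protein contacts: %.0f A2 (%.1f%%)\n",
              x$protein_buried_A2, 100 * x$protein_buried_A2 / x$total_A2))
  cat(sprintf("  buried by lipids: %.0f A2 (%.1f%%)\n",
              x$lipid_buried_A2, 100 * x$lipid_fraction))
  cat(sprintf("  combined buried fraction: %.1f%%\n",
              100 * x$combined_fraction))
  cat("  largest pairwise interfaces:\n")
  print(utils::head(x$pairs, 10), row.names = FALSE)
  invisible(x)
}

#' Radial geometry of a filament model
#'
#' Slices the model along z and reports per-slice radial extrema of atom
#' centers, plus aggregate diameters: the lumen diameter (twice the largest
#' empty coaxial cylinder radius over the central slices) and the outer
#' diameter (twice the 99th percentile of per-slice maximal radial extent).
#' Atom-center and van-der-Waals-padded variants are both reported, the
#' measurement convention being otherwise ambiguous.
#'
#' @param model An [atomic_model()] in the canonical frame (axis on z).
#' @param slice_A Slice thickness (default 4 A).
#' @param central_fraction Central z-fraction used for the lumen (default
#'   0.5, avoiding frayed filament ends).
#' @return Object of class `"radial_profile"`: list with `slices`
#'   (data.frame z, r_min, r_max, n_atoms), `lumen_diameter_A`,
#'   `outer_diameter_A`, `lumen_diameter_padded_A`,
#'   `outer_diameter_padded_A`.
#' @export
radial_geometry <- function(model, slice_A = 4, central_fraction = 0.5) {
  a <- model$atoms
  r <- sqrt(a$x^2 + a$y^2)
  vdw <- vdw_radius(a$element)
  zb <- floor(a$z / slice_A)
  if (length(unique(zb)) < 2) stop("fewer than 2 z-slices in model")
  agg <- function(v, f) as.numeric(tapply(v, zb, f))
  slices <- data.frame(z = (sort(unique(zb)) + 0.5) * slice_A,
                       r_min = agg(r, min), r_max = agg(r, max),
                       r_min_padded = agg(r - vdw, min),
                       r_max_padded = agg(r + vdw, max),
                       n_atoms = agg(r, length))
  zr <- range(slices$z)
  zc <- mean(zr) + c(-0.5, 0.5) * central_fraction * diff(zr)
  central <- slices$z >= zc[1] & slices$z <= zc[2]
  if (!any(central)) central <- rep(TRUE, nrow(slices))
  structure(list(
    slices = slices,
    lumen_diameter_A = 2 * min(slices$r_min[central]),
    outer_diameter_A = 2 * stats::quantile(slices$r_max, 0.99, names = FALSE),
    lumen_diameter_padded_A = 2 * max(0, min(slices$r_min_padded[central])),
    outer_diameter_padded_A = 2 * stats::quantile(slices$r_max_padded, 0.99,
                                                  names = FALSE)),
    class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile (%d slices)\n", nrow(x$slices)))
  cat(sprintf("  outer diameter: %.1f A (atom centers), %.1f A (vdW padded)\n",
              x$outer_diameter_A, x$outer_diameter_padded_A))
  cat(sprintf("  lumen diameter: %.1f A (atom centers), %.1f A (vdW padded)\n",
              x$lumen_diameter_A, x$lumen_diameter_padded_A))
  invisible(x)
}
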