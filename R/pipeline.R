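# End-to-end demo workflows: simulation -> reconstruction -> validation and
# unit -> assembly -> analysis, driven by a single plain-text (YAML) config.

default_run_config <- function() {
  list(
    seed = 1L,
    simulation = list(
      twist_deg = 28.2, rise_A = 12.1, cyclic_order = 5L,
      box_px = 96L, voxel_A = 2.0, n_segments = 250L,
      snr = 0.1, defocus_range_um = c(0.5, 3.5),
      template_seed = 7L, n_atoms = 18L),
    reconstruction = list(
      init_twist_deg = 27.0, init_rise_A = 11.5,
      max_iter = 8L, angular_step_deg = 4,
      tol_twist = 0.05, tol_rise = 0.02),
    sorting = list(
      rise_a_A = 12.5, twist_a_deg = 28.1,
      rise_b_A = 13.2, twist_b_deg = 27.9,
      fraction_a = 0.5, n_segments = 200L, n_cycles = 5L),
    building = list(units_per_strand = 16L),
    analysis = list(probe_radius = 1.4, n_sphere_points = 960L,
                    grid_spacing_A = 2))
}

#' Run configuration
#'
#' Reads (or creates) the plain-text configuration driving the demo
#' pipelines. Unknown keys are rejected; values in `overrides` replace file
#' values; every stochastic stage derives its seed from the global `seed`.
#'
#' @param path Optional YAML config path (NULL = package defaults).
#' @param overrides Named list of `section$key` overrides, e.g.
#'   `list(simulation = list(n_segments = 100))`.
#' @return Config list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  merge_into <- function(base, new, where) {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop("unknown config key: ", paste(c(where, k), collapse = "$"))
      if (is.list(base[[k]]) && is.list(new[[k]]))
        base[[k]] <- merge_into(base[[k]], new[[k]], c(where, k))
      else base[[k]] <- new[[k]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path), character())
  if (!is.null(overrides)) cfg <- merge_into(cfg, overrides, character())
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to a YAML file
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# provenance block common to all reports
provenance <- function(cfg, started) {
  list(seed = cfg$seed,
       config_hash = sum(utils::head(utf8ToInt(paste(
         deparse(unclass(cfg)), collapse = "")), 1e5) *
           (seq_len(min(1e5, nchar(paste(deparse(unclass(cfg)),
                                         collapse = "")))) %% 97 + 1)),
       package_version = as.character(utils::packageVersion("helifil")),
       runtime_s = as.numeric(difftime(Sys.time(), started, units = "secs")))
}

#' Demo: simulate a filament data set and reconstruct it
#'
#' Simulates segments of a helical filament under the configured imaging
#' conditions, runs [ihrsr()] from a featureless-cylinder start, and
#' computes a half-map FSC from reconstructions of the even and odd segment
#' halves (both back-projected with the final alignment).
#'
#' @param cfg A [run_config()].
#' @param verbose Print progress.
#' @return Report list: `fit` (the [ihrsr()] object), `symmetry`,
#'   `true_symmetry`, `fsc` curve, `resolution_A` (at 0.143), `provenance`.
#' @export
run_demo_reconstruction <- function(cfg = run_config(), verbose = FALSE) {
  started <- Sys.time()
  sc <- cfg$simulation
  rc <- cfg$reconstruction
  sym_true <- helical_symmetry(sc$twist_deg, sc$rise_A, sc$cyclic_order)
  tmpl <- make_test_subunit(sc$template_seed, sc$n_atoms)
  n_layers <- ceiling(sc$box_px * sc$voxel_A / sc$rise_A) + 4
  vol <- render_volume(tmpl, sym_true, n_layers, sc$box_px, sc$voxel_A,
                       clip_z = TRUE)
  sigma <- noise_sigma_for_snr(vol, sc$snr, acquisition_params())
  stack <- simulate_segment_stack(vol, sc$n_segments,
                                  defocus_range_um = sc$defocus_range_um,
                                  noise_sigma = sigma,
                                  seed = cfg$seed, rise_A = sc$rise_A)
  fit <- ihrsr(stack, helical_symmetry(rc$init_twist_deg, rc$init_rise_A,
                                       sc$cyclic_order),
               max_iter = rc$max_iter, tol_twist = rc$tol_twist,
               tol_rise = rc$tol_rise,
               angular_step_deg = rc$angular_step_deg, verbose = verbose)
  # half-map FSC from even/odd segment splits. Aligning both halves to the
  # same references imprints correlated reference noise into the two maps
  # and inflates their FSC, so after splitting, each half is refined for two
  # further iterations against references made from its own map only.
  idx_e <- seq(1, n_segments(stack), by = 2)
  idx_o <- seq(2, n_segments(stack), by = 2)
  flip <- phase_flip(stack)
  refine_half <- function(idx) {
    sub <- flip[idx]
    v <- symmetrize(backproject(sub, fit$alignment[idx, ]), fit$symmetry)
    for (k in 1:2) {
      refs <- make_references(v, fit$symmetry, rc$angular_step_deg)
      al <- align_segments(sub, refs)
      v <- symmetrize(backproject(sub, al), fit$symmetry)
    }
    v
  }
  half_e <- refine_half(idx_e)
  half_o <- refine_half(idx_o)
  curve <- fsc(half_e, half_o)
  res <- resolution_at_threshold(curve, 0.143)
  # model:map FSC: the model is built in the map's own lattice (the fitted
  # symmetry), as in model building against a reconstruction, then brought
  # onto the map over the helical gauge freedoms
  model_vol <- render_volume(tmpl, fit$symmetry, n_layers, sc$box_px,
                             sc$voxel_A, clip_z = TRUE)
  model_al <- align_volumes(model_vol, fit$volume, fit$symmetry)
  curve_mm <- fsc(fit$volume, model_al)
  res_mm <- resolution_at_threshold(curve_mm, 0.4)
  list(fit = fit, symmetry = fit$symmetry, true_symmetry = sym_true,
       fsc = curve, resolution_A = as.numeric(res),
       fsc_model_map = curve_mm, model_map_resolution_A = as.numeric(res_mm),
       half_maps = list(even = half_e, odd = half_o),
       provenance = provenance(cfg, started))
}

#' Demo: simulate and sort a two-rise mixture
#'
#' Simulates a mixture of segments from two filament forms differing in
#' helical rise, sorts them with [sort_segments()], and reports the
#' confusion matrix against the simulated ground truth.
#'
#' @param cfg A [run_config()].
#' @param verbose Print progress.
#' @return Report list: `sorting` (the [sort_segments()] result),
#'   `confusion`, `accuracy`, `provenance`.
#' @export
run_demo_sorting <- function(cfg = run_config(), verbose = FALSE) {
  started <- Sys.time()
  sc <- cfg$simulation
  so <- cfg$sorting
  sym_a <- helical_symmetry(so$twist_a_deg, so$rise_a_A, sc$cyclic_order)
  sym_b <- helical_symmetry(so$twist_b_deg, so$rise_b_A, sc$cyclic_order)
  tmpl <- make_test_subunit(sc$template_seed, sc$n_atoms)
  ref_vol <- render_volume(tmpl, sym_a,
                           ceiling(sc$box_px * sc$voxel_A / sym_a$rise_A) + 4,
                           sc$box_px, sc$voxel_A, clip_z = TRUE)
  sigma <- noise_sigma_for_snr(ref_vol, sc$snr, acquisition_params())
  stack <- simulate_mixture(tmpl, sym_a, sym_b, so$fraction_a,
                            so$n_segments, sc$box_px, sc$voxel_A,
                            seed = cfg$seed,
                            defocus_range_um = sc$defocus_range_um,
                            noise_sigma = sigma)
  srt <- sort_segments(stack, sym_a, sym_b, n_cycles = so$n_cycles,
                       verbose = verbose)
  conf <- sorting_confusion(srt, stack$meta$class)
  list(sorting = srt, confusion = conf, accuracy = srt$accuracy,
       provenance = provenance(cfg, started))
}

#' Demo: build a filament model and analyze its architecture
#'
#' Builds a full filament from the synthetic pilin+lipid unit and the given
#' helical symmetry, then computes the architectural statistics: radial
#' geometry (outer and lumen diameters), the per-neighbor buried-surface
#' table of an interior subunit, lipid burial, contact counts, and the mean
#' lumen potential with and without lipids.
#'
#' @param cfg A [run_config()].
#' @param unit Optional [atomic_model()] unit (default [make_test_pilin()]).
#' @return Report list with `model`, `geometry`, `interfaces`,
#'   `neighbors`, `lipid_burial`, `potential` (with/without),
#'   `provenance`.
#' @export
run_structure_analysis <- function(cfg = run_config(), unit = NULL) {
  started <- Sys.time()
  sc <- cfg$simulation
  bd <- cfg$building
  an <- cfg$analysis
  sym <- helical_symmetry(sc$twist_deg, sc$rise_A, sc$cyclic_order)
  if (is.null(unit)) unit <- make_test_pilin(cfg$seed)
  if (nrow(unit$atoms) == 0) stop("empty unit model")
  model <- build_filament_model(unit, sym, bd$units_per_strand)
  prot <- interior_protein_chain(model, bd$units_per_strand)
  lip <- sub("^([A-Z])\\.A", "\\1.L", prot)
  geom <- radial_geometry(model)
  tab <- pairwise_buried_table(model, prot,
                               probe_radius = an$probe_radius,
                               n_sphere_points = an$n_sphere_points)
  nb <- neighbor_count(model, prot, probe_radius = an$probe_radius,
                       n_sphere_points = an$n_sphere_points)
  a <- model$atoms
  prot_nb <- nb$neighbors[!vapply(nb$neighbors, function(ch)
    all(a$resid[a$chain == ch] == "PG"), logical(1))]
  lip_burial <- buried_fraction(model, lip, probe_radius = an$probe_radius,
                                n_sphere_points = an$n_sphere_points)
  lip_nb <- neighbor_count(model, lip, probe_radius = an$probe_radius,
                           n_sphere_points = an$n_sphere_points)
  lip_prot_nb <- lip_nb$neighbors[!vapply(lip_nb$neighbors, function(ch)
    all(a$resid[a$chain == ch] == "PG"), logical(1))]
  pot_with <- lumen_potential(model, TRUE, grid_spacing_A = an$grid_spacing_A)
  pot_without <- lumen_potential(model, FALSE,
                                 grid_spacing_A = an$grid_spacing_A)
  list(model = model, geometry = geom, interfaces = tab,
       neighbors = list(protein = prot_nb, count = length(prot_nb),
                        lipid_neighbors_of_lipid = lip_prot_nb,
                        subunits_per_lipid = length(lip_prot_nb)),
       lipid_burial = lip_burial,
       potential = list(with_lipids = pot_with$mean_lumen_potential,
                        without_lipids = pot_without$mean_lumen_potential),
       reference_chain = prot,
       provenance = provenance(cfg, started))
}

# pick an interior protein subunit chain (middle unit of the middle strand)
interior_protein_chain <- function(model, units_per_strand) {
  a <- model$atoms
  prot <- a[a$resid != "PG", ]
  strands <- sort(unique(prot$strand))
  mid_strand <- strands[ceiling(length(strands) / 2)]
  units <- sort(unique(prot$unit[prot$strand == mid_strand]))
  mid_unit <- units[ceiling(length(units) / 2)]
  unique(prot$chain[prot$strand == mid_strand & prot$unit == mid_unit])[1]
}
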