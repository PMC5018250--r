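#' Iterative helical real-space reconstruction (IHRSR)
#'
#' Fits a helically symmetric 3D density and its helical symmetry parameters
#' (twist, rise) to a stack of filament segment images by the IHRSR scheme:
#' starting from an initial volume (a featureless cylinder suffices) and an
#' initial symmetry guess, the loop alternates reference projection,
#' projection matching, filtered back-projection, helical symmetry search
#' and symmetry imposition until the symmetry parameters stop changing.
#'
#' `ihrsr` is the package's central fitting function; the returned object
#' supports `print`, `summary`, `coef` (the fitted twist/rise), `plot`
#' (parameter convergence history), `residuals` (per-segment matching
#' scores) and `simulate` (synthetic segments from the fitted map).
#'
#' @param stack A [segment_stack()] of filament segments; typically
#'   phase-flipped with [phase_flip()] first (done automatically when the
#'   stack carries defocus metadata and `auto_flip = TRUE`).
#' @param init_sym Initial [helical_symmetry()] guess. The search window
#'   (`twist_range`, `rise_range`) must bracket the true parameters.
#' @param init_volume Starting [density_volume()]; default a featureless
#'   soft cylinder of radius `cylinder_radius_A`.
#' @param scan Run a data-driven [symmetry_scan()] over the search window
#'   before the main loop and start from its estimate, with the volume-based
#'   symmetry search then refining in a narrowed window. Default (`NULL`):
#'   scan whenever starting from the featureless cylinder with the symmetry
#'   search enabled, the regime where the loop alone cannot be trusted to
#'   escape a wrong initial lattice.
#' @param max_iter Maximum iterations (0 returns the initial state).
#' @param tol_twist,tol_rise Convergence tolerances on consecutive-iteration
#'   parameter changes (default 0.05 degrees, 0.02 Angstrom).
#' @param angular_step_deg Reference azimuthal sampling (default 4 degrees).
#' @param psi_grid_deg In-plane rotation search grid.
#' @param shift_range_px Alignment shift window `c(x, y)`; default lets the
#'   axial window cover one rise.
#' @param twist_range,rise_range Symmetry search half-windows.
#' @param search_symmetry If FALSE the symmetry is held fixed at `init_sym`
#'   (used e.g. for the unsorted reconstruction seeding two-class sorting).
#' @param search_start_iter First iteration at which the symmetry search is
#'   applied (default 3): early iterations from a featureless start carry no
#'   azimuthal structure yet, and searching them replaces the initial guess
#'   with noise; the symmetry is held at `init_sym` until the map has
#'   developed structure.
#' @param cylinder_radius_A Radius of the default initial cylinder.
#' @param auto_flip Phase-flip the stack first when CTF metadata is present.
#' @param verbose Print per-iteration progress.
#' @return Object of class `"ihrsr"`: list with `volume` (symmetrized
#'   [density_volume()]), `symmetry` (fitted [helical_symmetry()]),
#'   `history` (per-iteration twist/rise/mean score), `alignment` (last
#'   [align_segments()] table), `converged`, `iterations`.
#' @export
ihrsr <- function(stack, init_sym, init_volume = NULL, scan = NULL,
                  max_iter = 10,
                  tol_twist = 0.05, tol_rise = 0.02,
                  angular_step_deg = 4,
                  psi_grid_deg = c(-4, -2, 0, 2, 4),
                  shift_range_px = NULL,
                  twist_range = 2, rise_range = 1,
                  search_symmetry = TRUE, search_start_iter = 3,
                  cylinder_radius_A = 45, auto_flip = TRUE,
                  verbose = FALSE) {
  stopifnot(inherits(stack, "segment_stack"),
            inherits(init_sym, "helical_symmetry"))
  d <- dim(stack$images)
  vx <- stack$pixel_size_A
  if (auto_flip && !isTRUE(stack$ctf_weighted) &&
      !is.null(stack$meta$defocus_A))
    stack <- phase_flip(stack)
  cold_start <- is.null(init_volume)
  if (is.null(init_volume)) {
    n <- d[1]
    cc <- (seq_len(n) - (n + 1) / 2) * vx
    r <- sqrt(outer(cc^2, cc^2, "+"))
    disk <- 1 / (1 + exp((r - cylinder_radius_A) / (2 * vx)))  # soft edge
    init_volume <- density_volume(array(rep(disk, d[2]), c(n, n, d[2])), vx)
  }
  if (is.null(shift_range_px))
    shift_range_px <- c(4, ceiling(init_sym$rise_A / vx) + 3)
  do_scan <- isTRUE(scan) ||
    (is.null(scan) && search_symmetry && cold_start && max_iter > 0)
  if (do_scan) {
    if (verbose) message("symmetry scan over the search window...")
    init_sym <- symmetry_scan(stack, init_sym, twist_range, rise_range,
                              verbose = verbose)
    twist_range <- min(twist_range, 0.6)
    rise_range <- min(rise_range, 0.3)
    search_start_iter <- max(search_start_iter, 4L)
    if (verbose)
      message(sprintf("scan estimate: twist %.2f deg, rise %.2f A",
                      init_sym$twist_deg, init_sym$rise_A))
  }
  sym <- init_sym
  vol <- init_volume
  hist <- data.frame(iteration = 0L, twist_deg = sym$twist_deg,
                     rise_A = sym$rise_A, mean_score = NA_real_)
  converged <- FALSE
  align <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sym_vol <- symmetrize(vol, sym)
    refs <- make_references(sym_vol, sym, angular_step_deg)
    align <- align_segments(stack, refs, shift_range_px, psi_grid_deg)
    vol <- backproject(stack, align)
    at_edge <- FALSE
    if (search_symmetry && it >= search_start_iter) {
      # the window stays centered on the initial guess (which must bracket
      # the true parameters); a mild low-pass stabilizes the residual
      # surface against back-projection noise
      new_sym <- symmetry_search(vol, init_sym, twist_range, rise_range,
                                 lowpass_sigma_vox = 1)
      if (isTRUE(attr(new_sym, "degenerate")))
        warning("symmetry search degenerate at iteration ", it)
      at_edge <- min(abs(new_sym$twist_deg -
                           (init_sym$twist_deg + c(-1, 1) * twist_range))) < 1e-6 ||
        min(abs(new_sym$rise_A -
                  (init_sym$rise_A + c(-1, 1) * rise_range))) < 1e-6
      # a minimum pinned to the window boundary is a noise artifact, not a
      # refinement; keep the current symmetry in that case
      if (at_edge) new_sym <- sym
    } else new_sym <- sym
    d_twist <- abs(new_sym$twist_deg - sym$twist_deg)
    d_rise <- abs(new_sym$rise_A - sym$rise_A)
    sym <- new_sym
    vol <- symmetrize(vol, sym)
    hist <- rbind(hist, data.frame(iteration = it, twist_deg = sym$twist_deg,
                                   rise_A = sym$rise_A,
                                   mean_score = mean(align$score)))
    if (verbose)
      message(sprintf("iter %2d: twist %.3f deg, rise %.3f A, score %.3f",
                      it, sym$twist_deg, sym$rise_A, mean(align$score)))
    if (search_symmetry && it > search_start_iter &&
        d_twist < tol_twist && d_rise < tol_rise) {
      converged <- TRUE
      break
    }
    if (!search_symmetry && it >= max_iter) break
  }
  structure(list(volume = vol, symmetry = sym, history = hist,
                 alignment = align, converged = converged, iterations = it,
                 n_segments = d[3], pixel_size_A = vx,
                 init_sym = init_sym, call = match.call()),
            class = "ihrsr")
}

#' @export
print.ihrsr <- function(x, ...) {
  cat("Iterative helical real-space reconstruction\n")
  cat(sprintf("  %d segments, %d iterations, %s\n", x$n_segments,
              x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  fitted symmetry: twist %.3f deg, rise %.3f A (C%d)\n",
              x$symmetry$twist_deg, x$symmetry$rise_A,
              x$symmetry$cyclic_order))
  invisible(x)
}

#' @export
coef.ihrsr <- function(object, ...) {
  c(twist_deg = object$symmetry$twist_deg, rise_A = object$symmetry$rise_A)
}

#' @export
summary.ihrsr <- function(object, ...) {
  out <- list(coef = coef(object), converged = object$converged,
              iterations = object$iterations, history = object$history,
              n_segments = object$n_segments,
              mean_score = if (!is.null(object$alignment))
                mean(object$alignment$score) else NA_real_,
              subunits_per_turn = subunits_per_turn(object$symmetry))
  class(out) <- "summary.ihrsr"
  out
}

#' @export
print.summary.ihrsr <- function(x, ...) {
  cat("IHRSR fit summary\n")
  cat(sprintf("  segments: %d   iterations: %d   converged: %s\n",
              x$n_segments, x$iterations, x$converged))
  cat(sprintf("  twist: %.3f deg   rise: %.3f A   (%.2f subunits/turn)\n",
              x$coef[1], x$coef[2], x$subunits_per_turn))
  cat(sprintf("  mean matching score: %.3f\n", x$mean_score))
  cat("  convergence history:\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ihrsr <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$iteration, h$twist_deg, type = "b", xlab = "iteration",
                 ylab = "twist (deg)", main = "Twist convergence", ...)
  graphics::plot(h$iteration, h$rise_A, type = "b", xlab = "iteration",
                 ylab = "rise (A)", main = "Rise convergence", ...)
  invisible(x)
}

#' @export
residuals.ihrsr <- function(object, ...) {
  if (is.null(object$alignment)) return(numeric(0))
  1 - object$alignment$score
}

#' Simulate segments from a fitted reconstruction
#'
#' Draws synthetic noisy segments from the fitted (symmetrized) map, using
#' the fitted helical rise for the axial offset distribution — a parametric-
#' bootstrap companion to [ihrsr()].
#'
#' @param object An [ihrsr()] fit.
#' @param nsim Number of segments.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_segment_stack()].
#' @return A [segment_stack()].
#' @export
simulate.ihrsr <- function(object, nsim = 100, seed = 1, ...) {
  simulate_segment_stack(object$volume, nsim, seed = seed,
                         rise_A = object$symmetry$rise_A, ...)
}
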