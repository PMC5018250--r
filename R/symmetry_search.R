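# Helical symmetry search and imposition on density volumes.

#' Search for the helical twist and rise of a volume
#'
#' Finds the (twist, rise) minimizing the mean squared difference between
#' the volume and its screw-transformed copy, evaluated inside an interior
#' cylindrical mask (avoiding box-edge effects), by a coarse grid scan
#' followed by Nelder-Mead refinement. The cyclic order is taken from
#' `init_sym`; use [compare_cyclic_orders()] to decide the point group.
#'
#' @param volume A [density_volume()].
#' @param init_sym Starting [helical_symmetry()] (search center).
#' @param twist_range Half-width of the twist search window (degrees,
#'   default 2).
#' @param rise_range Half-width of the rise search window (Angstrom,
#'   default 1).
#' @param grid Coarse grid steps `c(twist_deg, rise_A)` (default 0.25, 0.1).
#' @param mask_radii_A Cylindrical mask inner/outer radii (default 5-45 A).
#' @return A [helical_symmetry()] with attributes `residual` (normalized
#'   symmetrization residual at the optimum) and `degenerate` (TRUE for a
#'   featureless volume, in which case the input symmetry is returned).
#' @export
symmetry_search <- function(volume, init_sym, twist_range = 2, rise_range = 1,
                            grid = c(0.25, 0.1), mask_radii_A = c(5, 45),
                            lowpass_sigma_vox = 0) {
  stopifnot(inherits(volume, "density_volume"),
            inherits(init_sym, "helical_symmetry"))
  if (lowpass_sigma_vox > 0)
    volume <- lowpass_volume(volume, lowpass_sigma_vox)
  d <- vol_dim(volume)
  v <- as.numeric(volume$data)
  vx <- volume$voxel_A
  rmin <- mask_radii_A[1] / vx
  rmax <- min(mask_radii_A[2] / vx, (d[1] - 1) / 2)
  lo <- c(init_sym$twist_deg - twist_range,
          max(0.2, init_sym$rise_A - rise_range))
  hi <- c(init_sym$twist_deg + twist_range, init_sym$rise_A + rise_range)
  # objective: symmetrization MSE normalized by the signal power of the
  # compared region, so that different rises (different overlap regions)
  # are comparable
  resid <- function(p) {
    p <- pmin(pmax(p, lo), hi)
    r <- cpp_screw_residual(v, d, p[1], p[2] / vx, rmin, rmax)
    r[1] / r[3]
  }
  sig <- cpp_screw_residual(v, d, init_sym$twist_deg, init_sym$rise_A / vx,
                            rmin, rmax)[3]
  # featureless (constant) volumes carry no symmetry information
  if (!is.finite(sig) || stats::var(v) < 1e-16 * (mean(v)^2 + 1e-12)) {
    out <- init_sym
    attr(out, "degenerate") <- TRUE
    attr(out, "residual") <- NA_real_
    return(out)
  }
  tw <- seq(lo[1], hi[1], by = grid[1])
  ri <- seq(lo[2], hi[2], by = grid[2])
  gr <- as.matrix(expand.grid(twist = tw, rise = ri))
  vals <- apply(gr, 1, resid)
  p0 <- unname(gr[which.min(vals), ])
  opt <- stats::optim(p0, resid, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 200))
  par <- pmin(pmax(opt$par, lo), hi)
  out <- helical_symmetry(par[1], par[2], init_sym$cyclic_order)
  attr(out, "residual") <- opt$value
  attr(out, "degenerate") <- FALSE
  out
}

#' Compare candidate cyclic (point group) orders of a volume
#'
#' Computes, for each candidate n, the normalized mean squared difference
#' between the volume and its copy rotated by 360/n about the helix axis.
#' The correct point group gives a markedly lower residual (the analogue of
#' choosing the rotational symmetry that yields interpretable features).
#'
#' @param volume A [density_volume()].
#' @param orders Integer vector of candidate cyclic orders.
#' @param mask_radii_A Cylindrical mask radii (Angstrom).
#' @return data.frame with `cyclic_order` and `residual` (lower = better).
#' @export
compare_cyclic_orders <- function(volume, orders = 2:7,
                                  mask_radii_A = c(5, 45)) {
  d <- vol_dim(volume)
  v <- as.numeric(volume$data)
  vx <- volume$voxel_A
  rmin <- mask_radii_A[1] / vx
  rmax <- min(mask_radii_A[2] / vx, (d[1] - 1) / 2)
  res <- vapply(orders, function(n) {
    r <- cpp_screw_residual(v, d, 360 / n, 0, rmin, rmax)
    r[1] / r[3]
  }, numeric(1))
  data.frame(cyclic_order = orders, residual = res)
}

#' Impose helical symmetry on a volume
#'
#' Averages the volume over its helical lattice operations (all Cn rotations
#' combined with screw powers whose axial shift stays inside the box), with
#' per-voxel weighting by the number of in-bounds samples. The output is
#' invariant under the imposed screw and Cn operations up to interpolation
#' error, and re-symmetrizing is idempotent.
#'
#' @param volume A [density_volume()].
#' @param sym [helical_symmetry()] to impose.
#' @param layer_span Screw powers `-layer_span .. layer_span` to average;
#'   default covers half the box height.
#' @return A symmetrized [density_volume()].
#' @export
symmetrize <- function(volume, sym, layer_span = NULL) {
  stopifnot(inherits(volume, "density_volume"),
            inherits(sym, "helical_symmetry"))
  d <- vol_dim(volume)
  rise_vox <- sym$rise_A / volume$voxel_A
  if (is.null(layer_span))
    layer_span <- max(1L, floor((d[3] - 1) / (2 * rise_vox)))
  out <- cpp_symmetrize(as.numeric(volume$data), d, sym$twist_deg, rise_vox,
                        sym$cyclic_order, as.integer(layer_span))
  density_volume(array(out, d), volume$voxel_A, volume$origin)
}

#' Real-space correlation between a volume and a transformed copy of itself
#'
#' Convenience check of symmetry invariance: correlation between `volume`
#' and its copy rotated by `twist_deg` about z and shifted by `rise_A`
#' along z, over in-bounds voxels inside a cylindrical mask.
#'
#' @param volume A [density_volume()].
#' @param twist_deg Rotation (degrees).
#' @param rise_A Axial shift (Angstrom).
#' @param mask_radii_A Cylindrical mask radii.
#' @param lowpass_sigma_vox Optional Gaussian low-pass (real-space sigma in
#'   voxels) applied before comparison: trilinear resampling attenuates
#'   content near Nyquist, so invariance of noisy maps is meaningfully
#'   assessed on their band-limited content.
#' @return Pearson correlation.
#' @export
screw_self_correlation <- function(volume, twist_deg, rise_A,
                                   mask_radii_A = c(0, Inf),
                                   lowpass_sigma_vox = NULL) {
  if (!is.null(lowpass_sigma_vox))
    volume <- lowpass_volume(volume, lowpass_sigma_vox)
  d <- vol_dim(volume)
  vx <- volume$voxel_A
  rise_vox <- rise_A / vx
  a <- rot_z(-twist_deg)   # inverse map for resampling
  moved <- cpp_affine_sample(as.numeric(volume$data), d, a,
                             c(0, 0, -rise_vox))
  # build masks: voxels whose source sample was in bounds
  idx <- array(seq_len(prod(d)), d)
  zsrc <- (seq_len(d[3]) - (d[3] + 1) / 2) - rise_vox
  zok <- zsrc >= -(d[3] - 1) / 2 & zsrc <= (d[3] - 1) / 2
  cx <- (seq_len(d[1]) - (d[1] + 1) / 2) * vx
  r2 <- outer(cx^2, cx^2, "+")
  rok <- r2 >= mask_radii_A[1]^2 & r2 <= min(mask_radii_A[2],
                                             (d[1] - 1) / 2 * vx)^2
  keep <- idx[rep(rok, d[3]) & rep(zok, each = d[1] * d[2])]
  stats::cor(as.numeric(volume$data)[keep], moved[keep])
}

#' Gaussian low-pass filter a volume
#'
#' @param volume A [density_volume()].
#' @param sigma_vox Real-space Gaussian sigma in voxels.
#' @return Filtered [density_volume()].
#' @export
lowpass_volume <- function(volume, sigma_vox) {
  d <- vol_dim(volume)
  fr <- lapply(d, function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n)
  s2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  g <- exp(-2 * pi^2 * sigma_vox^2 * s2)
  out <- Re(stats::fft(stats::fft(volume$data) * g, inverse = TRUE)) / prod(d)
  density_volume(array(out, d), volume$voxel_A, volume$origin)
}

#' Score-based helical symmetry scan
#'
#' Investigates candidate helical symmetries by the criterion that the
#' correct one yields a self-consistent reconstruction: for each candidate
#' (twist, rise) a short fixed-symmetry reconstruction is run from a
#' featureless cylinder and the candidate is scored by the mean projection-
#' matching correlation of its final alignment. The scan is performed on
#' 2x-binned segments for speed (the layer-line band that discriminates the
#' lattice lies well below the binned Nyquist frequency). A coordinate scan
#' (rise first, then twist, each refined by parabolic interpolation of the
#' score peak) covers the search window.
#'
#' @param stack A [segment_stack()] (phase-flipped or raw + CTF metadata).
#' @param init_sym Window center [helical_symmetry()].
#' @param twist_range,rise_range Half-widths of the search window.
#' @param twist_step,rise_step Scan steps (default 1 degree, 0.4 A).
#' @param n_scan Number of segments used (default up to 96).
#' @param n_iter Mini-reconstruction iterations per candidate (default 3).
#' @param bin Fourier-crop binning factor for the scan (default 2).
#' @param verbose Print per-candidate scores.
#' @return A [helical_symmetry()] estimate with attribute `scan`
#'   (data.frame of twist, rise, score for all candidates tried).
#' @export
symmetry_scan <- function(stack, init_sym, twist_range = 2, rise_range = 1,
                          twist_step = 1.0, rise_step = 0.4,
                          n_scan = 96, n_iter = 3, bin = 2L,
                          verbose = FALSE) {
  stopifnot(inherits(stack, "segment_stack"))
  if (!isTRUE(stack$ctf_weighted) && !is.null(stack$meta$defocus_A))
    stack <- phase_flip(stack)
  sub <- stack[seq_len(min(n_scan, n_segments(stack)))]
  if (bin > 1L) sub <- downsample_stack(sub, bin)
  vx <- sub$pixel_size_A
  score_of <- function(tw, ri) {
    fit <- ihrsr(sub, helical_symmetry(tw, ri, init_sym$cyclic_order),
                 max_iter = n_iter, search_symmetry = FALSE,
                 auto_flip = FALSE, psi_grid_deg = c(-3, 0, 3),
                 shift_range_px = c(3, ceiling(ri / vx) + 2))
    mean(fit$alignment$score)
  }
  tried <- data.frame()
  note <- function(tw, ri, sc) {
    tried <<- rbind(tried, data.frame(twist = tw, rise = ri, score = sc))
    if (verbose) message(sprintf("  scan twist %.2f rise %.2f: score %.4f",
                                 tw, ri, sc))
  }
  peak <- function(x, s) {
    # parabolic interpolation around the argmax (clamped to the grid range)
    i <- which.max(s)
    if (i == 1 || i == length(x)) return(x[i])
    denom <- s[i - 1] - 2 * s[i] + s[i + 1]
    if (abs(denom) < 1e-12) return(x[i])
    off <- 0.5 * (s[i - 1] - s[i + 1]) / denom
    x[i] + max(-1, min(1, off)) * (x[2] - x[1])
  }
  scan_axis <- function(tw0, ri0, axis, half, step) {
    if (axis == "rise") {
      g <- seq(max(init_sym$rise_A - rise_range, ri0 - half),
               min(init_sym$rise_A + rise_range, ri0 + half), by = step)
      s <- vapply(g, function(r) {
        sc <- score_of(tw0, r); note(tw0, r, sc); sc
      }, numeric(1))
    } else {
      g <- seq(max(init_sym$twist_deg - twist_range, tw0 - half),
               min(init_sym$twist_deg + twist_range, tw0 + half), by = step)
      s <- vapply(g, function(t) {
        sc <- score_of(t, ri0); note(t, ri0, sc); sc
      }, numeric(1))
    }
    peak(g, s)
  }
  # coarse rise -> coarse twist -> fine rise -> fine twist
  ri_best <- scan_axis(init_sym$twist_deg, init_sym$rise_A, "rise",
                       rise_range, rise_step)
  tw_best <- scan_axis(init_sym$twist_deg, ri_best, "twist",
                       twist_range, twist_step)
  ri_best <- scan_axis(tw_best, ri_best, "rise", rise_step, rise_step / 2)
  tw_best <- scan_axis(tw_best, ri_best, "twist", twist_step, twist_step / 2)
  out <- helical_symmetry(tw_best, ri_best, init_sym$cyclic_order)
  attr(out, "scan") <- tried
  out
}

#' Align one volume to another over the helical gauge freedoms
#'
#' A helical reconstruction is determined only up to a global rotation about
#' the helix axis and a global axial shift. This utility finds the (phi, dz)
#' maximizing the real-space correlation between `volume` (transformed) and
#' `reference`, by a coarse grid scan plus local refinement, and returns the
#' transformed volume.
#'
#' @param volume A [density_volume()] to be rotated/shifted.
#' @param reference The target [density_volume()] (same grid).
#' @param sym Optional [helical_symmetry()]: restricts the rotation scan to
#'   one asymmetric unit and the shift to one rise (the rest is redundant).
#' @param phi_step_deg Rotation scan step (default 2).
#' @param dz_step_vox Axial scan step in voxels (default 0.25).
#' @return The aligned [density_volume()], with attributes `phi_deg`,
#'   `dz_vox` and `correlation`.
#' @export
align_volumes <- function(volume, reference, sym = NULL, phi_step_deg = 2,
                          dz_step_vox = 0.25) {
  stopifnot(identical(vol_dim(volume), vol_dim(reference)))
  d <- vol_dim(volume)
  v <- as.numeric(volume$data)
  ref <- as.numeric(reference$data)
  phi_max <- if (is.null(sym)) 360 else 360 / sym$cyclic_order
  dz_max <- if (is.null(sym)) d[3] / 4 else sym$rise_A / volume$voxel_A
  moved <- function(p) {
    cpp_affine_sample(v, d, rot_z(-p[1]), c(0, 0, -p[2]))
  }
  score <- function(p) stats::cor(moved(p), ref)
  grid <- expand.grid(phi = seq(0, phi_max - phi_step_deg, by = phi_step_deg),
                      dz = seq(-dz_max / 2, dz_max / 2, by = dz_step_vox))
  sc <- apply(grid, 1, score)
  p0 <- unname(as.numeric(grid[which.max(sc), ]))
  opt <- stats::optim(p0, function(p) -score(p), method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 100))
  out <- density_volume(array(moved(opt$par), d), volume$voxel_A,
                        volume$origin)
  attr(out, "phi_deg") <- opt$par[1]
  attr(out, "dz_vox") <- opt$par[2]
  attr(out, "correlation") <- -opt$value
  out
}
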