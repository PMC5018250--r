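# Pseudo-atomic subunit templates for the synthetic filament generator.
#
# The template is a proxy for one pilin(+lipid) unit: three short rod-like
# clusters of isotropic Gaussians emulating the three alpha-helices of the
# subunit, sized to the real protein (~25 A long, placed so the filament
# spans radii ~14-43 A, i.e. a ~28 A lumen and ~87 A outer diameter).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Generate a pseudo-atomic test subunit
#'
#' Builds a deterministic, internally asymmetric pseudo-atomic subunit for
#' synthetic filament simulations: `n_atoms` Gaussian scatterers arranged as
#' three short rod-like clusters (an alpha-helix proxy) within roughly a
#' 25 x 15 x 15 Angstrom envelope, offset from the helix axis so that a
#' rendered filament reproduces the radial extent of a conjugative pilus.
#'
#' @param seed Integer seed; the same seed always returns the same template.
#' @param n_atoms Number of pseudo-atoms (>= 10, default 18).
#' @param radius_A Radial offset of the template centroid from the helix
#'   axis (Angstrom, default 28).
#' @param width_A Gaussian sigma of each pseudo-atom (default 2.2 A).
#' @return Object of class `"subunit_template"`: list with `atoms`
#'   (n x 3 matrix, Angstrom), `amplitude`, `width_A`, `seed`.
#' @export
make_test_subunit <- function(seed, n_atoms = 18L, radius_A = 28,
                              width_A = 2.2) {
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 10L) stop("n_atoms must be >= 10")
  atoms <- with_seed(seed, {
    # three rods with distinct, non-symmetric directions and lengths
    dirs <- rbind(c(0.90, 0.25, 0.35),   # long, mostly radial
                  c(0.75, -0.45, -0.30),
                  c(0.55, 0.35, -0.70))
    dirs <- dirs + matrix(stats::runif(9, -0.08, 0.08), 3, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    lens <- c(24, 15, 12) * stats::runif(3, 0.92, 1.08)
    starts <- rbind(c(-12, -3, -4), c(-9, 5, 2), c(-6, -5, 5)) +
      matrix(stats::runif(9, -1.5, 1.5), 3, 3)
    per <- diff(round(seq(0, n_atoms, length.out = 4)))
    pts <- do.call(rbind, lapply(1:3, function(r) {
      f <- seq(0, 1, length.out = per[r])
      sweep(outer(f * lens[r], dirs[r, ]), 2, starts[r, ], "+") +
        matrix(stats::rnorm(per[r] * 3, sd = 0.6), per[r], 3)
    }))
    pts
  })
  atoms <- sweep(atoms, 2, colMeans(atoms))         # center
  atoms[, 1] <- atoms[, 1] + radius_A               # offset from helix axis
  structure(list(atoms = atoms, amplitude = rep(1, nrow(atoms)),
                 width_A = width_A, seed = seed),
            class = "subunit_template")
}

#' @export
print.subunit_template <- function(x, ...) {
  ext <- apply(x$atoms, 2, function(v) diff(range(v)))
  cat(sprintf("Subunit template: %d pseudo-atoms (sigma %.2f A), extent %.1f x %.1f x %.1f A\n",
              nrow(x$atoms), x$width_A, ext[1], ext[2], ext[3]))
  invisible(x)
}

#' Best self-superposition RMSD over a rotation grid
#'
#' Exhaustively rotates the (centered) template over a grid of rotations with
#' angle at least `min_angle_deg` and reports the smallest RMSD between the
#' rotated and original point sets under nearest-point matching. Large values
#' confirm the template has no internal rotational symmetry, which the
#' reconstruction tests rely on.
#'
#' @param template A [make_test_subunit()] template.
#' @param min_angle_deg Smallest rotation angle considered nontrivial.
#' @param n_axis Number of axis directions sampled.
#' @param angle_step_deg Rotation-angle grid step.
#' @return Minimum nearest-point RMSD (Angstrom) over the grid.
#' @export
template_self_symmetry_rmsd <- function(template, min_angle_deg = 30,
                                        n_axis = 40, angle_step_deg = 30) {
  pts <- sweep(template$atoms, 2, colMeans(template$atoms))
  angs <- seq(min_angle_deg, 180, by = angle_step_deg)
  # quasi-uniform axes (golden spiral)
  i <- seq_len(n_axis) - 0.5
  z <- 1 - 2 * i / n_axis
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  axes <- cbind(r * cos(th), r * sin(th), z)
  best <- Inf
  for (a in seq_len(n_axis)) {
    for (ang in angs) {
      rot <- screw_compose_axis(axes[a, ], ang, 0)$rotation
      q <- pts %*% t(rot)
      d2 <- vapply(seq_len(nrow(pts)), function(j) {
        min(colSums((t(pts) - q[j, ])^2))
      }, numeric(1))
      best <- min(best, sqrt(mean(d2)))
    }
  }
  best
}

#' Render a helical filament density volume from a subunit template
#'
#' Places copies of the template at every lattice transform of
#' [layer_transforms()] and renders the sum of isotropic Gaussians on a cubic
#' voxel grid. The filament axis lies on the box z-axis through the box
#' center; the layer stack is centered axially.
#'
#' @param template A [make_test_subunit()] template.
#' @param sym [helical_symmetry()] lattice parameters.
#' @param n_layers Number of layers to render (0 gives an empty box).
#' @param box_px Cubic box edge (voxels).
#' @param voxel_A Voxel size (Angstrom).
#' @param clip_z If TRUE, atoms beyond the box in z are silently clipped,
#'   which renders a helically continuous filament spanning the whole box —
#'   the appropriate forward model for segments of long filaments. If FALSE
#'   (default), an assembly extending past the box edge is an error.
#' @return A [density_volume()].
#' @export
render_volume <- function(template, sym, n_layers, box_px, voxel_A,
                          clip_z = FALSE) {
  stopifnot(inherits(template, "subunit_template"))
  box_px <- as.integer(box_px)
  dims <- c(box_px, box_px, box_px)
  if (n_layers == 0)
    return(density_volume(array(0, dims), voxel_A))
  tr <- layer_transforms(sym, n_layers)
  z_span <- (n_layers - 1) * sym$rise_A
  all_pts <- do.call(rbind, lapply(tr, function(g) {
    p <- apply_screw(g, template$atoms)
    p[, 3] <- p[, 3] - z_span / 2       # center the stack axially
    p
  }))
  half <- (box_px - 1) / 2 * voxel_A
  margin <- 3 * template$width_A
  over_xy <- max(abs(all_pts[, 1:2])) + margin - half
  over_z <- max(abs(all_pts[, 3])) + margin - half
  if (over_xy > 0)
    stop(sprintf("assembly exceeds box radially by %.1f A", over_xy))
  if (!clip_z && over_z > 0)
    stop(sprintf("assembly exceeds box axially by %.1f A", over_z))
  centers <- sweep(all_pts / voxel_A, 2, (dims - 1) / 2, "+")
  n_copy <- length(tr)
  arr <- cpp_render_gauss(dims, centers,
                          rep(template$amplitude, n_copy),
                          rep(template$width_A / voxel_A, nrow(centers)))
  # cpp_render_gauss normalizes to unit integral per atom in voxel units;
  # amplitude is therefore the per-atom integrated density
  density_volume(array(arr, dims), voxel_A)
}

#' Project a volume along a viewing direction
#'
#' Line-integral projection of a cubic volume viewed at azimuth `azimuth_deg`
#' about the helix (z) axis and out-of-plane tilt `tilt_deg` (90 degrees =
#' viewing direction in the xy plane, the helical-specimen geometry), then
#' in-plane rotation by `inplane_deg` and shift by `shift_px` pixels.
#' Rotating the volume by phi about z is equivalent to increasing the
#' azimuth by phi. Projection values are sums along the ray in voxel steps,
#' so the image integral equals the volume integral.
#'
#' @param volume A [density_volume()].
#' @param azimuth_deg Azimuthal viewing angle (degrees).
#' @param tilt_deg Out-of-plane tilt (degrees, default 90).
#' @param inplane_deg In-plane (psi) rotation of the image (degrees).
#' @param shift_px Length-2 image shift in pixels.
#' @return A square image matrix (u along rows, z along columns).
#' @export
project_volume <- function(volume, azimuth_deg, tilt_deg = 90,
                           inplane_deg = 0, shift_px = c(0, 0)) {
  stopifnot(inherits(volume, "density_volume"))
  d <- vol_dim(volume)
  stopifnot(length(unique(d)) == 1)
  rot <- rot_z(azimuth_deg) %*% rot_x(tilt_deg - 90)
  img <- cpp_project(as.numeric(volume$data), d, rot)
  if (inplane_deg != 0 || any(shift_px != 0))
    img <- cpp_image_transform(img, inplane_deg, shift_px[1], shift_px[2])
  img
}
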