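#' Helical symmetry parameters
#'
#' A helical filament lattice is generated by a screw operation (rotation by
#' `twist_deg` about the helix axis plus translation by `rise_A` along it)
#' together with an n-fold cyclic point group Cn acting about the same axis.
#' The conjugative pilus studied by this package is a C5 filament with a
#' twist near 28 degrees and a rise of 12-13 Angstrom, equivalently described
#' as five-start helical strands or as stacked pentamer layers.
#'
#' Conventions: the helix axis is +z, angles are in degrees, rotations are
#' right-handed about +z, and a positive twist denotes a right-handed helix.
#'
#' @param twist_deg Signed rotation between successive layers (degrees).
#'   The sign encodes handedness. Must satisfy `0 < abs(twist_deg) <= 360`.
#' @param rise_A Axial translation between successive layers (Angstrom, > 0).
#' @param cyclic_order Integer order n of the Cn point group (>= 1).
#' @return An object of class `"helical_symmetry"`.
#' @examples
#' helical_symmetry(28.2, 12.1, 5)
#' @export
helical_symmetry <- function(twist_deg, rise_A, cyclic_order = 1L) {
  stopifnot(is.numeric(twist_deg), length(twist_deg) == 1L, is.finite(twist_deg))
  stopifnot(is.numeric(rise_A), length(rise_A) == 1L, is.finite(rise_A))
  if (rise_A <= 0) stop("rise_A must be > 0")
  if (abs(twist_deg) <= 0 || abs(twist_deg) > 360)
    stop("twist_deg must satisfy 0 < |twist| <= 360")
  cyclic_order <- as.integer(cyclic_order)
  if (is.na(cyclic_order) || cyclic_order < 1L) stop("cyclic_order must be >= 1")
  structure(list(twist_deg = twist_deg, rise_A = rise_A,
                 cyclic_order = cyclic_order),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry: twist %.4g deg, rise %.4g A, C%d point group\n",
              x$twist_deg, x$rise_A, x$cyclic_order))
  cat(sprintf("  %s-handed helix, %.3f subunits per strand turn, pitch %.1f A\n",
              if (x$twist_deg > 0) "right" else "left",
              subunits_per_turn(x), subunits_per_turn(x) * x$rise_A))
  invisible(x)
}

#' Subunits per helical turn of one strand
#'
#' The number of subunits completing one full 360-degree turn of a single
#' helical strand, `360 / abs(twist_deg)`. For a twist of 28.2 degrees this
#' is about 12.8 pilins per turn.
#'
#' @param sym A [helical_symmetry()] object.
#' @return Subunits per turn (numeric scalar).
#' @export
subunits_per_turn <- function(sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (abs(sym$twist_deg) == 0) stop("twist is zero; subunits per turn undefined")
  360 / abs(sym$twist_deg)
}

# rotation about +z by theta degrees (right-handed)
rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}

#' Lattice transforms for a stack of layers
#'
#' Generates the rigid transform placing subunit (layer i, strand k) of a
#' helical lattice, for `i = 0 .. n_layers - 1` and `k = 0 .. cn - 1`:
#' rotation about z by `i * twist + k * 360 / cn` and translation
#' `i * rise` along z. Layer 0 / strand 0 is the identity; the layer index
#' increases toward +z.
#'
#' @param sym A [helical_symmetry()] object.
#' @param n_layers Number of layers (>= 1).
#' @return A list of [screw_transform()] objects with attributes `layer` and
#'   `strand` on each element; length `n_layers * cyclic_order`.
#' @export
layer_transforms <- function(sym, n_layers) {
  stopifnot(inherits(sym, "helical_symmetry"))
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 1L) stop("n_layers must be >= 1")
  out <- vector("list", n_layers * sym$cyclic_order)
  m <- 0L
  for (i in seq_len(n_layers) - 1L) {
    for (k in seq_len(sym$cyclic_order) - 1L) {
      m <- m + 1L
      tr <- screw_transform(rot_z(i * sym$twist_deg + k * 360 / sym$cyclic_order),
                            c(0, 0, i * sym$rise_A))
      attr(tr, "layer") <- i
      attr(tr, "strand") <- k
      out[[m]] <- tr
    }
  }
  out
}

#' Equivalence of the layer-stack and n-start strand lattice descriptions
#'
#' A Cn helical filament can be described either as stacked Cn layers, each
#' related to the next by (twist, rise), or as n interleaved helical strands,
#' strand k phased by `k * 360 / n` in azimuth with per-subunit generator
#' (twist, rise). This function generates the subunit reference points both
#' ways and tests whether the two point sets coincide.
#'
#' @param sym A [helical_symmetry()] object.
#' @param n_layers Number of layers / subunits per strand to generate.
#' @param ref_point Off-axis reference point marking a subunit (Angstrom).
#' @param phase_offsets_deg Optional per-strand azimuthal phase perturbations
#'   (degrees, length `cyclic_order`); nonzero values break the equivalence
#'   and are provided for testing.
#' @param tol_A Coincidence tolerance in Angstrom.
#' @return A list with `equivalent` (logical), `layer_points` and
#'   `strand_points` (matrices of xyz rows), and `max_mismatch_A`.
#' @export
strand_lattice_equivalence <- function(sym, n_layers, ref_point = c(25, 0, 0),
                                       phase_offsets_deg = NULL, tol_A = 1e-6) {
  stopifnot(inherits(sym, "helical_symmetry"))
  n <- sym$cyclic_order
  if (is.null(phase_offsets_deg)) phase_offsets_deg <- numeric(n)
  stopifnot(length(phase_offsets_deg) == n)
  # (a) layer-stack description
  tr <- layer_transforms(sym, n_layers)
  layer_pts <- t(vapply(tr, function(g) apply_screw(g, ref_point),
                        numeric(3)))
  # (b) n-start strand description
  strand_pts <- matrix(0, n_layers * n, 3)
  m <- 0L
  for (k in seq_len(n) - 1L) {
    phase <- k * 360 / n + phase_offsets_deg[k + 1L]
    for (j in seq_len(n_layers) - 1L) {
      m <- m + 1L
      p <- rot_z(phase + j * sym$twist_deg) %*% ref_point
      strand_pts[m, ] <- p + c(0, 0, j * sym$rise_A)
    }
  }
  # match as sets: for each layer point find nearest strand point
  d <- vapply(seq_len(nrow(layer_pts)), function(i) {
    dd <- sqrt(colSums((t(strand_pts) - layer_pts[i, ])^2))
    min(dd)
  }, numeric(1))
  list(equivalent = max(d) < tol_A,
       layer_points = layer_pts,
       strand_points = strand_pts,
       max_mismatch_A = max(d))
}
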