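# Segment boxing, CTF handling, projection matching and back-projection:
# the per-iteration machinery of the helical reconstruction loop.

#' Cut overlapping boxes from a long filament image
#'
#' Long filament images are windowed into overlapping square segments
#' stepped along the filament axis (the z/column axis of the image), the
#' standard segment extraction for helical processing. The number of boxes
#' is `floor((L - box_px) / step_px) + 1`.
#'
#' @param long_img Matrix `box_px x L` (u along rows, filament axis along
#'   columns), or wider: only the first `box_px` rows are used.
#' @param box_px Segment edge length (pixels).
#' @param step_px Inter-box step (pixels, `0 < step_px <= box_px`).
#' @param pixel_size_A Pixel size (Angstrom).
#' @param filament_id Provenance id stored per box.
#' @return A [segment_stack()] with per-box `offset_px` provenance.
#' @export
extract_overlapping_boxes <- function(long_img, box_px, step_px,
                                      pixel_size_A = 1, filament_id = 1L) {
  stopifnot(is.matrix(long_img))
  if (step_px <= 0 || step_px > box_px)
    stop("need 0 < step_px <= box_px")
  if (nrow(long_img) < box_px)
    stop(sprintf("filament image width %d narrower than box %d",
                 nrow(long_img), box_px))
  len <- ncol(long_img)
  if (len < box_px)
    stop(sprintf("filament image length %d shorter than box %d", len, box_px))
  n_box <- floor((len - box_px) / step_px) + 1
  imgs <- array(0, c(box_px, box_px, n_box))
  offs <- integer(n_box)
  for (i in seq_len(n_box)) {
    o <- (i - 1L) * step_px
    imgs[, , i] <- long_img[seq_len(box_px), o + seq_len(box_px)]
    offs[i] <- o
  }
  meta <- data.frame(filament_id = filament_id, segment = seq_len(n_box),
                     offset_px = offs)
  segment_stack(imgs, meta, pixel_size_A)
}

#' Correct phase reversals by multiplying images by their CTF
#'
#' Multiplies each image's Fourier transform by its calculated CTF (the
#' Wiener filter in the very-poor-SNR limit). Because the microscope already
#' multiplied the signal by the CTF once, the corrected images carry CTF^2
#' amplitude weighting; this is recorded on the stack so [backproject()] can
#' later divide the volume by the summed squared CTF.
#'
#' @param stack A [segment_stack()] with `defocus_A` in the metadata.
#' @param acq [acquisition_params()]; defaults to the stack's own.
#' @return The stack with CTF-multiplied images and `ctf_weighted = TRUE`.
#' @export
phase_flip <- function(stack, acq = NULL) {
  stopifnot(inherits(stack, "segment_stack"))
  if (is.null(acq)) acq <- stack$acq
  if (is.null(acq)) acq <- acquisition_params()
  acq$pixel_size_A <- stack$pixel_size_A
  df <- stack$meta$defocus_A
  if (is.null(df) || anyNA(df))
    stop("per-image defocus missing from stack metadata")
  for (i in seq_len(n_segments(stack)))
    stack$images[, , i] <- apply_ctf_image(stack$images[, , i], df[i], acq)
  stack$ctf_weighted <- TRUE
  stack
}

#' Subset a segment stack
#' @param x A [segment_stack()].
#' @param i Segment indices.
#' @param ... Ignored.
#' @return A [segment_stack()] with the selected segments.
#' @export
`[.segment_stack` <- function(x, i, ...) {
  out <- x
  out$images <- x$images[, , i, drop = FALSE]
  out$meta <- x$meta[i, , drop = FALSE]
  out
}

#' Reference projections of a symmetrized volume
#'
#' Projects the volume at azimuths covering one asymmetric unit,
#' `0 ... 360/cn - step`, in steps of `angular_step_deg` (the Cn point group
#' makes the remaining azimuths redundant).
#'
#' @param volume Symmetrized [density_volume()].
#' @param sym [helical_symmetry()] (supplies the cyclic order).
#' @param angular_step_deg Azimuthal sampling step (> 0, default 4).
#' @return Object of class `"reference_set"`: list with `azimuths` and
#'   `images` (array).
#' @export
make_references <- function(volume, sym, angular_step_deg = 4) {
  if (angular_step_deg <= 0) stop("angular_step_deg must be > 0")
  az <- seq(0, 360 / sym$cyclic_order - angular_step_deg,
            by = angular_step_deg)
  d <- vol_dim(volume)
  imgs <- array(0, c(d[1], d[3], length(az)))
  for (i in seq_along(az))
    imgs[, , i] <- project_volume(volume, az[i])
  structure(list(azimuths = az, images = imgs,
                 angular_step_deg = angular_step_deg),
            class = "reference_set")
}

# circularly-indexed shift window rows/cols of an n-point FFT grid
shift_window <- function(n, r) {
  r <- min(r, n %/% 2 - 1)
  c(seq_len(r + 1), seq(n - r + 1, n))
}

# FFT-grid index -> signed shift
idx_to_shift <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)

#' Align segments to reference projections
#'
#' Exhaustive projection matching: for every segment, finds the (reference
#' azimuth, in-plane rotation, x/y shift) triple maximizing the normalized
#' cross-correlation, over the given in-plane rotation grid and within the
#' allowed shift window (FFT cross-correlation, integer-pixel peaks).
#'
#' @param stack A [segment_stack()].
#' @param references A [make_references()] reference set.
#' @param shift_range_px Length-2 vector: maximum |x| and |y| shift searched
#'   (pixels). The y (axial) range should cover one helical rise.
#' @param psi_grid_deg In-plane rotation candidates (degrees).
#' @return data.frame of class `"alignment_params"`: one row per segment
#'   with `azimuth`, `psi`, `sx_px`, `sy_px`, `score`.
#' @export
align_segments <- function(stack, references, shift_range_px = c(4, 8),
                           psi_grid_deg = c(-4, -2, 0, 2, 4)) {
  stopifnot(inherits(stack, "segment_stack"),
            inherits(references, "reference_set"))
  ns <- n_segments(stack)
  if (ns == 0) stop("empty segment stack")
  n <- dim(stack$images)[1]
  if (length(shift_range_px) == 1) shift_range_px <- rep(shift_range_px, 2)
  rows <- shift_window(n, shift_range_px[1])
  cols <- shift_window(dim(stack$images)[2], shift_range_px[2])
  nr <- dim(references$images)[3]
  ref_fft <- vector("list", nr)
  ref_sd <- numeric(nr)
  for (r in seq_len(nr)) {
    im <- references$images[, , r]
    im <- im - mean(im)
    ref_sd[r] <- sqrt(mean(im^2))   # population scale, so self-match scores 1
    ref_fft[[r]] <- Conj(stats::fft(im))
  }
  npx <- n * dim(stack$images)[2]
  out <- data.frame(segment = seq_len(ns), azimuth = NA_real_, psi = NA_real_,
                    sx_px = NA_real_, sy_px = NA_real_, score = -Inf)
  for (i in seq_len(ns)) {
    img0 <- stack$images[, , i]
    for (psi in psi_grid_deg) {
      img <- if (psi != 0) cpp_image_transform(img0, -psi, 0, 0) else img0
      img <- img - mean(img)
      isd <- sqrt(mean(img^2))
      if (isd == 0) next
      fi <- stats::fft(img)
      for (r in seq_len(nr)) {
        cc <- Re(stats::fft(fi * ref_fft[[r]], inverse = TRUE)) / npx
        sub <- cc[rows, cols]
        k <- which.max(sub)
        sc <- sub[k] / (npx * isd * ref_sd[r])
        if (sc > out$score[i]) {
          ki <- arrayInd(k, dim(sub))
          sp <- c(idx_to_shift(rows[ki[1]], n),
                  idx_to_shift(cols[ki[2]], dim(stack$images)[2]))
          # peak shift is in the rotated frame; map to the image frame
          smap <- as.numeric(rot_z(psi)[1:2, 1:2] %*% sp)
          out$azimuth[i] <- references$azimuths[r]
          out$psi[i] <- psi
          out$sx_px[i] <- smap[1]
          out$sy_px[i] <- smap[2]
          out$score[i] <- sc
        }
      }
    }
  }
  class(out) <- c("alignment_params", "data.frame")
  out
}

# undo psi/shift of one image in a single resampling
unalign_image <- function(img, psi, sx, sy) {
  d <- -as.numeric(rot_z(-psi)[1:2, 1:2] %*% c(sx, sy))
  cpp_image_transform(img, -psi, d[1], d[2])
}

# windowed ramp filter weights for an n-point FFT axis (cycles/px)
ramp_weights <- function(n, type = c("ramp-hann", "ramp", "none")) {
  type <- match.arg(type)
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1):1))) / n
  w <- switch(type,
              "ramp" = f,
              "ramp-hann" = f * (0.5 + 0.5 * cos(pi * f / 0.5)),
              "none" = rep(1, n))
  w
}

#' Back-project aligned segments into a volume
#'
#' Real-space filtered back-projection adapted to the helical geometry: each
#' aligned segment is brought to its canonical frame (in-plane rotation and
#' shifts undone), ramp-filtered along the in-plane axis, and smeared into
#' the volume along its viewing direction; the result is scaled by
#' pi / n_segments. For CTF^2-weighted stacks (after [phase_flip()]) the
#' volume's Fourier amplitudes are then divided per shell by the segment-
#' averaged squared CTF plus a small Wiener constant, implementing the
#' divide-by-summed-CTF-squared amplitude correction.
#'
#' @param stack A [segment_stack()] (typically phase-flipped).
#' @param params [align_segments()] output matched to the stack.
#' @param acq [acquisition_params()]; defaults to the stack's own.
#' @param wiener_constant Wiener constant added to the mean squared CTF;
#'   default 0.1 x its spectral mean.
#' @param filter Ramp filter variant (default Hann-windowed ramp).
#' @param ctf_correct Divide out the CTF^2 weighting (default: TRUE when the
#'   stack is CTF-weighted).
#' @return A [density_volume()].
#' @export
backproject <- function(stack, params, acq = NULL, wiener_constant = NULL,
                        filter = c("ramp-hann", "ramp", "none"),
                        ctf_correct = NULL) {
  stopifnot(inherits(stack, "segment_stack"))
  ns <- n_segments(stack)
  if (ns == 0) stop("empty segment stack")
  if (nrow(params) != ns)
    stop("alignment parameters do not match stack length")
  filter <- match.arg(filter)
  n <- dim(stack$images)[1]
  nz <- dim(stack$images)[2]
  dims <- c(n, n, nz)
  vol <- numeric(prod(dims))
  w <- ramp_weights(n, filter)
  for (i in seq_len(ns)) {
    img <- unalign_image(stack$images[, , i], params$psi[i],
                         params$sx_px[i], params$sy_px[i])
    if (filter != "none")
      img <- Re(stats::mvfft(stats::mvfft(img) * w, inverse = TRUE)) / n
    vol <- cpp_backproject_add(vol, dims, img, params$azimuth[i])
  }
  vol <- vol * pi / ns
  if (is.null(ctf_correct)) ctf_correct <- isTRUE(stack$ctf_weighted)
  if (ctf_correct) {
    if (is.null(acq)) acq <- stack$acq
    if (is.null(acq)) acq <- acquisition_params()
    acq$pixel_size_A <- stack$pixel_size_A
    df <- stack$meta$defocus_A
    if (is.null(df)) stop("defocus metadata required for CTF correction")
    sgrid <- seq(0, sqrt(3) * 0.5 / stack$pixel_size_A, length.out = 400)
    w2 <- rowMeans(vapply(df, function(d) ctf_function(sgrid, d, acq)^2,
                          numeric(length(sgrid))))
    if (is.null(wiener_constant)) wiener_constant <- 0.1 * mean(w2)
    fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * stack$pixel_size_A)
    s3 <- sqrt(outer(outer(fr^2, fr^2, "+"), fr^2, "+"))
    denom <- stats::approx(sgrid, w2, xout = as.numeric(s3), rule = 2)$y +
      wiener_constant
    va <- array(vol, dims)
    vf <- stats::fft(va) / array(denom, dims)
    vol <- Re(stats::fft(vf, inverse = TRUE)) / prod(dims)
  }
  density_volume(array(vol, dims), stack$pixel_size_A)
}

#' Back-project a paired stack using alignments found on another stack
#'
#' Applies alignment parameters determined on one dose/exposure to a
#' segment-for-segment paired stack (e.g. transferring orientations found on
#' high-dose images to paired low-dose images of the same segments to limit
#' radiation damage in the final map).
#'
#' @param params [align_segments()] output from the donor stack.
#' @param other_stack The paired [segment_stack()], same length and order.
#' @param ... Passed to [backproject()].
#' @return A [density_volume()].
#' @export
transfer_alignment <- function(params, other_stack, ...) {
  if (nrow(params) != n_segments(other_stack))
    stop("alignment parameters and paired stack differ in length")
  backproject(other_stack, params, ...)
}

#' Lattice-reduced alignment errors against simulation ground truth
#'
#' For a helical filament, (azimuth, axial shift) is identifiable only
#' modulo the lattice: rotating the view by i*twist + k*360/cn while
#' shifting axially by -i*rise maps the filament onto itself. This helper
#' reduces recovered-vs-true alignment differences by the closest lattice
#' operation and reports the residual errors.
#'
#' @param stack A simulated [segment_stack()] (ground truth in metadata).
#' @param params [align_segments()] output.
#' @param sym The true [helical_symmetry()].
#' @param max_layer Lattice layer search range (default 3).
#' @return data.frame with per-segment `d_azimuth_deg`, `d_axial_px`,
#'   `d_psi_deg`, `d_sx_px`.
#' @export
alignment_error <- function(stack, params, sym, max_layer = 3) {
  rise_vox <- sym$rise_A / stack$pixel_size_A
  wrap <- function(a) {
    a <- a %% 360
    ifelse(a > 180, a - 360, a)
  }
  daz <- params$azimuth - stack$meta$azimuth
  dy <- params$sy_px - stack$meta$sy_px
  n <- length(daz)
  best_a <- numeric(n)
  best_z <- numeric(n)
  ops <- expand.grid(i = -max_layer:max_layer,
                     k = seq_len(sym$cyclic_order) - 1L)
  for (j in seq_len(n)) {
    da <- abs(wrap(daz[j] - (ops$i * sym$twist_deg + ops$k * 360 / sym$cyclic_order)))
    dz <- abs(dy[j] + ops$i * rise_vox)
    cost <- da / sym$twist_deg + dz / rise_vox
    m <- which.min(cost)
    best_a[j] <- da[m]
    best_z[j] <- dz[m]
  }
  data.frame(d_azimuth_deg = best_a, d_axial_px = best_z,
             d_psi_deg = params$psi - stack$meta$psi,
             d_sx_px = params$sx_px - stack$meta$sx_px)
}
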