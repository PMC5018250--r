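# Synthetic segment-stack simulation: the stand-in for boxed micrograph
# segments of helical filaments.

#' Segment stack container
#'
#' Boxed filament images with per-segment metadata. Images are stored as an
#' n x n x n_segments array; the metadata has one row per image with the
#' ground truth (when simulated) or alignment provenance: filament id,
#' azimuth, tilt, in-plane rotation psi, x/y shifts in pixels, defocus and
#' class label.
#'
#' @param images n x n x n_seg numeric array (or a single matrix).
#' @param meta data.frame with one row per image.
#' @param pixel_size_A Pixel size (Angstrom).
#' @param ctf_weighted Logical: TRUE once images have been multiplied by
#'   their CTF a second time by [phase_flip()] (so amplitudes carry CTF^2).
#' @param acq Optional [acquisition_params()] describing how the images were
#'   (or are assumed to have been) acquired.
#' @return Object of class `"segment_stack"`.
#' @export
segment_stack <- function(images, meta, pixel_size_A, ctf_weighted = FALSE,
                          acq = NULL) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  stopifnot(length(dim(images)) == 3)
  if (nrow(meta) != dim(images)[3])
    stop("metadata rows must match image count")
  structure(list(images = images, meta = meta, pixel_size_A = pixel_size_A,
                 ctf_weighted = ctf_weighted, acq = acq),
            class = "segment_stack")
}

#' @export
print.segment_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Segment stack: %d images of %d x %d px at %.2f A/px%s\n",
              d[3], d[1], d[2], x$pixel_size_A,
              if (x$ctf_weighted) " (CTF^2-weighted)" else ""))
  if (!is.null(x$meta$class))
    cat("  classes:", paste(sprintf("%s:%d", names(table(x$meta$class)),
                                    table(x$meta$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of segments in a stack
#' @param stack A [segment_stack()].
#' @return Integer count.
#' @export
n_segments <- function(stack) dim(stack$images)[3]

#' Noise level for a requested signal-to-noise ratio
#'
#' Computes the white-noise standard deviation giving variance ratio
#' `var(signal)/var(noise) = snr` for CTF-filtered projections of a volume,
#' using a representative projection at mid-range defocus.
#'
#' @param volume A [density_volume()].
#' @param snr Requested signal-to-noise (variance) ratio.
#' @param acq [acquisition_params()].
#' @param defocus_A Representative defocus (Angstrom).
#' @return Noise standard deviation.
#' @export
noise_sigma_for_snr <- function(volume, snr, acq, defocus_A = 2e4) {
  img <- project_volume(volume, azimuth_deg = 17)
  img <- apply_ctf_image(img, defocus_A, acq)
  stats::sd(as.numeric(img)) / sqrt(snr)
}

#' Simulate a stack of noisy CTF-modulated filament segments
#'
#' Forward model for boxed segments of long helical filaments: each segment
#' is a projection of the filament volume at a random azimuth, with a small
#' out-of-plane tilt jitter about 90 degrees, a random in-plane rotation,
#' random sub-pixel shifts and (if `rise_A` is given) a random axial offset
#' uniform over one rise; the projection is multiplied in Fourier space by
#' the CTF at a per-segment random defocus and white Gaussian noise is
#' added. All ground truth is stored in the metadata and the output is
#' deterministic for a fixed seed.
#'
#' @param volume Filament [density_volume()] (helically continuous in z).
#' @param n_seg Number of segments (>= 1).
#' @param acq [acquisition_params()] (its pixel size is overridden by the
#'   volume voxel size).
#' @param defocus_range_um Underfocus range in micrometers (default 0.5-3.5).
#' @param noise_sigma White-noise standard deviation (0 = noiseless).
#' @param seed Integer seed.
#' @param rise_A Helical rise for the axial-offset draw (NULL = none).
#' @param tilt_jitter_deg Max out-of-plane tilt deviation from 90 (default 2).
#' @param psi_jitter_deg Max in-plane rotation magnitude (default 4).
#' @param shift_jitter_px Max x/y shift magnitude in pixels (default 2).
#' @param class_label Class label stored per segment (default 1).
#' @param filament_id Filament id stored per segment.
#' @return A [segment_stack()].
#' @export
simulate_segment_stack <- function(volume, n_seg, acq = acquisition_params(),
                                   defocus_range_um = c(0.5, 3.5),
                                   noise_sigma = 0, seed = 1,
                                   rise_A = NULL,
                                   tilt_jitter_deg = 2, psi_jitter_deg = 4,
                                   shift_jitter_px = 2,
                                   class_label = 1L, filament_id = 1L) {
  n_seg <- as.integer(n_seg)
  if (is.na(n_seg) || n_seg < 1) stop("n_seg must be >= 1")
  stopifnot(inherits(volume, "density_volume"))
  acq$pixel_size_A <- volume$voxel_A
  d <- vol_dim(volume)
  with_seed(seed, {
    azimuth <- stats::runif(n_seg, 0, 360)
    tilt <- 90 + stats::runif(n_seg, -tilt_jitter_deg, tilt_jitter_deg)
    psi <- stats::runif(n_seg, -psi_jitter_deg, psi_jitter_deg)
    sx <- stats::runif(n_seg, -shift_jitter_px, shift_jitter_px)
    sy <- stats::runif(n_seg, -shift_jitter_px, shift_jitter_px)
    if (!is.null(rise_A))
      sy <- sy + stats::runif(n_seg, 0, rise_A) / volume$voxel_A
    defocus <- stats::runif(n_seg, defocus_range_um[1], defocus_range_um[2]) * 1e4
    imgs <- array(0, c(d[1], d[3], n_seg))
    for (i in seq_len(n_seg)) {
      im <- project_volume(volume, azimuth[i], tilt[i], psi[i], c(sx[i], sy[i]))
      im <- apply_ctf_image(im, defocus[i], acq)
      if (noise_sigma > 0)
        im <- im + matrix(stats::rnorm(length(im), sd = noise_sigma), nrow(im))
      imgs[, , i] <- im
    }
    meta <- data.frame(filament_id = filament_id, segment = seq_len(n_seg),
                       azimuth = azimuth, tilt = tilt, psi = psi,
                       sx_px = sx, sy_px = sy, defocus_A = defocus,
                       class = class_label)
    segment_stack(imgs, meta, volume$voxel_A, acq = acq)
  })
}

#' Simulate a two-population mixture of filament segments
#'
#' Draws segments from two filament models built from the same subunit
#' template but with different helical symmetries (by default the two
#' coexisting F-pilus lattices, rise 12.5 vs 13.2 Angstrom), with stratified
#' class counts and true class labels stored for later confusion-matrix
#' scoring of the sorting procedure.
#'
#' @param template A [make_test_subunit()] template.
#' @param sym_a,sym_b The two [helical_symmetry()] lattices.
#' @param fraction_a Fraction of segments from `sym_a` (strictly in (0, 1)).
#' @param n_seg Total number of segments.
#' @param box_px Box edge (pixels).
#' @param voxel_A Pixel size (Angstrom).
#' @param ... Passed to [simulate_segment_stack()] (noise, defocus, jitters).
#' @param seed Integer seed.
#' @return A [segment_stack()] with `meta$class` in {1, 2}; the rendered
#'   class volumes are attached as attribute `"volumes"`.
#' @export
simulate_mixture <- function(template,
                             sym_a = helical_symmetry(28.1, 12.5, 5),
                             sym_b = helical_symmetry(27.9, 13.2, 5),
                             fraction_a = 0.5, n_seg = 200,
                             box_px = 96, voxel_A = 3.0, seed = 1, ...) {
  if (!(fraction_a > 0 && fraction_a < 1))
    stop("fraction_a must be strictly between 0 and 1")
  n_a <- round(fraction_a * n_seg)
  n_b <- n_seg - n_a
  if (n_a < 1 || n_b < 1) stop("degenerate mixture fractions")
  mk <- function(sym) {
    n_layers <- ceiling(box_px * voxel_A / sym$rise_A) + 4
    render_volume(template, sym, n_layers, box_px, voxel_A, clip_z = TRUE)
  }
  vol_a <- mk(sym_a)
  vol_b <- mk(sym_b)
  st_a <- simulate_segment_stack(vol_a, n_a, seed = seed, rise_A = sym_a$rise_A,
                                 class_label = 1L, filament_id = 1L, ...)
  st_b <- simulate_segment_stack(vol_b, n_b, seed = seed + 1L,
                                 rise_A = sym_b$rise_A,
                                 class_label = 2L, filament_id = 2L, ...)
  imgs <- array(0, c(dim(st_a$images)[1:2], n_seg))
  imgs[, , seq_len(n_a)] <- st_a$images
  imgs[, , n_a + seq_len(n_b)] <- st_b$images
  meta <- rbind(st_a$meta, st_b$meta)
  meta$segment <- seq_len(n_seg)
  out <- segment_stack(imgs, meta, voxel_A, acq = st_a$acq)
  attr(out, "volumes") <- list(a = vol_a, b = vol_b)
  out
}

#' Write per-segment metadata as a plain-text table
#' @param stack A [segment_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_meta <- function(stack, path) {
  utils::write.table(stack$meta, path, row.names = FALSE, quote = FALSE,
                     sep = "\t")
  invisible(path)
}

#' Read a per-segment metadata table written by [write_segment_meta()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_segment_meta <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write a segment stack as MRC plus a metadata table
#' @param stack A [segment_stack()].
#' @param mrc_path Path for the MRC image stack.
#' @param meta_path Path for the metadata table (default: mrc path with .txt).
#' @return `mrc_path`, invisibly.
#' @export
write_segment_stack <- function(stack, mrc_path,
                                meta_path = sub("\\.mrcs?$", ".txt", mrc_path)) {
  write_mrc(stack$images, mrc_path, voxel_A = stack$pixel_size_A)
  write_segment_meta(stack, meta_path)
  invisible(mrc_path)
}

#' Read a segment stack from MRC plus metadata table
#' @param mrc_path MRC stack path.
#' @param meta_path Metadata table path.
#' @return A [segment_stack()].
#' @export
read_segment_stack <- function(mrc_path,
                               meta_path = sub("\\.mrcs?$", ".txt", mrc_path)) {
  m <- read_mrc(mrc_path)
  segment_stack(m$data, read_segment_meta(meta_path), m$voxel_A)
}

#' Fourier-crop (bin) a segment stack
#'
#' Downsamples every image by an integer factor by cropping its Fourier
#' transform (exact band limitation, no aliasing). Pixel size and stored
#' shift metadata are rescaled accordingly.
#'
#' @param stack A [segment_stack()].
#' @param factor Integer binning factor (default 2).
#' @return A binned [segment_stack()].
#' @export
downsample_stack <- function(stack, factor = 2L) {
  factor <- as.integer(factor)
  d <- dim(stack$images)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  m1 <- d[1] %/% factor
  m2 <- d[2] %/% factor
  keep1 <- c(seq_len(m1 %/% 2 + 1), seq(d[1] - m1 %/% 2 + 2, d[1]))
  keep2 <- c(seq_len(m2 %/% 2 + 1), seq(d[2] - m2 %/% 2 + 2, d[2]))
  imgs <- array(0, c(m1, m2, d[3]))
  for (i in seq_len(d[3])) {
    f <- stats::fft(stack$images[, , i])[keep1, keep2]
    imgs[, , i] <- Re(stats::fft(f, inverse = TRUE)) / (d[1] * d[2])
  }
  meta <- stack$meta
  if (!is.null(meta$sx_px)) meta$sx_px <- meta$sx_px / factor
  if (!is.null(meta$sy_px)) meta$sy_px <- meta$sy_px / factor
  segment_stack(imgs, meta, stack$pixel_size_A * factor,
                ctf_weighted = stack$ctf_weighted, acq = stack$acq)
}
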