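# Fourier shell correlation and model-to-map resolution assessment.

#' Fourier shell correlation between two maps
#'
#' Per-shell normalized complex correlation of the Fourier coefficients of
#' two maps on the same grid:
#' FSC(s) = Re sum(F_a conj(F_b)) / sqrt(sum |F_a|^2 sum |F_b|^2).
#'
#' @param map_a,map_b [density_volume()] objects (same grid, same voxel).
#' @param shell_width_vox Shell width in Fourier voxels (default 1).
#' @return Object of class `"fsc_curve"`: data.frame with `freq` (1/A,
#'   shell centers, increasing up to Nyquist), `fsc`, `n_vox` (voxels per
#'   shell); voxel size kept as attribute.
#' @export
fsc <- function(map_a, map_b, shell_width_vox = 1) {
  stopifnot(inherits(map_a, "density_volume"),
            inherits(map_b, "density_volume"))
  if (!identical(vol_dim(map_a), vol_dim(map_b)) ||
      abs(map_a$voxel_A - map_b$voxel_A) > 1e-9)
    stop("maps must share grid dimensions and voxel size")
  d <- vol_dim(map_a)
  fa <- stats::fft(map_a$data)
  fb <- stats::fft(map_b$data)
  fr <- lapply(d, function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n)
  s_vox <- sqrt(outer(outer(fr[[1]]^2 * d[1]^2, fr[[2]]^2 * d[2]^2, "+"),
                      fr[[3]]^2 * d[3]^2, "+"))
  nyq_vox <- d[1] / 2
  shell <- floor(s_vox / shell_width_vox) + 1L
  keep <- s_vox > 0 & s_vox <= nyq_vox
  sh <- shell[keep]
  cross <- Re(fa[keep] * Conj(fb[keep]))
  pa <- Mod(fa[keep])^2
  pb <- Mod(fb[keep])^2
  num <- tapply(cross, sh, sum)
  da <- tapply(pa, sh, sum)
  db <- tapply(pb, sh, sum)
  nv <- tapply(rep(1, length(sh)), sh, sum)
  corr <- as.numeric(num / sqrt(da * db))
  corr[!is.finite(corr)] <- 0
  idx <- as.integer(names(num))
  freq <- pmin((idx - 0.5) * shell_width_vox, nyq_vox) /
    (d[1] * map_a$voxel_A)
  out <- data.frame(freq = freq, fsc = corr, n_vox = as.integer(nv))
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  class(out) <- c("fsc_curve", "data.frame")
  attr(out, "voxel_A") <- map_a$voxel_A
  out
}

#' @export
plot.fsc_curve <- function(x, thresholds = c(0.143, 0.4), ...) {
  graphics::plot(x$freq, x$fsc, type = "l", ylim = c(-0.1, 1.05),
                 xlab = "spatial frequency (1/A)", ylab = "FSC", ...)
  graphics::abline(h = thresholds, lty = 3, col = "grey40")
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the frequency of the first downward crossing of the
#' threshold, linearly interpolated between the bracketing shells. The
#' conventional thresholds are 0.143 for two independent half-maps and 0.4
#' for a model-to-map FSC (available as named presets).
#'
#' @param curve An [fsc()] curve.
#' @param threshold Numeric in (-1, 1), or `"half-map"` (0.143) /
#'   `"model-map"` (0.4).
#' @return Resolution in Angstrom, with attribute `crossed` = FALSE and the
#'   Nyquist resolution returned when the curve never drops below the
#'   threshold.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  stopifnot(inherits(curve, "fsc_curve"), nrow(curve) > 0)
  if (is.character(threshold))
    threshold <- switch(match.arg(threshold, c("half-map", "model-map")),
                        "half-map" = 0.143, "model-map" = 0.4)
  if (threshold <= -1 || threshold >= 1)
    stop("threshold must be inside (-1, 1)")
  below <- which(curve$fsc < threshold)
  if (length(below) == 0 || below[1] == 1) {
    if (length(below) == 0) {
      res <- 1 / max(curve$freq)
      attr(res, "crossed") <- FALSE
      return(res)
    }
    res <- 1 / curve$freq[1]
    attr(res, "crossed") <- TRUE
    return(res)
  }
  i <- below[1]
  f1 <- curve$freq[i - 1]; f2 <- curve$freq[i]
  c1 <- curve$fsc[i - 1];  c2 <- curve$fsc[i]
  fx <- f1 + (c1 - threshold) / (c1 - c2) * (f2 - f1)
  res <- 1 / fx
  attr(res, "crossed") <- TRUE
  res
}

#' Render an atomic model as a density volume
#'
#' Sum of one isotropic Gaussian per atom, amplitude proportional to the
#' atomic number and width set by an overall B-factor via
#' sigma^2 = B / (8 pi^2) (a single-Gaussian scattering approximation,
#' adequate for model:map FSC consistency at moderate resolution).
#'
#' @param model An [atomic_model()].
#' @param voxel_A Voxel size.
#' @param box_px Cubic box edge (voxels).
#' @param bfactor Overall isotropic B (A^2, default 150).
#' @return A [density_volume()].
#' @export
model_to_density <- function(model, voxel_A, box_px, bfactor = 150) {
  stopifnot(inherits(model, "atomic_model"))
  box_px <- as.integer(box_px)
  dims <- rep(box_px, 3)
  if (nrow(model$atoms) == 0)
    return(density_volume(array(0, dims), voxel_A))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  half <- (box_px - 1) / 2 * voxel_A
  if (max(abs(xyz)) > half)
    stop(sprintf("atoms extend %.1f A outside the box", max(abs(xyz)) - half))
  z <- atomic_number(model$atoms$element)
  sigma <- sqrt(bfactor / (8 * pi^2)) + 0.8   # 0.8 A base atomic width
  centers <- sweep(xyz / voxel_A, 2, (dims - 1) / 2, "+")
  arr <- cpp_render_gauss(dims, centers, z, rep(sigma / voxel_A, nrow(xyz)))
  density_volume(array(arr, dims), voxel_A)
}
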