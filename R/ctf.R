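# Contrast transfer function model (single defocus, no astigmatism).

#' Relativistic electron wavelength
#'
#' @param voltage_kV Acceleration voltage in kV.
#' @return Wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kV) {
  v <- voltage_kV * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Acquisition parameters
#'
#' Microscope/detector parameters of the simulated data collection. Defaults
#' follow the imaging conditions of the pilus study: 300 kV, 1.1 A/px
#' calibrated pixel (desk-scale simulations typically use 2-3 A/px), with a
#' dose budget of ~100 e/A2 fractionated during acquisition.
#'
#' @param voltage_kV Acceleration voltage (kV).
#' @param spherical_aberration_mm Cs (mm).
#' @param amplitude_contrast Amplitude-contrast fraction in [0, 1).
#' @param pixel_size_A Pixel size (Angstrom).
#' @param dose_e_per_A2 Electron dose (e-/A2).
#' @return Object of class `"acquisition_params"`.
#' @export
acquisition_params <- function(voltage_kV = 300, spherical_aberration_mm = 2.0,
                               amplitude_contrast = 0.1, pixel_size_A = 1.1,
                               dose_e_per_A2 = 20) {
  stopifnot(voltage_kV > 0, spherical_aberration_mm > 0, pixel_size_A > 0,
            dose_e_per_A2 > 0,
            amplitude_contrast >= 0, amplitude_contrast < 1)
  structure(list(voltage_kV = voltage_kV,
                 spherical_aberration_mm = spherical_aberration_mm,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size_A = pixel_size_A,
                 dose_e_per_A2 = dose_e_per_A2),
            class = "acquisition_params")
}

#' Contrast transfer function
#'
#' CTF(s) = -(sqrt(1 - A^2) sin(gamma) + A cos(gamma)) with
#' gamma = pi lambda df s^2 - (pi/2) Cs lambda^3 s^4. Defocus is stored as
#' positive underfocus (a display convention of "-0.5 to -3.5 um" maps to
#' 0.5-3.5 um underfocus here), which makes the CTF negative at low
#' frequency: CTF(0) = -A.
#'
#' @param s Spatial frequency (1/Angstrom), >= 0. Vectorized.
#' @param defocus_A Underfocus in Angstrom (positive = underfocus).
#' @param acq [acquisition_params()].
#' @return CTF values between -1 and 1.
#' @export
ctf_function <- function(s, defocus_A, acq = acquisition_params()) {
  stopifnot(all(s >= 0))
  lambda <- electron_wavelength(acq$voltage_kV)
  cs <- acq$spherical_aberration_mm * 1e7   # mm -> Angstrom
  a <- acq$amplitude_contrast
  gamma <- pi * lambda * defocus_A * s^2 - (pi / 2) * cs * lambda^3 * s^4
  -(sqrt(1 - a^2) * sin(gamma) + a * cos(gamma))
}

#' First zero crossing of the CTF
#'
#' Locates the lowest spatial frequency at which the CTF changes sign, by
#' bracketing the first sign change on a fine grid and polishing with
#' root-finding on the CTF itself.
#'
#' @inheritParams ctf_function
#' @return Frequency of the first zero (1/Angstrom).
#' @export
ctf_first_zero <- function(defocus_A, acq = acquisition_params()) {
  f <- function(s) ctf_function(s, defocus_A, acq)
  grid <- seq(1e-4, 0.5, length.out = 4000)
  v <- f(grid)
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  if (is.na(i)) stop("no CTF zero crossing below 0.5 1/A")
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

# 2D radially symmetric CTF image in FFT layout (DC at [1,1]) for an
# n x n image at pixel size px_A
ctf_image <- function(n, defocus_A, acq) {
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * acq$pixel_size_A)
  s2 <- outer(fr^2, fr^2, "+")
  matrix(ctf_function(sqrt(as.numeric(s2)), defocus_A, acq), n, n)
}

# multiply an image by a CTF in Fourier space
apply_ctf_image <- function(img, defocus_A, acq) {
  n <- nrow(img)
  h <- ctf_image(n, defocus_A, acq)
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / length(img)
}
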