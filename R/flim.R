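#' Modulated frequency-domain FLIM image stack
#'
#' Container for one frequency-domain FLIM acquisition: `K` images of the
#' modulated emission, one per equally spaced excitation phase step over a
#' single modulation period.
#'
#' @param pixels numeric array indexed `(phase_step, row, col)`, all values
#'   finite and non-negative.
#' @param modulation_frequency_hz modulation frequency f in Hz (default
#'   550 kHz, the frequency of the camera class this models).
#' @param pixel_size_um physical pixel size in micrometres.
#' @param timestamp_s acquisition time in seconds since experiment start.
#' @return an object of class `modulated_stack`.
#' @export
modulated_stack <- function(pixels, modulation_frequency_hz = 550e3,
                            pixel_size_um = 0.065, timestamp_s = 0) {
  if (length(dim(pixels)) != 3L)
    stop("`pixels` must be a 3-d array (phase_step, row, col)")
  K <- dim(pixels)[1L]
  if (K < 3L)
    stop("at least 3 phase steps are required (got ", K, ")")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0")
  if (modulation_frequency_hz <= 0)
    stop("modulation_frequency_hz must be > 0")
  structure(
    list(pixels = pixels, n_phase_steps = K,
         modulation_frequency_hz = modulation_frequency_hz,
         pixel_size_um = pixel_size_um, timestamp_s = timestamp_s),
    class = "modulated_stack")
}

#' @export
print.modulated_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<modulated_stack> %d phase steps, %d x %d px, f = %g kHz, t = %g s\n",
              d[1], d[2], d[3], x$modulation_frequency_hz / 1e3, x$timestamp_s))
  invisible(x)
}

#' First-harmonic phasor estimation
#'
#' Computes the per-pixel first-harmonic phase and modulation depth of a
#' modulated image stack. For a pixel series \eqn{I_k}, \eqn{k = 0..K-1},
#' the DC level is \eqn{c_0 = \sum I_k / K}, the harmonic coefficients are
#' \eqn{a = (2/K)\sum I_k \cos(2\pi k/K)} and
#' \eqn{b = (2/K)\sum I_k \sin(2\pi k/K)}, the phase is `atan2(b, a)` (a pure
#' emission delay yields a positive phase) and the modulation depth is
#' \eqn{\sqrt{a^2+b^2}/c_0}.
#'
#' Dark pixels (`c0 == 0`) yield `NaN` phase and modulation. A purely DC
#' series yields modulation 0 and, by convention, phase 0 (`atan2(0, 0)`).
#'
#' @param stack a [modulated_stack()].
#' @return an object of class `phasor_image` with matrix fields `phase_rad`
#'   (wrapped to (-pi, pi]), `modulation`, `mean_intensity`, plus
#'   `modulation_frequency_hz`, `pixel_size_um` and `timestamp_s`.
#' @export
compute_phasor <- function(stack) {
  stopifnot(inherits(stack, "modulated_stack"))
  d <- dim(stack$pixels)
  K <- d[1L]
  m <- matrix(stack$pixels, nrow = K)      # K x (nrow*ncol), column-major
  k <- 0:(K - 1L)
  ck <- cos(2 * pi * k / K)
  sk <- sin(2 * pi * k / K)
  c0 <- colMeans(m)
  a <- as.vector(crossprod(ck, m)) * (2 / K)
  b <- as.vector(crossprod(sk, m)) * (2 / K)
  phase <- atan2(b, a)
  modl <- sqrt(a^2 + b^2) / c0
  # pure DC series: the harmonic is numerically zero and the phase undefined;
  # report phase 0 (documented convention)
  dc_only <- is.finite(modl) & modl < 1e-12
  phase[dc_only] <- 0
  dark <- c0 == 0
  phase[dark] <- NaN
  modl[dark] <- NaN
  shape <- d[2:3]
  structure(
    list(phase_rad = matrix(phase, shape[1], shape[2]),
         modulation = matrix(modl, shape[1], shape[2]),
         mean_intensity = matrix(c0, shape[1], shape[2]),
         modulation_frequency_hz = stack$modulation_frequency_hz,
         pixel_size_um = stack$pixel_size_um,
         timestamp_s = stack$timestamp_s),
    class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("<phasor_image> %d x %d px, f = %g kHz, median phase %.4f rad, median modulation %.4f\n",
              nrow(x$phase_rad), ncol(x$phase_rad),
              x$modulation_frequency_hz / 1e3,
              stats::median(x$phase_rad, na.rm = TRUE),
              stats::median(x$modulation, na.rm = TRUE)))
  invisible(x)
}

#' Rectangular region of interest
#'
#' ROIs are axis-aligned pixel rectangles in 0-based, half-open coordinates:
#' rows `row0 <= r < row1`, columns `col0 <= c < col1`.
#'
#' @param row0,row1,col0,col1 integer bounds (0-based, half-open).
#' @return an object of class `roi_rect`.
#' @export
roi_rect <- function(row0, row1, col0, col1) {
  if (row1 <= row0 || col1 <= col0) stop("ROI must be non-empty")
  if (row0 < 0 || col0 < 0) stop("ROI bounds must be >= 0")
  structure(list(row0 = row0, row1 = row1, col0 = col0, col1 = col1),
            class = "roi_rect")
}

roi_subset <- function(mat, roi) {
  if (is.null(roi)) return(mat)
  stopifnot(inherits(roi, "roi_rect"))
  if (roi$row1 > nrow(mat) || roi$col1 > ncol(mat))
    stop("ROI exceeds image dimensions")
  mat[(roi$row0 + 1L):roi$row1, (roi$col0 + 1L):roi$col1, drop = FALSE]
}

#' Instrument calibration from a reference slide
#'
#' Derives the instrument phase offset and modulation gain from a phasor
#' image of a reference slide of known lifetime `tau_ref` (default use case:
#' a stable dye slide, e.g. 3.75 ns). With \eqn{\omega = 2\pi f}:
#' `phase_offset = <phase>_ROI - atan(omega * tau_ref)` and
#' `modulation_factor = <modulation>_ROI * sqrt(1 + (omega * tau_ref)^2)`.
#' A calibration is only valid at the frequency it was computed for.
#'
#' @param ref_phasor `phasor_image` of the reference slide.
#' @param reference_lifetime_ns known reference lifetime in ns.
#' @param roi optional [roi_rect()]; `NULL` means the whole image.
#' @return object of class `instrument_calibration`.
#' @export
calibrate_instrument <- function(ref_phasor, reference_lifetime_ns, roi = NULL) {
  stopifnot(inherits(ref_phasor, "phasor_image"))
  if (reference_lifetime_ns < 0) stop("reference lifetime must be >= 0")
  ph <- roi_subset(ref_phasor$phase_rad, roi)
  mo <- roi_subset(ref_phasor$modulation, roi)
  ok <- is.finite(ph) & is.finite(mo)
  if (!any(ok)) stop("ROI contains no finite phasor values")
  mp <- mean(ph[ok])
  mm <- mean(mo[ok])
  if (mm == 0) stop("calibration failure: ROI mean modulation is 0")
  w <- 2 * pi * ref_phasor$modulation_frequency_hz
  wt <- w * reference_lifetime_ns * 1e-9
  structure(
    list(reference_lifetime_ns = reference_lifetime_ns,
         measured_ref_phase_rad = mp,
         measured_ref_modulation = mm,
         phase_offset_rad = mp - atan(wt),
         modulation_factor = mm * sqrt(1 + wt^2),
         modulation_frequency_hz = ref_phasor$modulation_frequency_hz),
    class = "instrument_calibration")
}

#' @export
print.instrument_calibration <- function(x, ...) {
  cat(sprintf("<instrument_calibration> tau_ref = %g ns @ %g kHz: phase offset %.5f rad, modulation factor %.5f\n",
              x$reference_lifetime_ns, x$modulation_frequency_hz / 1e3,
              x$phase_offset_rad, x$modulation_factor))
  invisible(x)
}

wrap_phase <- function(p) {
  # wrap to (-pi, pi]
  w <- ((p + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Apply an instrument calibration to a sample phasor image
#'
#' Subtracts the instrument phase offset and divides out the modulation gain.
#' The calibration and the sample must share the same modulation frequency.
#'
#' @param sample a `phasor_image`.
#' @param calib an `instrument_calibration`.
#' @return corrected `phasor_image`.
#' @export
correct_phasor <- function(sample, calib) {
  stopifnot(inherits(sample, "phasor_image"),
            inherits(calib, "instrument_calibration"))
  if (!isTRUE(all.equal(sample$modulation_frequency_hz,
                        calib$modulation_frequency_hz)))
    stop("modulation frequency mismatch between sample and calibration")
  out <- sample
  out$phase_rad <- wrap_phase(sample$phase_rad - calib$phase_offset_rad)
  out$modulation <- sample$modulation / calib$modulation_factor
  out
}

#' Lifetime image wrapper
#' @keywords internal
lifetime_image <- function(tau_ns, method, timestamp_s = 0,
                           pixel_size_um = NA_real_, n_flagged = 0L) {
  structure(list(tau_ns = tau_ns, method = method,
                 timestamp_s = timestamp_s, pixel_size_um = pixel_size_um,
                 n_flagged = n_flagged),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  cat(sprintf("<lifetime_image> %d x %d px (%s), median tau %.2f ns, %d flagged px\n",
              nrow(x$tau_ns), ncol(x$tau_ns), x$method,
              stats::median(x$tau_ns, na.rm = TRUE), x$n_flagged))
  invisible(x)
}

#' Phase lifetime
#'
#' Per-pixel lifetime from the corrected phase: \eqn{\tau = \tan(\phi)/\omega}.
#' Phases outside `[0, pi/2)` are unphysical for a mono-exponential decay and
#' map to `NaN` (the count is recorded in `n_flagged`); `phi = 0` maps to 0.
#'
#' @param phasor corrected `phasor_image`.
#' @return a `lifetime_image` (ns), `method = "phase"`.
#' @export
lifetime_from_phase <- function(phasor) {
  stopifnot(inherits(phasor, "phasor_image"))
  w <- 2 * pi * phasor$modulation_frequency_hz
  ph <- phasor$phase_rad
  tau <- tan(ph) / w * 1e9
  bad <- is.finite(ph) & (ph < 0 | ph >= pi / 2)
  tau[bad] <- NaN
  lifetime_image(tau, "phase", phasor$timestamp_s, phasor$pixel_size_um,
                 n_flagged = sum(bad))
}

#' Modulation lifetime
#'
#' Per-pixel lifetime from the corrected modulation depth:
#' \eqn{\tau = \sqrt{1/m^2 - 1}/\omega}. Depths `m >= 1` (possible under
#' noise after gain correction) clip to `tau = 0` and are counted in
#' `n_flagged`; `m <= 0` maps to `NaN`.
#'
#' @param phasor corrected `phasor_image`.
#' @return a `lifetime_image` (ns), `method = "modulation"`.
#' @export
lifetime_from_modulation <- function(phasor) {
  stopifnot(inherits(phasor, "phasor_image"))
  w <- 2 * pi * phasor$modulation_frequency_hz
  m <- phasor$modulation
  tau <- sqrt(pmax(1 / m^2 - 1, 0)) / w * 1e9
  clipped <- is.finite(m) & m >= 1
  tau[clipped] <- 0
  tau[is.finite(m) & m <= 0] <- NaN
  lifetime_image(tau, "modulation", phasor$timestamp_s, phasor$pixel_size_um,
                 n_flagged = sum(clipped))
}

#' ROI-mean lifetime
#'
#' Arithmetic mean of the finite lifetimes inside an ROI. Single lifetime
#' images of the oxygen sensor are noisy at the single-pixel level, so each
#' image is reduced to its average before conversion to a concentration.
#'
#' @param image a `lifetime_image`.
#' @param roi optional [roi_rect()]; `NULL` means the whole image.
#' @return scalar mean lifetime in ns, with attribute `n_excluded` giving the
#'   number of non-finite pixels dropped from the ROI.
#' @export
mean_lifetime <- function(image, roi = NULL) {
  stopifnot(inherits(image, "lifetime_image"))
  v <- roi_subset(image$tau_ns, roi)
  ok <- is.finite(v)
  if (!any(ok)) stop("all ROI pixels are NaN; no lifetime defined")
  structure(mean(v[ok]), n_excluded = sum(!ok))
}
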