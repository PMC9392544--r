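#' IIR filter specification
#'
#' Describes one stage of the preprocessing filter chain. Three designs are
#' supported: a narrow band-stop (notch) biquad for power-line removal, and
#' Chebyshev type-II or elliptic band-pass designs. All filters are applied
#' zero-phase (forward-backward), so the effective magnitude response is the
#' squared design response and no group delay is introduced.
#'
#' @param kind One of `"notch"`, `"chebyshev2_bandpass"`, `"elliptic_bandpass"`.
#' @param low_hz,high_hz Band edges in Hz (band-pass kinds).
#' @param center_hz Center frequency in Hz (notch).
#' @param order Filter order per design (band-pass kinds; the resulting
#'   transfer function has twice this order).
#' @param stopband_db Minimum stopband attenuation in dB.
#' @param ripple_db Passband ripple in dB (elliptic only).
#' @param q Quality factor of the notch (center / -3 dB width).
#' @return An object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec("notch", center_hz = 50)
#' filter_spec("elliptic_bandpass", low_hz = 0.1, high_hz = 60)
filter_spec <- function(kind = c("elliptic_bandpass", "chebyshev2_bandpass",
                                 "notch"),
                        low_hz = 0.1, high_hz = 60, center_hz = 50,
                        order = 4, stopband_db = 40, ripple_db = 1, q = 30) {
  kind <- match.arg(kind)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (kind != "notch" && !(0 < low_hz && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 center_hz = center_hz, order = order,
                 stopband_db = stopband_db, ripple_db = ripple_db, q = q),
            class = "filter_spec")
}

# RBJ-cookbook band-stop biquad; zeros exactly on the unit circle at w0.
design_notch <- function(center_hz, q, fs) {
  w0 <- 2 * pi * center_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Design the digital filter for a given sampling rate
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @export
design_filter <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- fs / 2
  hi <- if (spec$kind == "notch") spec$center_hz else spec$high_hz
  if (hi >= nyq) {
    stop("filter frequencies must lie below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  }
  flt <- switch(
    spec$kind,
    notch = design_notch(spec$center_hz, spec$q, fs),
    chebyshev2_bandpass = {
      d <- signal::cheby2(spec$order, spec$stopband_db,
                          c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
      list(b = d$b, a = d$a)
    },
    elliptic_bandpass = {
      d <- signal::ellip(spec$order, spec$ripple_db, spec$stopband_db,
                         c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
      list(b = d$b, a = d$a)
    }
  )
  poles <- polyroot(rev(flt$a))
  if (max(Mod(poles)) >= 1) {
    stop("unstable filter design: pole modulus ",
         format(max(Mod(poles))), " >= 1", call. = FALSE)
  }
  flt
}

#' Apply a filter zero-phase to a recording
#'
#' Applies the designed filter forward and backward (`signal::filtfilt`)
#' channel-wise, giving zero phase distortion and squared magnitude response.
#'
#' @param rec An [eeg_recording()] (or a numeric matrix/vector, in which case
#'   `fs` must be given).
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, only needed for bare numeric input.
#' @return Filtered data of the same class and shape as the input.
#' @export
apply_filter <- function(rec, spec, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    flt <- design_filter(spec, rec$sampling_rate)
    out <- rec
    out$data <- t(apply(rec$data, 1, function(ch) {
      signal::filtfilt(signal::Arma(b = flt$b, a = flt$a), ch)
    }))
    rownames(out$data) <- rownames(rec$data)
    return(out)
  }
  if (is.null(fs)) stop("fs required for matrix/vector input", call. = FALSE)
  flt <- design_filter(spec, fs)
  ff <- function(ch) signal::filtfilt(signal::Arma(b = flt$b, a = flt$a), ch)
  if (is.matrix(rec)) t(apply(rec, 1, ff)) else ff(rec)
}

#' Default preprocessing filter chain
#'
#' The chain applied to every recording before segmentation: a 50 Hz notch
#' (Q = 30) followed by a 0.1-60 Hz elliptic band-pass (order 4, 1 dB
#' passband ripple, 40 dB stopband). A Chebyshev type-II band-pass of the
#' same band is available by setting `bandpass = "chebyshev2_bandpass"`.
#'
#' @param bandpass Which band-pass design to use.
#' @return A list of [filter_spec()] objects, applied in order.
#' @export
default_filters <- function(bandpass = c("elliptic_bandpass",
                                         "chebyshev2_bandpass")) {
  bandpass <- match.arg(bandpass)
  list(filter_spec("notch", center_hz = 50, q = 30),
       filter_spec(bandpass, low_hz = 0.1, high_hz = 60, order = 4,
                   stopband_db = 40, ripple_db = 1))
}

#' Run the full preprocessing chain on one recording
#'
#' Optionally removes artifact components by ICA, then applies the filter
#' chain (notch, band-pass). ICA precedes filtering so that slow ocular
#' transients are still visible to the blink detector.
#'
#' @param rec An [eeg_recording()].
#' @param filters List of [filter_spec()]s, in application order.
#' @param ica If `TRUE`, run ICA artifact rejection first.
#' @param ica_criteria Rejection thresholds, see [reject_artifact_components()].
#' @param seed Seed for the ICA initialisation.
#' @return The preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, filters = default_filters(),
                                 ica = FALSE,
                                 ica_criteria = list(blink_cor = 0.8,
                                                     kurtosis = 5),
                                 seed = 1) {
  if (ica) {
    fit <- run_ica(rec, seed = seed)
    fit <- reject_artifact_components(fit, rec, ica_criteria)
    rec$data <- ica_reconstruct(fit)
  }
  for (spec in filters) rec <- apply_filter(rec, spec)
  rec
}
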