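#' Convert voice fundamental frequency between Hertz and cents
#'
#' Vocal pitch responses are analysed on the cent scale, a log-frequency scale
#' on which 100 cents equal one semitone and 1200 cents one octave:
#' `cents = 1200 * log2(f0 / reference)`. The default reference is the G3 note
#' (195.997 Hz), a conventional anchor near typical speaking pitch, so that
#' responses from speakers with very different absolute F0 are comparable.
#'
#' `cents_to_hz()` is the exact inverse; the round trip is an identity up to
#' floating-point precision.
#'
#' @param f0_hz Numeric vector of fundamental frequencies in Hz. Must be
#'   strictly positive; `NA` (unvoiced frames) pass through.
#' @param cents Numeric vector of values on the cent scale.
#' @param reference_hz Single positive number, the 0-cent reference frequency.
#' @return Numeric vector of the same length: cents relative to the reference,
#'   or Hz.
#' @examples
#' hz_to_cents(195.997)                 # 0
#' hz_to_cents(195.997 * 2^(1 / 12))    # 100 cents = 1 semitone
#' cents_to_hz(1200)                    # one octave above G3
#' @export
hz_to_cents <- function(f0_hz, reference_hz = G3_HZ) {
  check_reference(reference_hz)
  if (!is.numeric(f0_hz)) stop("`f0_hz` must be numeric")
  if (any(f0_hz <= 0, na.rm = TRUE)) {
    stop("`f0_hz` must be strictly positive (frequencies on the cent scale)")
  }
  1200 * log2(f0_hz / reference_hz)
}

#' @rdname hz_to_cents
#' @export
cents_to_hz <- function(cents, reference_hz = G3_HZ) {
  check_reference(reference_hz)
  if (!is.numeric(cents)) stop("`cents` must be numeric")
  reference_hz * 2^(cents / 1200)
}

check_reference <- function(reference_hz) {
  if (!is.numeric(reference_hz) || length(reference_hz) != 1L ||
      !is.finite(reference_hz) || reference_hz <= 0) {
    stop("`reference_hz` must be a single positive finite number")
  }
  invisible(reference_hz)
}
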