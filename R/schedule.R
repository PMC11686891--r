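#' MRF acquisition schedule
#'
#' A fingerprinting acquisition is defined by a per-excitation history of
#' flip angles, repetition times, echo times and RF phases, optionally
#' preceded by a 180-degree inversion preparation. The deliberate variation
#' of these parameters destroys the steady state and gives every (T1, T2)
#' combination a distinct transient signal evolution (its "fingerprint").
#'
#' @param flip_angle numeric vector of flip angles in degrees, one per
#'   excitation, each in \[0, 180\].
#' @param tr repetition times in ms (scalar or per-excitation vector).
#' @param te echo times in ms (scalar or per-excitation vector); must
#'   satisfy `0 <= te < tr` elementwise.
#' @param rf_phase RF pulse phase in degrees (scalar or vector); the
#'   rotation axis of each excitation lies in the transverse plane at this
#'   azimuth.
#' @param invert_first apply a 180-degree inversion pulse before the first
#'   excitation.
#' @param inversion_delay delay in ms between the inversion pulse and the
#'   first excitation.
#' @return An object of class `mrf_schedule`.
#' @seealso [default_schedule()], [simulate_fingerprint()]
#' @export
acquisition_schedule <- function(flip_angle, tr, te, rf_phase = 0,
                                 invert_first = TRUE, inversion_delay = 20) {
  n <- length(flip_angle)
  if (n < 1L) stop("schedule needs at least one excitation")
  tr <- rep_len(as.numeric(tr), n)
  te <- rep_len(as.numeric(te), n)
  rf_phase <- rep_len(as.numeric(rf_phase), n)
  if (any(flip_angle < 0 | flip_angle > 180))
    stop("flip angles must lie in [0, 180] degrees")
  if (any(te < 0) || any(tr <= te))
    stop("echo times must satisfy 0 <= te < tr")
  if (invert_first && inversion_delay < 0)
    stop("inversion_delay must be non-negative")
  structure(
    list(n_excitations = n, flip_angle = as.numeric(flip_angle), tr = tr,
         te = te, rf_phase = rf_phase, invert_first = isTRUE(invert_first),
         inversion_delay = as.numeric(inversion_delay)),
    class = "mrf_schedule")
}

#' Default fingerprinting schedule
#'
#' An inversion-prepared SSFP-style train with a fixed 9.3 ms TR and flip
#' angles following a piecewise-sinusoidal ramp capped at 70 degrees:
#' the excitation train is split into equal segments and segment `s` runs a
#' half-sine lobe peaking at `peak_flips[s]`. The published acquisitions
#' this emulates keep the exact parameter history private, so this schedule
#' is a configurable stand-in with the same structure: it excites both T1
#' and T2 sensitivity through the inversion preparation and the varying
#' flip-angle envelope.
#'
#' @param n_excitations number of excitations (default 500).
#' @param tr repetition time in ms (default 9.3).
#' @param te echo time in ms (default 2).
#' @param peak_flips peak flip angle (degrees) of each sinusoidal segment;
#'   values above 70 are capped.
#' @param inversion_delay ms between inversion and first excitation.
#' @return An `mrf_schedule`.
#' @export
default_schedule <- function(n_excitations = 500, tr = 9.3, te = 2,
                             peak_flips = c(70, 35, 55, 25, 60),
                             inversion_delay = 20) {
  peak_flips <- pmin(peak_flips, 70)
  n_seg <- length(peak_flips)
  seg <- rep(seq_len(n_seg), length.out = n_excitations,
             each = ceiling(n_excitations / n_seg))[seq_len(n_excitations)]
  pos <- stats::ave(seq_len(n_excitations), seg, FUN = seq_along)
  len <- stats::ave(seq_len(n_excitations), seg, FUN = length)
  flip <- peak_flips[seg] * sin(pi * pos / (len + 1))
  acquisition_schedule(flip, tr = tr, te = te, rf_phase = 0,
                       invert_first = TRUE,
                       inversion_delay = inversion_delay)
}

#' @export
print.mrf_schedule <- function(x, ...) {
  cat(sprintf(
    "MRF acquisition schedule: %d excitations, TR %.3g-%.3g ms, TE %.3g-%.3g ms\n",
    x$n_excitations, min(x$tr), max(x$tr), min(x$te), max(x$te)))
  cat(sprintf("  flip angles %.1f-%.1f deg; inversion prep: %s (delay %.3g ms)\n",
              min(x$flip_angle), max(x$flip_angle),
              if (x$invert_first) "yes" else "no", x$inversion_delay))
  invisible(x)
}
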