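#' Acquisition parameters for a dual gradient-echo DCE-MRI study
#'
#' Bundles the sequence and timing constants of a dual gradient-echo (DGE)
#' spoiled gradient-echo acquisition. Defaults reproduce a typical small-animal
#' protocol at 7 T: TR/TE1/TE2 = 24/2/4 ms, nominal flip angle 18 degrees,
#' 400 frames at ~1.55 s with the contrast bolus injected at frame 15.
#'
#' @param tr Repetition time in seconds.
#' @param te1,te2 First and second echo times in seconds; `te2 > te1` is
#'   required and the echo-time ratio `mu = te2/te1` is stored. At the default
#'   `mu = 2` the transverse-relaxation factor cancels exactly from the
#'   dual-echo concentration estimator.
#' @param theta_nominal Prescribed flip angle in radians (default 18 degrees).
#' @param frame_interval Time between dynamic frames in seconds.
#' @param n_frames Number of dynamic frames.
#' @param injection_frame 1-based frame index of the bolus injection.
#'
#' @return An object of class `acq_params`: a list with the above fields plus
#'   `mu = te2/te1` and `times`, the frame-start time grid in seconds
#'   (frame 1 at t = 0).
#' @export
#' @examples
#' acq <- acq_params()
#' acq$mu   # 2
acq_params <- function(tr = 0.024, te1 = 0.002, te2 = 0.004,
                       theta_nominal = 18 * pi / 180,
                       frame_interval = 1.55, n_frames = 400,
                       injection_frame = 15) {
  stopifnot(te1 > 0, te2 > te1, tr > te2,
            frame_interval > 0, n_frames >= 2,
            injection_frame >= 2, injection_frame < n_frames,
            theta_nominal > 0, theta_nominal <= pi / 2)
  structure(
    list(tr = tr, te1 = te1, te2 = te2, mu = te2 / te1,
         theta_nominal = theta_nominal,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         injection_frame = as.integer(injection_frame),
         times = (seq_len(n_frames) - 1) * frame_interval),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> TR %.1f ms, TE1/TE2 %.1f/%.1f ms (mu = %.3g), theta %.1f deg\n",
    x$tr * 1e3, x$te1 * 1e3, x$te2 * 1e3, x$mu, x$theta_nominal * 180 / pi))
  cat(sprintf("  %d frames at %.3g s (%.1f min), injection at frame %d\n",
              x$n_frames, x$frame_interval,
              x$n_frames * x$frame_interval / 60, x$injection_frame))
  invisible(x)
}

#' Baseline and saturation windows for dual-echo signal calibration
#'
#' The tip-angle and concentration estimators average the echo signals over a
#' pre-injection (baseline) window `m..n` and a late post-injection
#' (saturation) window `o..p`. The two windows must have equal length
#' (`p - o == n - m`) and the baseline window must end before the injection
#' frame. Defaults: the 10 frames ending one frame before injection, and the
#' final 10 frames of the acquisition.
#'
#' @param acq An [acq_params()] object.
#' @param m,n 1-based inclusive bounds of the pre-injection window.
#' @param o,p 1-based inclusive bounds of the saturation window
#'   (default: the last `n - m + 1` frames).
#'
#' @return An object of class `baseline_windows`: list with fields
#'   `m`, `n`, `o`, `p`.
#' @export
baseline_windows <- function(acq, m = NULL, n = NULL, o = NULL, p = NULL) {
  stopifnot(inherits(acq, "acq_params"))
  if (is.null(n)) n <- acq$injection_frame - 1L
  if (is.null(m)) m <- max(1L, n - 9L)
  if (is.null(p)) p <- acq$n_frames
  if (is.null(o)) o <- p - (n - m)
  m <- as.integer(m); n <- as.integer(n); o <- as.integer(o); p <- as.integer(p)
  if (!(m >= 1 && m <= n && n < acq$injection_frame))
    stop("baseline window must satisfy 1 <= m <= n < injection_frame")
  if (!(o >= 1 && o <= p && p <= acq$n_frames))
    stop("saturation window must satisfy 1 <= o <= p <= n_frames")
  if ((p - o) != (n - m))
    stop("windows must have equal length: (p - o) must equal (n - m)")
  structure(list(m = m, n = n, o = o, p = p), class = "baseline_windows")
}
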