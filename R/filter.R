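# Forward-backward (zero-phase) Butterworth filtering of one series.
# signal::filtfilt starts both passes from zero filter state, which leaves
# long-lived transients when the series has a large offset or trend; the
# wrapper removes the line through the endpoints, pads the residual by odd
# reflection (so the padded series is continuous and zero at the joins), and
# restores the line afterwards. A line passes a zero-phase unit-DC-gain filter
# unchanged in steady state, so this is transparent to the ideal response.
#' @keywords internal
filtfilt_padded <- function(x, b, a, pad) {
  n <- length(x)
  if (n < 8) return(x)
  line <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  r <- x - line
  pad <- max(1L, min(n - 1L, as.integer(pad)))
  xp <- c(-rev(r[2:(pad + 1)]), r, -rev(r[(n - pad):(n - 1)]))
  yp <- signal::filtfilt(b, a, xp)
  yp[(pad + 1):(pad + n)] + line
}

#' Low-pass filter a trial to remove gait oscillations
#'
#' Applies a forward-backward (zero phase lag) Butterworth filter of the given
#' order to every coordinate series, removing the step-frequency head sway
#' while leaving the trajectory-scale motion intact. The frame grid is
#' unchanged; each pedestrian's observed (contiguous) span is filtered
#' independently.
#'
#' @param trial A `stripeflow_trial`.
#' @param cutoff_hz Cutoff frequency, Hz; must lie below the Nyquist frequency.
#'   The default 0.5 Hz sits below typical ~1 Hz step-induced sway and above
#'   trajectory-scale dynamics.
#' @param order Filter order (default 4).
#' @return A filtered `stripeflow_trial` on the same grid.
#' @export
lowpass_filter_trial <- function(trial, cutoff_hz = 0.5, order = 4) {
  fs <- trial$frame_rate_hz
  if (!is.finite(fs) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    rlang::abort(
      sprintf("cutoff %.3g Hz must lie in (0, Nyquist = %.3g Hz)",
              cutoff_hz, fs / 2),
      class = "stripeflow_error_bad_cutoff"
    )
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2))
  pad <- round(3 * fs / cutoff_hz)

  d <- trial$data
  d <- d[base::order(d$id, d$time), ]
  sp <- split(seq_len(nrow(d)), d$id)
  for (idx in sp) {
    d$x[idx] <- filtfilt_padded(d$x[idx], bf$b, bf$a, pad)
    d$y[idx] <- filtfilt_padded(d$y[idx], bf$b, bf$a, pad)
  }
  trial(d, frame_rate_hz = trial$frame_rate_hz,
        expected_angle_deg = trial$expected_angle_deg)
}
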