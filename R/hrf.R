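#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response: a gamma density peaking at 6 s minus a
#' 16 s undershoot scaled by 1/6, evaluated on a fine time grid and
#' truncated at 32 s. The curve is scaled to unit peak so that a planted
#' amplitude of `a` produces a peak BOLD deflection of `a` signal units.
#'
#' @param t Numeric vector of times (seconds, >= 0).
#' @param peak_delay,undershoot_delay Gamma shape parameters (seconds);
#'   scale is fixed at 1 s.
#' @param undershoot_ratio Weight of the undershoot gamma.
#' @param duration Support of the response; values of `t` beyond it give 0.
#' @return Numeric vector, same length as `t`.
#' @export
#' @examples
#' h <- canonical_hrf(seq(0, 32, by = 0.1))
#' max(h) # 1
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 1 / 6, duration = 32) {
  h <- stats::dgamma(t, shape = peak_delay, scale = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_delay, scale = 1)
  h[t < 0 | t > duration] <- 0
  fine <- seq(0, duration, by = 0.01)
  peak <- max(stats::dgamma(fine, shape = peak_delay, scale = 1) -
    undershoot_ratio * stats::dgamma(fine, shape = undershoot_delay, scale = 1))
  h / peak
}

# Microtime resolution (s) at which regressors are built before
# downsampling to the TR grid.
MICROTIME_DT <- 0.1

#' Canonical HRF basis: response, temporal and dispersion derivatives
#'
#' The temporal derivative is the (negated) derivative of the HRF with
#' respect to onset time; the dispersion derivative is the sensitivity to a
#' common widening of both gamma components. Both are computed by central /
#' forward finite differences on the microtime grid, the convention used by
#' the standard informed basis set.
#'
#' @param dt Microtime step in seconds.
#' @return A list with `time` and three kernels `hrf`, `tderiv`, `ddisp`,
#'   each sampled at `dt` on `[0, 32]` s.
#' @export
hrf_basis <- function(dt = MICROTIME_DT) {
  tt <- seq(0, 32, by = dt)
  h <- canonical_hrf(tt)
  # shift by one microtime step: response to an onset dt earlier
  h_shift <- canonical_hrf(tt + dt)
  tderiv <- (h_shift - h) / dt
  eps <- 0.01
  h_disp <- canonical_hrf(tt, peak_delay = 6 * (1 + eps),
                          undershoot_delay = 16 * (1 + eps))
  ddisp <- (h - h_disp) / eps
  list(time = tt, hrf = h, tderiv = tderiv, ddisp = ddisp)
}

#' Convolve event onsets with a kernel and sample on the TR grid
#'
#' Builds a microtime stick function (one unit impulse per onset, optionally
#' weighted), convolves it with the kernel by FFT, and samples the result at
#' volume acquisition times `0, TR, 2 TR, ...`.
#'
#' @param onsets Event onsets in seconds from run start.
#' @param n_vol Number of volumes in the run.
#' @param tr Repetition time (s).
#' @param kernel Microtime kernel (e.g. `hrf_basis()$hrf`).
#' @param weights Optional per-onset amplitudes (default 1).
#' @param dt Microtime step used for `kernel`.
#' @return Numeric vector of length `n_vol`.
#' @export
convolve_onsets <- function(onsets, n_vol, tr, kernel = hrf_basis()$hrf,
                            weights = NULL, dt = MICROTIME_DT) {
  if (is.null(weights)) weights <- rep(1, length(onsets))
  stopifnot(length(weights) == length(onsets))
  n_micro <- ceiling(n_vol * tr / dt) + length(kernel)
  stick <- numeric(n_micro)
  idx <- pmin(n_micro, round(onsets / dt) + 1L)
  for (k in seq_along(idx)) stick[idx[k]] <- stick[idx[k]] + weights[k]
  conv <- stats::convolve(stick, rev(kernel), type = "open")[seq_len(n_micro)]
  vol_idx <- round((seq_len(n_vol) - 1) * tr / dt) + 1L
  conv[vol_idx]
}
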