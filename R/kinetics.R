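## Time-series quantification of ligand binding: compartmental intensity
## traces, exponential association fits, washout loss, FRAP recovery and
## window-averaged F/F0 summaries.

#' Compartmental intensity traces from a masked movie
#'
#' Quantifies a movie in two disjoint compartments: synaptic (inside the PSD
#' mask) and extrasynaptic (cell mask minus PSD mask). Per frame the
#' integrated density is the sum of background-subtracted intensities,
#' \eqn{\sum (I - \bar{b})}, with \eqn{\bar{b}} the mean intensity in the
#' background ROI of that frame.
#'
#' @param movie list of 3D arrays (or 2D matrices), one per frame.
#' @param times frame times in seconds.
#' @param psd_mask,cell_mask,background_mask logical arrays matching the
#'   frame geometry; `background_mask` should be disjoint from `cell_mask`.
#' @return list with `synaptic` and `extrasynaptic` [intensity_trace()]s.
#' @export
compartment_traces <- function(movie, times, psd_mask, cell_mask, background_mask) {
  for (nm in c("psd_mask", "cell_mask", "background_mask")) {
    m <- get(nm)
    if (!any(m)) stop(sprintf("empty mask: %s", nm))
  }
  if (any(background_mask & cell_mask)) {
    warning("background ROI overlaps the cell mask")
  }
  syn <- psd_mask
  extra <- cell_mask & !psd_mask
  vals <- vapply(movie, function(fr) {
    b <- mean(fr[background_mask])
    c(sum(fr[syn]) - b * sum(syn), sum(fr[extra]) - b * sum(extra))
  }, numeric(2))
  list(synaptic = intensity_trace(times, vals[1, ], compartment = "synaptic"),
       extrasynaptic = intensity_trace(times, vals[2, ], compartment = "extrasynaptic"))
}

#' Normalize a trace to a baseline window (F/F0)
#'
#' Divides by the mean value over `frame_range`; by construction the mean of
#' the normalized trace over that range is 1, and normalizing an
#' already-normalized trace is the identity.
#'
#' @param trace an [intensity_trace()].
#' @param frame_range integer indices of the baseline frames.
#' @return a normalized `intensity_trace`.
#' @export
normalize_trace <- function(trace, frame_range) {
  f0 <- mean(trace$value[frame_range])
  if (!is.finite(f0) || f0 == 0) stop("baseline mean is zero or non-finite")
  intensity_trace(trace$time_s, trace$value / f0,
                  compartment = attr(trace, "compartment"),
                  normalized = TRUE, normalization_range = frame_range)
}

#' Fit single-exponential association kinetics
#'
#' Least-squares fit of
#' `F(t) = baseline + (plateau - baseline) (1 - exp(-t / tau))`
#' to a normalized binding trace, with the baseline fixed (default 1, the
#' pre-addition F/F0 level). `tau` is reported in minutes. When the fitted
#' amplitude is indistinguishable from the residual noise the time constant
#' is unidentifiable and the result is flagged not converged rather than
#' returning a silent number.
#'
#' @param trace a normalized [intensity_trace()] (>= 5 points).
#' @param baseline fixed starting level (default 1).
#' @return object of class `exp_fit_result`: `plateau`, `tau` (min), `sse`,
#'   `converged`, `message`.
#' @export
fit_association <- function(trace, baseline = 1) {
  if (nrow(trace) < 5L) stop("need at least 5 points")
  t_min <- trace$time_s / 60
  v <- trace$value
  plateau0 <- mean(utils::tail(v, max(3L, nrow(trace) %/% 5L)))
  amp0 <- plateau0 - baseline
  tau0 <- max(diff(range(t_min)) / 5, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ baseline + (plateau - baseline) * (1 - exp(-t_min / tau)),
                      start = list(plateau = baseline + ifelse(amp0 == 0, 0.1, amp0),
                                   tau = tau0),
                      lower = c(plateau = -Inf, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(plateau = plateau0, tau = NA_real_, sse = NA_real_,
                          converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "exp_fit_result"))
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  sse <- sum(res^2)
  amp <- cf[["plateau"]] - baseline
  noise <- stats::sd(res)
  identifiable <- abs(amp) > 1e-8 + 3 * noise / sqrt(nrow(trace))
  structure(list(plateau = cf[["plateau"]], tau = cf[["tau"]], sse = sse,
                 converged = identifiable,
                 message = if (identifiable) "ok" else
                   "amplitude indistinguishable from noise; tau unidentifiable"),
            class = "exp_fit_result")
}

#' Percent signal loss after washout
#'
#' `loss = 100 (1 - F(t_w + horizon) / F(t_w))`, with `t_w` the washout time;
#' an optional photobleaching control (fraction lost over the same window in
#' fixed samples) is subtracted in percentage points. Scale-invariant in the
#' raw trace.
#'
#' @param trace an [intensity_trace()].
#' @param washout_time time of washout in seconds.
#' @param horizon interval after washout in seconds (must lie inside the
#'   trace).
#' @param photobleach_control fraction in \[0, 1\] lost to photobleaching
#'   (default 0); `0.022` subtracts 2.2 percentage points.
#' @return percent loss (can be negative if signal rises).
#' @export
quantify_washout <- function(trace, washout_time, horizon, photobleach_control = 0) {
  t2 <- washout_time + horizon
  if (washout_time < min(trace$time_s) || t2 > max(trace$time_s)) {
    stop("washout window must lie within the trace")
  }
  fw <- stats::approx(trace$time_s, trace$value, xout = washout_time)$y
  fh <- stats::approx(trace$time_s, trace$value, xout = t2)$y
  if (fw <= 0) stop("signal at washout is not positive")
  100 * (1 - fh / fw) - 100 * photobleach_control
}

#' Fit FRAP recovery kinetics
#'
#' Normalizes to the prebleach mean, then fits the postbleach recovery
#' `F(t) = Fb + (Finf - Fb)(1 - exp(-k t))` with the bleach depth `Fb` fixed
#' at the first postbleach value. The mobile fraction is
#' `(Finf - Fb) / (1 - Fb)` (clipped to \[0, 1\] with a warning) and the
#' recovery rate `k` is per minute (`tau = 1/k` is also reported; some
#' conventions quote the recovery timescale in minutes instead of the rate).
#'
#' @param trace an [intensity_trace()] (raw or normalized).
#' @param bleach_frame index of the first postbleach point (>= 4, with at
#'   least 5 postbleach points).
#' @return object of class `frap_fit_result`: `mobile_fraction`, `rate`
#'   (1/min), `tau` (min), `bleach_depth`, `converged`.
#' @export
fit_frap <- function(trace, bleach_frame) {
  n <- nrow(trace)
  if (bleach_frame < 4L) stop("need at least 3 prebleach points")
  if (n - bleach_frame + 1L < 5L) stop("need at least 5 postbleach points")
  pre <- trace$value[seq_len(bleach_frame - 1L)]
  f0 <- mean(pre)
  v <- trace$value / f0
  fb <- v[bleach_frame]
  if (fb >= 1) stop("no bleach detected: postbleach level is not below prebleach")
  t_min <- (trace$time_s[bleach_frame:n] - trace$time_s[bleach_frame]) / 60
  y <- v[bleach_frame:n]
  if (stats::sd(y) < 1e-12 || all(abs(y - fb) < 1e-10)) {
    return(structure(list(mobile_fraction = (mean(y) - fb) / (1 - fb),
                          rate = NA_real_, tau = NA_real_, bleach_depth = fb,
                          converged = TRUE),
                     class = "frap_fit_result"))
  }
  finf0 <- mean(utils::tail(y, max(3L, length(y) %/% 5L)))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fb + (finf - fb) * (1 - exp(-k * t_min)),
                      start = list(finf = max(finf0, fb + 1e-3), k = 0.2),
                      lower = c(finf = fb, k = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(mobile_fraction = NA_real_, rate = NA_real_,
                          tau = NA_real_, bleach_depth = fb, converged = FALSE),
                     class = "frap_fit_result"))
  }
  cf <- stats::coef(fit)
  mf <- (cf[["finf"]] - fb) / (1 - fb)
  if (mf < 0 || mf > 1) {
    warning(sprintf("mobile fraction %.3g outside [0, 1]; clipped", mf))
    mf <- min(max(mf, 0), 1)
  }
  structure(list(mobile_fraction = mf, rate = cf[["k"]], tau = 1 / cf[["k"]],
                 bleach_depth = fb, converged = TRUE),
            class = "frap_fit_result")
}

#' Mean normalized intensity over a time window
#'
#' Arithmetic mean of the trace values inside the closed window, e.g. the
#' average F/F0 over the final minutes of imaging compared with baseline.
#'
#' @param trace an [intensity_trace()].
#' @param window `c(t0, t1)` in seconds, inside the trace.
#' @return mean value.
#' @export
window_mean <- function(trace, window) {
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (!any(sel)) stop("window contains no trace points")
  mean(trace$value[sel])
}
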