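#' Periodic haemodynamic waveform
#'
#' A `waveform` is one period of a sampled haemodynamic signal: volume flow
#' rate, luminal cross-sectional area or pressure. Values are stored in SI
#' units (m^3/s, m^2, Pa); use [read_waveform()] / [write_waveform()] or
#' [to_si()] for clinical units.
#'
#' @param times numeric, strictly increasing sample times in seconds,
#'   spanning at most one period.
#' @param values numeric samples, same length as `times`, in SI units.
#' @param quantity one of `"flow"`, `"area"`, `"pressure"`.
#' @param period cycle duration in seconds; defaults to the sample span
#'   extended by one mean sample interval (i.e. the samples tile the cycle).
#' @return an object of class `waveform` with fields `times`, `values`,
#'   `quantity`, `period`.
#' @examples
#' t <- seq(0, 0.95, by = 0.05)
#' w <- waveform(t, 1e-4 * (1 + sin(2 * pi * t)), "flow", period = 1)
#' waveform_mean(w)
#' @export
waveform <- function(times, values,
                     quantity = c("flow", "area", "pressure"),
                     period = NULL) {
  quantity <- match.arg(quantity)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 16L)
    stop("a waveform needs at least 16 samples")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (is.null(period))
    period <- (times[length(times)] - times[1]) * length(times) /
      (length(times) - 1)
  if (period <= 0) stop("period must be positive")
  span <- times[length(times)] - times[1]
  if (span > period * (1 + 1e-9))
    stop("samples span more than one period")
  structure(
    list(times = times, values = values, quantity = quantity,
         period = period),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cu <- clinical_unit_of(x$quantity)
  cat(sprintf(
    "<waveform> %s, %d samples, period %.4g s, mean %.4g %s\n",
    x$quantity, length(x$times), x$period,
    from_si(waveform_mean(x), cu), cu))
  invisible(x)
}

#' Cycle statistics of a waveform
#'
#' `waveform_mean()` integrates the periodic signal over one cycle
#' (trapezoidal rule with periodic closure) and divides by the period, so it
#' is exact for the cycle average rather than a plain sample mean.
#' `waveform_max()`/`waveform_min()` return the extreme sample values.
#'
#' @param w a [waveform].
#' @return a scalar in SI units.
#' @export
waveform_mean <- function(w) {
  t <- w$times; v <- w$values
  ## close the cycle: wrap the first sample to t[1] + period
  tt <- c(t, t[1] + w$period)
  vv <- c(v, v[1])
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / w$period
}

#' @rdname waveform_mean
#' @export
waveform_max <- function(w) max(w$values)

#' @rdname waveform_mean
#' @export
waveform_min <- function(w) min(w$values)

#' Heart rate of a waveform in beats per minute
#' @param w a [waveform].
#' @return HR in bpm (`60 / period`).
#' @export
waveform_heart_rate <- function(w) 60 / w$period

#' Evaluate a periodic waveform at arbitrary times
#'
#' Periodic interpolation: cubic spline with periodic end conditions by
#' default, linear as a fallback for non-smooth signals.
#'
#' @param w a [waveform].
#' @param t numeric times (any real values; reduced modulo the period).
#' @param method `"spline"` (periodic cubic) or `"linear"`.
#' @return numeric values at `t`.
#' @export
waveform_at <- function(w, t, method = c("spline", "linear")) {
  method <- match.arg(method)
  tau <- (t - w$times[1]) %% w$period + w$times[1]
  tt <- c(w$times, w$times[1] + w$period)
  vv <- c(w$values, w$values[1])
  if (method == "spline") {
    f <- stats::splinefun(tt, vv, method = "periodic")
    f(tau)
  } else {
    stats::approx(tt, vv, xout = tau, rule = 2)$y
  }
}

#' Resample a waveform onto a uniform grid
#'
#' @param w a [waveform].
#' @param n number of uniform samples per cycle.
#' @param method interpolation method, see [waveform_at()].
#' @return a new [waveform] with `n` samples starting at the original first
#'   sample time.
#' @export
waveform_resample <- function(w, n = 256L, method = "spline") {
  t <- w$times[1] + w$period * (seq_len(n) - 1L) / n
  waveform(t, waveform_at(w, t, method = method), w$quantity,
           period = w$period)
}

#' Rescale the time axis of a waveform to a new period
#'
#' Affine rescaling `t -> t0 + (t - t0) * new_period / period`; sample
#' values are untouched, so the cycle-mean value is preserved exactly.
#' Used for heart-rate harmonization.
#'
#' @param w a [waveform].
#' @param period new period in seconds.
#' @return a [waveform] with the new period.
#' @export
waveform_set_period <- function(w, period) {
  stopifnot(period > 0)
  s <- period / w$period
  waveform(w$times[1] + (w$times - w$times[1]) * s, w$values, w$quantity,
           period = period)
}

#' Downsample a waveform by cycle-uniform bin averaging
#'
#' Emulates gated MRI reconstruction with a fixed number of cardiac phases:
#' the cycle is split into `phases` equal bins and the signal averaged
#' within each bin (midpoint sample time).
#'
#' @param w a [waveform].
#' @param phases number of bins (default 40, as in gated PC-MRI protocols).
#' @param oversample internal fine sampling per bin.
#' @return a [waveform] with `phases` samples.
#' @export
waveform_gate <- function(w, phases = 40L, oversample = 16L) {
  edges <- w$times[1] + w$period * (0:phases) / phases
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  vals <- vapply(seq_len(phases), function(i) {
    tt <- seq(edges[i], edges[i + 1], length.out = oversample)
    mean(waveform_at(w, tt))
  }, numeric(1))
  waveform(mids, vals, w$quantity, period = w$period)
}
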