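#' Detect the foot of a pulse wave
#'
#' Intersecting-tangents algorithm: the foot is the intersection of (i) the
#' horizontal line through the pre-systolic local minimum and (ii) the
#' tangent through the point of maximum gradient of the systolic upstroke.
#' The local minimum is the last one preceding (cyclically) the point of
#' maximum gradient, which makes the detection robust to diastolic ripples.
#'
#' @param w a [waveform] with a rising systolic limb.
#' @return list with `foot_time`, `local_min_time`, `max_gradient_time`
#'   (all within one period of the waveform's time axis), `slope` and
#'   `intercept` of the tangent line.
#' @export
detect_foot <- function(w) {
  t <- w$times; v <- w$values; n <- length(t)
  if (diff(range(v)) <= .Machine$double.eps * max(abs(v), 1))
    stop("flat waveform: no systolic upstroke to detect")
  ## periodic central differences
  ip <- c(n, seq_len(n - 1L)); im <- c(seq_len(n - 1L) + 1L, 1L) # prev, next
  tp <- t[ip] - ifelse(seq_len(n) == 1L, w$period, 0)
  tn <- t[im] + ifelse(seq_len(n) == n, w$period, 0)
  dv <- (v[im] - v[ip]) / (tn - tp)
  ig <- which.max(dv)
  if (dv[ig] <= 0) stop("flat waveform: no systolic upstroke to detect")
  ## last local minimum preceding the maximum-gradient point (cyclic scan)
  imin <- NA_integer_
  for (k in seq_len(n - 1L)) {
    j <- ((ig - 1L - k) %% n) + 1L
    jp <- (j %% n) + 1L; jm <- ((j - 2L) %% n) + 1L
    if (v[j] <= v[jp] && v[j] <= v[jm]) { imin <- j; break }
  }
  if (is.na(imin)) imin <- which.min(v)
  tmin <- t[imin]
  ## unwrap so the minimum precedes the gradient point
  if (tmin > t[ig]) tmin <- tmin - w$period
  slope <- dv[ig]
  foot <- t[ig] + (v[imin] - v[ig]) / slope
  list(foot_time = foot, local_min_time = tmin,
       max_gradient_time = t[ig], slope = slope,
       intercept = v[ig] - slope * t[ig])
}

#' Foot-to-foot pulse wave velocity
#'
#' Diastolic pulse wave velocity as the ratio of the centreline distance
#' between two measurement sites to the transit time of the wave foot,
#' with feet located by [detect_foot()].
#'
#' @param w_proximal,w_distal [waveform]s at the proximal and distal sites
#'   on a common clock.
#' @param path_length centreline distance between the sites, m.
#' @param n fine resampling grid used before foot detection (periodic
#'   spline; emulates working on the post-processed waves rather than the
#'   raw cardiac phases).
#' @return speed in m/s.
#' @export
foot_to_foot_speed <- function(w_proximal, w_distal, path_length, n = 512L) {
  stopifnot(path_length > 0)
  ## resample to a fine grid first (the post-processed wave): gated signals
  ## with few cardiac phases resolve the foot too coarsely otherwise
  wp <- waveform_resample(w_proximal, n)
  wd <- waveform_resample(w_distal, n)
  tt <- detect_foot(wd)$foot_time - detect_foot(wp)$foot_time
  if (tt <= 0)
    stop("non-positive transit time: are the waveforms ordered ",
         "proximal, distal?")
  path_length / tt
}

#' QA-loop pulse wave velocity
#'
#' Local diastolic wave speed from the slope dQ/dA of the flow-area loop
#' over the early-systolic limb, where the loop is approximately linear
#' because reflections have not yet arrived. The fit window starts at the
#' detected foot of the flow wave and its end is scanned from shortly after
#' the foot up to the time of maximum dQ/dt plus a margin; the window with
#' the largest linear-fit R-squared is kept.
#'
#' @param q flow [waveform] (m^3/s).
#' @param a area [waveform] (m^2) at the same site.
#' @param n resampling grid size for loop construction.
#' @param margin window-end margin past the time of maximum dQ/dt, as a
#'   fraction of the period (default 0: the window never extends past the
#'   maximum upstroke gradient, before reflections from nearby junctions
#'   reach the loop).
#' @return list with `speed` (m/s, the loop slope), `window` (start/end
#'   times), `r_squared`, and the windowed `Q`, `A` samples.
#' @export
qa_loop_speed <- function(q, a, n = 256L, margin = 0) {
  if (abs(q$period - a$period) > 1e-9 * q$period)
    stop("flow and area waveforms must share a period")
  qs <- waveform_resample(q, n)
  as <- waveform(qs$times, waveform_at(a, qs$times), "area",
                 period = a$period)
  if (diff(range(as$values)) <= 0)
    stop("degenerate QA loop: no area variation")
  ft <- detect_foot(qs)
  i0 <- which.min(abs(qs$times - ft$foot_time))
  ig <- which.min(abs(qs$times - ft$max_gradient_time))
  iend_max <- ig + as.integer(ceiling(margin * n))
  idx_of <- function(i) ((i - 1L) %% n) + 1L
  best <- NULL
  for (iend in seq(i0 + 3L, iend_max)) {
    sel <- idx_of(seq(i0, iend))
    A <- as$values[sel]; Q <- qs$values[sel]
    if (stats::sd(A) == 0) next
    fit <- stats::lm.fit(cbind(1, A), Q)
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((Q - mean(Q))^2), .Machine$double.xmin)
    if (is.null(best) || r2 > best$r2)
      best <- list(r2 = r2, slope = fit$coefficients[2], sel = sel,
                   t0 = qs$times[idx_of(i0)], t1 = qs$times[idx_of(iend)])
  }
  if (is.null(best)) stop("degenerate QA loop: no usable fit window")
  list(speed = unname(best$slope),
       window = c(start = best$t0, end = best$t1),
       r_squared = best$r2,
       Q = qs$values[best$sel], A = as$values[best$sel])
}

#' Fit a speed-diameter power law
#'
#' Least-squares fit of \eqn{c = a d^b} in log-log space to pairs of
#' diastolic diameter and diastolic wave speed. For the tube law with a
#' spatially uniform elastic parameter the expected exponent is
#' \eqn{b = -1/2}.
#'
#' @param d diastolic diameters, m.
#' @param c_d diastolic wave speeds, m/s.
#' @return object of class `power_law_fit` with fields `a`, `b`, `rss`
#'   (residual sum of squares in log space) and the `pairs` used.
#' @export
fit_speed_diameter_power_law <- function(d, c_d) {
  stopifnot(length(d) == length(c_d), length(d) >= 2,
            all(d > 0), all(c_d > 0))
  if (length(unique(d)) < 2L)
    stop("power-law fit needs at least two distinct diameters")
  X <- cbind(1, log(d))
  fit <- stats::lm.fit(X, log(c_d))
  structure(
    list(a = exp(unname(fit$coefficients[1])),
         b = unname(fit$coefficients[2]),
         rss = sum(fit$residuals^2),
         pairs = data.frame(d = d, c_d = c_d)),
    class = "power_law_fit"
  )
}

#' @rdname fit_speed_diameter_power_law
#' @param fit a `power_law_fit`.
#' @param d diameters (m) at which to evaluate the law.
#' @export
predict_power_law <- function(fit, d) {
  stopifnot(inherits(fit, "power_law_fit"), all(d > 0))
  fit$a * d^fit$b
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> c = %.4g * d^%.4g (%d pairs, log-RSS %.3g)\n",
              x$a, x$b, nrow(x$pairs), x$rss))
  invisible(x)
}
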