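#' Three-element Windkessel parameters
#'
#' Lumped model of the vasculature downstream of a terminal branch: a
#' proximal resistance `R1` in series with the parallel combination of a
#' distal resistance `R2` and a compliance `C`, discharging to the outflow
#' pressure `Pout` (interpretable as the pressure at which flow to the
#' microcirculation ceases).
#'
#' @param R1 proximal resistance, Pa s/m^3 (>= 0).
#' @param R2 distal resistance, Pa s/m^3 (> 0).
#' @param C compliance, m^3/Pa (> 0).
#' @param Pout outflow pressure, Pa.
#' @return object of class `windkessel_params`.
#' @export
windkessel_params <- function(R1, R2, C, Pout) {
  stopifnot(R1 >= 0, R2 > 0, C > 0)
  structure(list(R1 = R1, R2 = R2, C = C, Pout = Pout),
            class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf(
    "<windkessel> R1 %.3g, R2 %.3g Pa s/m^3, C %.3g m^3/Pa, Pout %.3g mmHg\n",
    x$R1, x$R2, x$C, from_si(x$Pout, "mmHg")))
  invisible(x)
}

#' Fit the exponential diastolic pressure decay
#'
#' Nonlinear least-squares fit of
#' \deqn{P(t) = P_\infty + (P_0 - P_\infty) e^{-(t - t_0)/\tau}}
#' to the late-diastolic part of a pressure waveform. When no window is
#' given, the decay interval is taken from the systolic peak to the
#' pre-upstroke minimum of the next beat, candidate start times are
#' scanned over the final 60% of that interval, and the window whose fit
#' has the largest R-squared is kept.
#'
#' @param p pressure [waveform] (Pa).
#' @param window optional `c(start, end)` times bounding the fit.
#' @param n_candidates number of candidate start times scanned in
#'   automatic-window mode.
#' @return list with `P_inf`, `tau`, `P0`, `t0`, `window`, `r_squared`.
#' @export
fit_diastolic_decay <- function(p, window = NULL, n_candidates = 12L) {
  pr <- waveform_resample(p, 512L)
  if (!is.null(window)) {
    starts <- window[1]; tend <- window[2]
  } else {
    ipk <- which.max(pr$values)
    tpk <- pr$times[ipk]
    ## diastole ends at the pre-upstroke local minimum of the next beat
    tmin <- detect_foot(pr)$local_min_time
    tend <- if (tmin > tpk) tmin else tmin + pr$period
    tend <- tend - 0.01 * pr$period
    span <- tend - tpk
    starts <- tpk + span * seq(0.4, 0.9, length.out = n_candidates)
  }
  best <- NULL
  for (t0 in starts) {
    tt <- seq(t0, tend, length.out = 64L)
    vv <- waveform_at(pr, tt)
    if (vv[1] <= vv[length(vv)]) next       # not decaying
    dat <- data.frame(t = tt - t0, P = vv)
    Pinf0 <- max(min(vv) - 0.5 * (vv[1] - min(vv)), 1e3)
    tau0 <- (tt[length(tt)] - tt[1]) /
      max(log((vv[1] - Pinf0) / max(vv[length(vv)] - Pinf0, 1)), 0.5)
    fit <- try(minpack.lm::nlsLM(
      P ~ Pinf + (P0 - Pinf) * exp(-t / tau), data = dat,
      start = list(Pinf = Pinf0, P0 = vv[1], tau = max(tau0, 0.1)),
      lower = c(-1e6, 0, 1e-3), upper = c(vv[1], 2 * vv[1], 100),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cf <- stats::coef(fit)
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((vv - mean(vv))^2)
    if (is.null(best) || r2 > best$r_squared)
      best <- list(P_inf = unname(cf["Pinf"]), tau = unname(cf["tau"]),
                   P0 = unname(cf["P0"]), t0 = t0,
                   window = c(start = t0, end = tend), r_squared = r2)
  }
  if (is.null(best))
    stop("diastolic decay fit failed: window does not decay")
  best
}

#' Total resistance at the root of the arterial network
#'
#' \deqn{R_T = (\bar P - P_{out}) / \bar Q}
#' with \eqn{\bar P} the mean calibration (carotid) pressure and
#' \eqn{\bar Q} the mean aortic root inflow.
#'
#' @param mean_pressure mean pressure, Pa.
#' @param Pout outflow pressure, Pa.
#' @param mean_inflow mean inflow, m^3/s.
#' @return RT in Pa s/m^3.
#' @export
total_resistance <- function(mean_pressure, Pout, mean_inflow) {
  if (mean_pressure <= Pout)
    stop("mean pressure must exceed the outflow pressure")
  if (mean_inflow <= 0) stop("mean inflow must be positive")
  (mean_pressure - Pout) / mean_inflow
}

#' Terminal total resistances from the flow distribution
#'
#' \deqn{R_{T,j} = R_T / \gamma_j} where \eqn{\gamma_j} is the fraction of
#' cardiac output leaving terminal j. The parallel combination recovers
#' \eqn{R_T} exactly.
#'
#' @param RT root total resistance, Pa s/m^3.
#' @param gamma named vector of flow fractions (must sum to 1, all > 0).
#' @return named vector of per-terminal total resistances.
#' @export
terminal_total_resistances <- function(RT, gamma) {
  if (any(gamma <= 0)) stop("flow fractions must be positive")
  if (abs(sum(gamma) - 1) > 1e-8) stop("flow fractions must sum to 1")
  RT / gamma
}

#' Conduit compliance of the 1D network
#'
#' Sum over segments of the axial integral of the local area compliance of
#' the tube law at diastolic conditions,
#' \deqn{C_c = \sum_s \int_0^{L_s} \frac{2 A_d(x)^{3/2}}{\beta(x)}\,dx.}
#'
#' @param net a [network] with wave speeds assigned.
#' @return conduit compliance in m^3/Pa.
#' @export
conduit_compliance <- function(net) {
  total <- 0
  for (id in net$segments$id) {
    L <- seg_row(net, id)$length
    f <- function(frac) {
      m <- segment_material_at(net, id, frac)
      2 * m$Ad^1.5 / m$beta
    }
    total <- total + L * stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  total
}

#' Total systemic compliance
#'
#' Two estimators, matching the two outflow-pressure strategies:
#' * `"fitted"`: from the diastolic decay time constant,
#'   \eqn{C_T = \tau / R_T};
#' * `"capillary"`: from the inflow extrema and carotid pulse pressure,
#'   \eqn{C_T = (Q_{max} - Q_{min})\,\Delta t / (P_s - P_d)}, with
#'   \eqn{\Delta t} the (cyclic) time between the inflow extrema: the
#'   minimum sits just before the systolic upstroke, so the distance is
#'   measured across the cycle wrap when shorter.
#'
#' @param mode `"fitted"` or `"capillary"`.
#' @param RT root total resistance (fitted mode), Pa s/m^3.
#' @param tau diastolic decay time constant (fitted mode), s.
#' @param inflow aortic root inflow [waveform] (capillary mode).
#' @param p_sys,p_dias systolic and diastolic carotid pressures, Pa
#'   (capillary mode).
#' @return CT in m^3/Pa.
#' @export
total_compliance <- function(mode = c("fitted", "capillary"),
                             RT = NULL, tau = NULL, inflow = NULL,
                             p_sys = NULL, p_dias = NULL) {
  mode <- match.arg(mode)
  if (mode == "fitted") {
    if (is.null(RT) || is.null(tau)) stop("fitted mode needs RT and tau")
    tau / RT
  } else {
    if (is.null(inflow) || is.null(p_sys) || is.null(p_dias))
      stop("capillary mode needs the inflow and carotid pressures")
    imax <- which.max(inflow$values); imin <- which.min(inflow$values)
    dt <- abs(inflow$times[imax] - inflow$times[imin])
    dt <- min(dt, inflow$period - dt)   # extrema straddle the cycle wrap
    dq <- inflow$values[imax] - inflow$values[imin]
    if (p_sys <= p_dias) stop("pulse pressure must be positive")
    dq * dt / (p_sys - p_dias)
  }
}

#' Distribute peripheral compliance to the terminals
#'
#' The total peripheral compliance \eqn{C_p = C_T - C_c} is first split in
#' proportion to the flow distribution, \eqn{C_{p,j} = \gamma_j C_p}.
#' Because the three-element Windkessel stores its compliance behind the
#' proximal resistance, the value entered in the model is the
#' low-frequency-equivalent
#' \deqn{C_j = C_{p,j} \left(R_{T,j}/R_{2,j}\right)^2,}
#' which reduces to the plain split when \eqn{R_{1,j} = 0}.
#'
#' @param Cp total peripheral compliance, m^3/Pa (> 0).
#' @param gamma flow fractions (sum to 1).
#' @param RTj per-terminal total resistances, Pa s/m^3.
#' @param R1j per-terminal proximal resistances, Pa s/m^3.
#' @return list with `Cpj` (the proportional split) and `C` (the Windkessel
#'   compliances).
#' @export
distribute_compliances <- function(Cp, gamma, RTj, R1j) {
  if (Cp <= 0) stop("peripheral compliance must be positive ",
                    "(is the network stiffer than the whole circulation?)")
  R2j <- RTj - R1j
  if (any(R2j <= 0))
    stop("proximal resistance exceeds a terminal's total resistance")
  Cpj <- gamma * Cp
  list(Cpj = Cpj, C = Cpj * (RTj / R2j)^2)
}

#' Characteristic impedance of a vessel end point
#'
#' \deqn{Z_0 = \rho c_d / A_d} evaluated at diastolic conditions. A
#' terminal with `R1 = Z0` absorbs incident wavefronts ("matched").
#'
#' @param c_d diastolic wave speed, m/s.
#' @param Ad diastolic area, m^2.
#' @param rho blood density, kg/m^3.
#' @return Z0 in Pa s/m^3.
#' @export
characteristic_impedance <- function(c_d, Ad, rho) {
  stopifnot(all(c_d > 0), all(Ad > 0), rho > 0)
  rho * c_d / Ad
}

#' Reflection coefficient of a terminal
#'
#' \deqn{R_f = (R_1 - Z_0)/(R_1 + Z_0)}; lies in (-1, 1) for positive
#' arguments, 0 for a matched terminal, -1 for an open end.
#'
#' @param R1 proximal resistance, Pa s/m^3.
#' @param Z0 characteristic impedance, Pa s/m^3.
#' @return dimensionless reflection coefficient.
#' @export
reflection_coefficient <- function(R1, Z0) {
  if (any(R1 + Z0 <= 0)) stop("R1 + Z0 must be positive")
  (R1 - Z0) / (R1 + Z0)
}

#' Reflective proximal resistance at the aortic outlet
#'
#' Chooses the descending-aorta `R1` so that linear wavefront theory
#' reproduces the inflection point observed on the decay of the carotid
#' pressure wave in the second half of systole. The drop from the systolic
#' pressure \eqn{p_S} to the inflection-point pressure \eqn{p_I} is
#' attributed to the wavefront reflected at the aortic outlet; relative to
#' an incident wavefront amplitude \eqn{p_S - P_\infty} this gives the
#' reflection coefficient estimate
#' \deqn{R_f = -\frac{p_S - p_I}{p_S - P_\infty}, \qquad
#'       R_1 = Z_0 \frac{1 + R_f}{1 - R_f}.}
#' A drooping inflection (\eqn{p_I < p_S}) therefore yields a negative
#' reflection coefficient and \eqn{R_1 < Z_0}.
#'
#' @param Z0 characteristic impedance at the aortic outlet, Pa s/m^3.
#' @param p_sys systolic pressure of the carotid waveform, Pa.
#' @param p_infl pressure at the systolic-decay inflection point, Pa.
#' @param decay a [fit_diastolic_decay()] result (supplies `P_inf`).
#' @return R1 in Pa s/m^3; the implied reflection coefficient lies in
#'   (-1, 1).
#' @export
reflective_aortic_R1 <- function(Z0, p_sys, p_infl, decay) {
  if (p_sys <= decay$P_inf)
    stop("systolic pressure must exceed the fitted asymptotic pressure")
  if (p_infl > p_sys)
    stop("inflection-point pressure above systolic pressure: ",
         "no systolic-decay inflection detected")
  Rf <- -(p_sys - p_infl) / (p_sys - decay$P_inf)
  if (Rf <= -1 || Rf >= 1)
    stop("implied reflection coefficient outside (-1, 1): ", signif(Rf, 3))
  Z0 * (1 + Rf) / (1 - Rf)
}

#' Carotid pressure waveform features
#'
#' Systolic, diastolic and cycle-mean pressures, plus the pressure at the
#' inflection point of the systolic decay. The inflection point is the
#' local maximum of the first derivative between the systolic peak and the
#' subsequent pressure minimum, after smoothing the derivative with a
#' moving average (discrete tonometry data are noisy).
#'
#' @param p pressure [waveform].
#' @param smooth moving-average width in samples for the derivative
#'   (default 5).
#' @return list with `p_sys`, `p_dias`, `p_mean`, `p_infl`, `t_infl`.
#' @export
carotid_features <- function(p, smooth = 5L) {
  pr <- waveform_resample(p, 512L)
  v <- pr$values; t <- pr$times; n <- length(v)
  d <- c(diff(v), v[1] - v[n]) / diff(c(t, t[1] + pr$period))
  if (smooth > 1L)
    d <- as.numeric(
      stats::filter(c(d, d, d), rep(1 / smooth, smooth))[(n + 1):(2 * n)])
  ipk <- which.max(v)
  ## search from just after the peak to the pre-upstroke minimum (cyclic)
  offs <- seq_len(n - 1L)
  idx_after <- ((ipk - 1L + offs) %% n) + 1L
  iend_off <- offs[which.min(v[idx_after])]
  if (iend_off < 9L) stop("no systolic decay to search for inflection")
  idx <- ((ipk - 1L + 2L:(iend_off - 2L)) %% n) + 1L
  dd <- d[idx]
  ## local maxima of the (negative) derivative along the decay
  loc <- which(diff(sign(diff(dd))) < 0) + 1L
  if (!length(loc))
    stop("no inflection point found on the systolic decay")
  i_infl <- idx[loc[1]]
  list(p_sys = max(v), p_dias = min(v), p_mean = waveform_mean(pr),
       p_infl = v[i_infl], t_infl = t[i_infl])
}

#' Periodic space-independent Windkessel pressure
#'
#' Periodic solution of the lumped balance of the whole network,
#' \deqn{C_T \frac{dP_w}{dt} = Q_{in}(t) - \frac{P_w - P_{out}}{R_T},}
#' computed in closed form with an integrating factor. This
#' space-independent pressure approximates pressure waves throughout the
#' domain and underlies the compliance estimators.
#'
#' @param inflow periodic inflow [waveform] (m^3/s).
#' @param RT total resistance, Pa s/m^3.
#' @param CT total compliance, m^3/Pa.
#' @param Pout outflow pressure, Pa.
#' @param n output grid size.
#' @return pressure [waveform] over one period.
#' @export
windkessel_pressure_0d <- function(inflow, RT, CT, Pout, n = 2048L) {
  tau <- RT * CT
  Tp <- inflow$period
  t <- inflow$times[1] + Tp * (0:n) / n
  q <- waveform_at(inflow, t)
  ## cumulative trapezoid of e^{s/tau} q(s) / CT
  g <- exp((t - t[1]) / tau) * q / CT
  cum <- c(0, cumsum(diff(t) * (g[-1] + g[-length(g)]) / 2))
  eT <- exp(-Tp / tau)
  u0 <- eT * cum[n + 1] / (1 - eT)
  u <- exp(-(t - t[1]) / tau) * (u0 + cum)
  waveform(t[1:n], Pout + u[1:n], "pressure", period = Tp)
}

#' One implicit step of a three-element Windkessel
#'
#' Advances the compliance-node pressure `Pc` by one backward-Euler step
#' under boundary flow `Q` and returns the boundary pressure
#' `P = Pc + Q R1`. This mirrors the outlet update used inside the 1D
#' solver and is exposed for verification.
#'
#' @param Q boundary flow, m^3/s.
#' @param wk a [windkessel_params].
#' @param dt time step, s.
#' @param Pc current compliance-node pressure, Pa.
#' @return list with `P` (boundary pressure) and `Pc` (updated state).
#' @export
windkessel_step <- function(Q, wk, dt, Pc) {
  stopifnot(dt > 0)
  a <- dt / (wk$R2 * wk$C)
  Pc_new <- (Pc + dt * Q / wk$C + a * wk$Pout) / (1 + a)
  list(P = Pc_new + Q * wk$R1, Pc = Pc_new)
}
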