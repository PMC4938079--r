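test_that("diastolic decay fit recovers exact exponentials", {
  Tp <- 1
  t <- Tp * (0:255) / 256
  Pinf <- to_si(40, "mmHg"); tau <- 1.5; P0 <- to_si(95, "mmHg")
  ## one systolic bump then a clean exponential decay from t = 0.3
  v <- ifelse(t < 0.3,
              P0 + to_si(25, "mmHg") * sin(pi * t / 0.3),
              Pinf + (P0 - Pinf) * exp(-(t - 0.3) / tau))
  w <- waveform(t, v, "pressure", period = Tp)
  fit <- fit_diastolic_decay(w, window = c(0.35, 0.97))
  expect_rel_equal(fit$P_inf, Pinf, 1e-4)
  expect_rel_equal(fit$tau, tau, 1e-4)
  ## log-linear regression oracle with the true asymptote
  tt <- seq(0.35, 0.97, length.out = 50)
  y <- log(waveform_at(w, tt) - Pinf)
  slope <- stats::coef(stats::lm(y ~ tt))[2]
  expect_rel_equal(fit$tau, -1 / slope, 1e-4)
  ## site-averaged (tau, P_inf): amplified copies about the asymptote
  ## (peripheral sites) share both parameters, so the average equals each
  fits <- lapply(c(1, 1.08, 1.15), function(f) {
    wf <- waveform(t, Pinf + (v - Pinf) * f, "pressure", period = Tp)
    fit_diastolic_decay(wf, window = c(0.35, 0.97))
  })
  expect_rel_equal(mean(vapply(fits, `[[`, numeric(1), "tau")), tau, 1e-4)
  expect_rel_equal(mean(vapply(fits, `[[`, numeric(1), "P_inf")), Pinf,
                   1e-4)
  expect_error(fit_diastolic_decay(
    waveform(t, rev(v), "pressure", period = Tp), window = c(0.35, 0.9)))
})

test_that("total resistance is the driving pressure over mean flow", {
  ## 100 mmHg mean, 20 mmHg outflow, 80 ml/s -> 1 mmHg s / ml
  RT <- total_resistance(to_si(100, "mmHg"), to_si(20, "mmHg"),
                         to_si(80, "ml/s"))
  expect_rel_equal(RT, to_si(1, "mmHg") / to_si(1, "ml/s"), 1e-12)
  ## zero outflow pressure reduces to P/Q; SI hand computation
  expect_equal(total_resistance(13332.2, 0, 8e-5), 13332.2 / 8e-5)
  expect_error(total_resistance(to_si(30, "mmHg"), to_si(33, "mmHg"), 1e-5))
})

test_that("terminal resistances conserve the parallel total", {
  g <- rep(0.25, 4)
  expect_equal(terminal_total_resistances(1e8, g), rep(4e8, 4))
  set.seed(7)
  for (i in 1:20) {
    g <- stats::runif(5); g <- g / sum(g)
    RTj <- terminal_total_resistances(1e8, g)
    expect_rel_equal(1 / sum(1 / RTj), 1e8, 1e-10)
  }
  ## two-terminal Ohmic oracle: branch mean flow = gamma * total
  g <- c(0.7, 0.3); RT <- 9e7; P <- to_si(60, "mmHg"); Q <- P / RT
  RTj <- terminal_total_resistances(RT, g)
  expect_rel_equal(P / RTj[1], 0.7 * Q, 1e-12)
  expect_rel_equal(P / RTj[2], 0.3 * Q, 1e-12)
  expect_error(terminal_total_resistances(1e8, c(0.5, 0.4)), "sum to 1")
})

test_that("conduit compliance matches quadrature and scales physically", {
  seg1 <- function(L, c = 5) data.frame(
    id = 1L, name = "v", length = L, r_in = 0.008, r_out = 0.008,
    c_in = c, c_out = c, parent = NA_integer_, terminal = TRUE)
  net <- network(seg1(0.1))
  ## uniform vessel: closed form 2 Ad^{3/2} L / beta
  Ad <- pi * 0.008^2
  beta <- beta_from_speed(5, Ad, net$fluid$rho)
  expect_rel_equal(conduit_compliance(net), 2 * Ad^1.5 * 0.1 / beta, 1e-8)
  ## linear in length; decreasing in stiffness
  expect_rel_equal(conduit_compliance(network(seg1(0.2))),
                   2 * conduit_compliance(net), 1e-8)
  expect_lt(conduit_compliance(network(seg1(0.1, c = 8))),
            conduit_compliance(net))
  ## tapered segment: independent Simpson-rule oracle
  segt <- data.frame(id = 1L, name = "t", length = 0.2, r_in = 0.012,
                     r_out = 0.008, c_in = 4.5, c_out = 5.5,
                     parent = NA_integer_, terminal = TRUE)
  nett <- network(segt)
  f <- function(x) {
    m <- pulsewave:::segment_material_at(nett, 1L, x)
    2 * m$Ad^1.5 / m$beta
  }
  xs <- seq(0, 1, length.out = 201)
  simpson <- sum((f(xs[-201]) + 4 * f((xs[-201] + xs[-1]) / 2) +
                    f(xs[-1])) / 6 * diff(xs)) * 0.2
  expect_rel_equal(conduit_compliance(nett), simpson, 1e-8)
})

test_that("total compliance estimators have the stated structure", {
  ## fitted mode: tau over net resistance
  expect_equal(total_compliance("fitted", RT = to_si(1.2, "mmHg") /
                                  to_si(1, "ml/s"), tau = 1.5),
               1.5 / (to_si(1.2, "mmHg") / to_si(1, "ml/s")))
  ## capillary mode: difference form is invariant to a constant inflow
  ## offset
  qin <- make_inflow(diastolic_level = 0)
  ps <- to_si(110, "mmHg"); pd <- to_si(70, "mmHg")
  ct1 <- total_compliance("capillary", inflow = qin, p_sys = ps,
                          p_dias = pd)
  qoff <- waveform(qin$times, qin$values + 2e-5, "flow",
                   period = qin$period)
  ct2 <- total_compliance("capillary", inflow = qoff, p_sys = ps,
                          p_dias = pd)
  expect_rel_equal(ct1, ct2, 1e-10)
  ## structural oracle: (Qmax - Qmin) * dt / pulse pressure, cyclic dt
  imax <- which.max(qin$values); imin <- which.min(qin$values)
  dtc <- abs(qin$times[imax] - qin$times[imin])
  dtc <- min(dtc, qin$period - dtc)
  expect_rel_equal(ct1, diff(range(qin$values)) * dtc / (ps - pd), 1e-12)
})

test_that("a two-element Windkessel analysed by the fitted mode recovers C", {
  R <- 1.1e8; C <- 1.4e-8; Pout <- to_si(33, "mmHg")
  qin <- make_inflow(diastolic_level = 0)
  pw <- windkessel_pressure_0d(qin, R, C, Pout)
  fit <- fit_diastolic_decay(pw)
  CT <- total_compliance("fitted", RT = R, tau = fit$tau)
  expect_rel_equal(CT, C, 0.02)
})

test_that("compliance distribution conserves and converts correctly", {
  g <- c(0.69, 0.14, 0.07, 0.10)
  Cp <- 9e-9
  RTj <- 1e8 / g
  ## R1 = 0 keeps the proportional split untouched
  d0 <- distribute_compliances(Cp, g, RTj, rep(0, 4))
  expect_equal(d0$C, d0$Cpj)
  expect_rel_equal(sum(d0$Cpj), Cp, 1e-12)
  ## symbolic evaluation of the split and the RCR conversion
  R1j <- 0.2 * RTj
  d <- distribute_compliances(Cp, g, RTj, R1j)
  expect_equal(d$Cpj, g * Cp, tolerance = 1e-14)
  expect_equal(d$C, g * Cp * (RTj / (RTj - R1j))^2, tolerance = 1e-14)
  expect_error(distribute_compliances(Cp, g, RTj, RTj * 1.01), "exceeds")
  expect_error(distribute_compliances(-1e-9, g, RTj, R1j))
})

test_that("characteristic impedance and reflection coefficient behave", {
  Ad <- pi * 0.0075^2
  Z0 <- characteristic_impedance(5.84, Ad, 1060)
  ## arithmetic oracle at the descending-aorta end point
  expect_rel_equal(Z0, 1060 * 5.84 / (pi * 0.0075^2), 1e-12)
  expect_rel_equal(characteristic_impedance(5.84, 2 * Ad, 1060), Z0 / 2,
                   1e-12)
  expect_equal(reflection_coefficient(Z0, Z0), 0)
  expect_equal(reflection_coefficient(0, Z0), -1)
  expect_equal(reflection_coefficient(3 * Z0, Z0), 0.5)
})

test_that("the reflective aortic R1 has the matched limit and sign", {
  Z0 <- 1e7
  decay <- list(P_inf = to_si(33, "mmHg"), tau = 1.4)
  ps <- to_si(110, "mmHg")
  ## inflection equal to the systolic peak -> matched terminal
  expect_equal(reflective_aortic_R1(Z0, ps, ps, decay), Z0)
  ## a drooping inflection gives R1 < Z0 and a negative reflection
  ## coefficient
  r1 <- reflective_aortic_R1(Z0, ps, to_si(100, "mmHg"), decay)
  expect_lt(r1, Z0)
  expect_lt(reflection_coefficient(r1, Z0), 0)
  ## algebra oracle on random admissible inputs
  set.seed(11)
  for (i in 1:25) {
    pi_ <- stats::runif(1, to_si(80, "mmHg"), ps)
    rf <- -(ps - pi_) / (ps - decay$P_inf)
    expect_rel_equal(reflective_aortic_R1(Z0, ps, pi_, decay),
                     Z0 * (1 + rf) / (1 - rf), 1e-12)
  }
  expect_error(reflective_aortic_R1(Z0, ps, ps * 1.1, decay), "inflection")
})

test_that("the space-independent Windkessel pressure solves the lumped ODE", {
  RT <- 1.1e8; CT <- 1.4e-8; Pout <- to_si(33, "mmHg")
  ## constant inflow: steady state everywhere
  Tp <- 1
  qconst <- waveform(Tp * (0:63) / 64, rep(9e-5, 64), "flow", period = Tp)
  pw <- windkessel_pressure_0d(qconst, RT, CT, Pout)
  expect_lt(max(abs(pw$values - (Pout + 9e-5 * RT))), 1e-6 * Pout)
  ## cycle-averaged balance for a pulsatile inflow
  qin <- make_inflow()
  pw2 <- windkessel_pressure_0d(qin, RT, CT, Pout)
  expect_rel_equal(waveform_mean(pw2),
                   Pout + waveform_mean(qin) * RT, 1e-6)
  ## fine-step explicit integrator oracle, run to the periodic state
  dt <- qin$period / 2e4
  tt <- seq(0, 30 * qin$period, by = dt)
  q <- waveform_at(qin, tt)
  P <- numeric(length(tt)); P[1] <- Pout
  for (i in seq_len(length(tt) - 1))
    P[i + 1] <- P[i] + dt * (q[i] / CT - (P[i] - Pout) / (RT * CT))
  last <- tt > 29 * qin$period
  ref <- stats::approx(tt[last] - 29 * qin$period, P[last],
                       xout = pw2$times %% qin$period, rule = 2)$y
  rms <- sqrt(mean((pw2$values - ref)^2)) / mean(ref)
  expect_lt(rms, 1e-3)
})

test_that("a single Windkessel step is the implicit update of the RC node", {
  wkp <- windkessel_params(R1 = 1e7, R2 = 1.2e8, C = 1e-8,
                           Pout = to_si(33, "mmHg"))
  ## constant flow forever approaches Pout + Q (R1 + R2)
  Pc <- wkp$Pout; Q <- 8e-5
  for (i in 1:20000) {
    st <- windkessel_step(Q, wkp, 1e-3, Pc)
    Pc <- st$Pc
  }
  expect_rel_equal(st$P, wkp$Pout + Q * (wkp$R1 + wkp$R2), 1e-6)
  ## zero flow: exponential discharge with time constant R2 C
  Pc <- wkp$Pout + to_si(40, "mmHg")
  dt <- 1e-4
  n <- round(wkp$R2 * wkp$C / dt)     # integrate exactly one tau
  for (i in 1:n) Pc <- windkessel_step(0, wkp, dt, Pc)$Pc
  expect_rel_equal(Pc - wkp$Pout, to_si(40, "mmHg") * exp(-1), 1e-3)
})
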