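## bipolar (zero-net-volume) wavefront used for linear wave checks
bipolar_pulse <- function(Qp = 1e-5, t0 = 0.06, w = 0.012, Tp = 2,
                          n = 4096) {
  t <- Tp * (0:(n - 1)) / n
  x <- (t - t0) / w
  waveform(t, Qp * (-2 * x) * exp(-x^2), "flow", period = Tp)
}

ptp_in <- function(tv, v, a, b) diff(range(v[tv >= a & tv < b]))

test_that("steady inviscid flow gives a uniform pressure set by the outlet", {
  net <- pw_single_segment(mu = 0)
  Tp <- 1
  qin <- waveform(Tp * (0:63) / 64, rep(9e-5, 64), "flow", period = Tp)
  R <- 9e7
  wk <- list(`1` = windkessel_params(R1 = 0, R2 = R, C = 1e-10,
                                     Pout = to_si(30, "mmHg")))
  sim <- run_simulation(net, qin, wk,
                        solver_config(min_cycles = 4, max_cycles = 8,
                                      tol_periodicity = 1e-6,
                                      monitor = "out"))
  Pexp <- to_si(30, "mmHg") + 9e-5 * R
  for (s in c("in", "mid", "out"))
    expect_rel_equal(mean(sim$P[[s]]$values), Pexp, 1e-4)
  expect_rel_equal(waveform_mean(sim$Q$out), 9e-5, 1e-4)
})

test_that("steady viscous flow reproduces the polynomial-profile friction
          law", {
  mu <- 4e-3; zeta <- 9
  L <- 0.2; r <- 0.004
  segs <- data.frame(id = 1L, name = "v", length = L, r_in = r, r_out = r,
                     c_in = 6, c_out = 6, parent = NA_integer_,
                     terminal = TRUE)
  net <- network(segs, fluid_properties(mu = mu, zeta = zeta),
                 Pd = to_si(75, "mmHg"),
                 planes = data.frame(site = c("in", "mid", "out"),
                                     segment = 1L, frac = c(0, 0.5, 1)))
  Tp <- 1; Q <- 1e-5
  qin <- waveform(Tp * (0:63) / 64, rep(Q, 64), "flow", period = Tp)
  wk <- list(`1` = windkessel_params(R1 = 0, R2 = 9e7, C = 1e-10,
                                     Pout = to_si(30, "mmHg")))
  sim <- run_simulation(net, qin, wk,
                        solver_config(min_cycles = 4, max_cycles = 8,
                                      tol_periodicity = 1e-7,
                                      monitor = "out"))
  drop <- mean(sim$P$`in`$values) - mean(sim$P$out$values)
  ## Poiseuille-type law at the working (distended) cross-section
  A <- mean(sim$A$mid$values)
  drop_th <- 2 * (zeta + 2) * pi * mu * Q * L / A^2
  expect_rel_equal(drop, drop_th, 0.01)
})

test_that("a short stiff segment with a Windkessel matches the lumped ODE", {
  ## transit time ~1.3 ms << cycle: the 1D segment degenerates to a wire
  segs <- data.frame(id = 1L, name = "v", length = 0.02, r_in = 0.008,
                     r_out = 0.008, c_in = 15, c_out = 15,
                     parent = NA_integer_, terminal = TRUE)
  net <- network(segs, fluid_properties(mu = 0), Pd = to_si(75, "mmHg"),
                 planes = data.frame(site = "out", segment = 1L, frac = 1))
  qin <- make_inflow()
  wkp <- windkessel_params(R1 = 8e6, R2 = 1.1e8, C = 1.2e-8,
                           Pout = to_si(33, "mmHg"))
  sim <- run_simulation(net, qin, list(`1` = wkp),
                        solver_config(min_cycles = 10, max_cycles = 30,
                                      tol_periodicity = 1e-5,
                                      monitor = "out"))
  p <- sim$P$out
  ## analytic periodic solution: compliance-node pressure from the linear
  ## RC balance, plus the R1 drop
  pc <- windkessel_pressure_0d(qin, wkp$R2, wkp$C, wkp$Pout)
  ref <- waveform_at(pc, p$times) + waveform_at(qin, p$times) * wkp$R1
  rms <- sqrt(mean((p$values - ref)^2)) / mean(ref)
  expect_lt(rms, 0.02)
})

test_that("junctions split symmetric children evenly and conserve mass", {
  segs <- data.frame(id = 1:3, name = c("p", "c1", "c2"), length = 0.1,
                     r_in = c(0.012, 0.009, 0.009),
                     r_out = c(0.012, 0.009, 0.009),
                     c_in = 5, c_out = 5, parent = c(NA, 1L, 1L),
                     terminal = c(FALSE, TRUE, TRUE))
  net <- network(segs, fluid_properties(mu = 0), Pd = to_si(75, "mmHg"),
                 planes = data.frame(site = c("c1", "c2"),
                                     segment = c(2L, 3L), frac = 0.5))
  wk1 <- windkessel_params(R1 = 1e7, R2 = 2.4e8, C = 5e-9,
                           Pout = to_si(33, "mmHg"))
  sim <- run_simulation(net, make_inflow(), list(`2` = wk1, `3` = wk1),
                        solver_config(min_cycles = 6, max_cycles = 16,
                                      tol_periodicity = 1e-4,
                                      monitor = "c1"))
  expect_equal(sim$Q$c1$values, sim$Q$c2$values, tolerance = 1e-10)
  expect_equal(sim$P$c1$values, sim$P$c2$values, tolerance = 1e-10)
  ## junction mass residual relative to peak inflow
  expect_lt(sim$max_junction_residual, 1e-10)
})

test_that("wavefront reflection and transmission at an area step match
          linear theory", {
  rho <- 1060
  segs <- data.frame(id = 1:2, name = c("a", "b"), length = c(0.6, 0.6),
                     r_in = c(0.010, 0.007), r_out = c(0.010, 0.007),
                     c_in = 5, c_out = 5, parent = c(NA, 1L),
                     terminal = c(FALSE, TRUE))
  A1 <- pi * 0.01^2; A2 <- pi * 0.007^2
  net <- network(segs, fluid_properties(rho = rho, mu = 0),
                 Pd = to_si(75, "mmHg"),
                 planes = data.frame(site = c("p1", "p2"),
                                     segment = c(1L, 2L), frac = 0.5))
  ## matched absorber at the far end; slow compliance node
  wk <- list(`2` = windkessel_params(R1 = rho * 5 / A2, R2 = 1e12,
                                     C = 1e-7, Pout = to_si(75, "mmHg")))
  sim <- run_simulation(net, bipolar_pulse(), wk,
                        solver_config(dx = 1.25e-3, min_cycles = 4,
                                      max_cycles = 4,
                                      tol_periodicity = 1e-9,
                                      monitor = "p1", n_out = 4096))
  p1 <- sim$P$p1; tv <- p1$times - p1$times[1]
  inc <- ptp_in(tv, p1$values, 0, 0.18)
  ref <- ptp_in(tv, p1$values, 0.19, 0.36)
  Y1 <- A1 / (rho * 5); Y2 <- A2 / (rho * 5)
  expect_lt(abs(ref / inc - (Y1 - Y2) / (Y1 + Y2)), 0.02)
  p2 <- sim$P$p2; tv2 <- p2$times - p2$times[1]
  trans <- ptp_in(tv2, p2$values, 0, 0.36)
  expect_lt(abs(trans / inc - 2 * Y1 / (Y1 + Y2)), 0.02)
})

test_that("a matched outlet minimizes the re-reflected wave", {
  rho <- 1060
  seg1 <- data.frame(id = 1L, name = "v", length = 0.6, r_in = 0.009,
                     r_out = 0.009, c_in = 5, c_out = 5,
                     parent = NA_integer_, terminal = TRUE)
  Z0 <- rho * 5 / (pi * 0.009^2)
  refl <- vapply(c(0.5, 1, 2), function(f) {
    net <- network(seg1, fluid_properties(rho = rho, mu = 0),
                   Pd = to_si(75, "mmHg"),
                   planes = data.frame(site = "p", segment = 1L,
                                       frac = 0.5))
    wk <- list(`1` = windkessel_params(R1 = f * Z0, R2 = 1e12, C = 1e-7,
                                       Pout = to_si(75, "mmHg")))
    sim <- run_simulation(net, bipolar_pulse(), wk,
                          solver_config(dx = 1.25e-3, min_cycles = 4,
                                        max_cycles = 4,
                                        tol_periodicity = 1e-9,
                                        monitor = "p", n_out = 4096))
    tv <- sim$P$p$times - sim$P$p$times[1]
    ptp_in(tv, sim$P$p$values, 0.16, 0.31) /
      ptp_in(tv, sim$P$p$values, 0, 0.15)
  }, numeric(1))
  ## R1 = Z0 (middle entry) reflects least, and both mismatched outlets
  ## agree with |R1 - Z0| / (R1 + Z0)
  expect_lt(refl[2], 0.01)
  expect_lt(refl[2], min(refl[c(1, 3)]))
  expect_lt(abs(refl[1] - 1 / 3), 0.02)
  expect_lt(abs(refl[3] - 1 / 3), 0.02)
})

test_that("relative error metrics follow their definitions", {
  t <- (0:127) / 128
  meas <- waveform(t, to_si(80 + 20 * sin(2 * pi * t) +
                              5 * sin(4 * pi * t + 1), "mmHg"),
                   "pressure", period = 1)
  expect_equal(unname(compute_relative_errors(meas, meas)),
               rep(0, 4), tolerance = 1e-12)
  ## uniform 10% scaling: sys and dias errors are exactly 10%
  sim <- waveform(t, 1.1 * meas$values, "pressure", period = 1)
  e <- compute_relative_errors(sim, meas, align = FALSE)
  expect_equal(unname(e[c("sys", "dias")]), c(0.1, 0.1), tolerance = 1e-9)
  ## direct per-sample oracle (no alignment)
  n <- 256
  tt <- (0:(n - 1)) / n
  vm <- waveform_at(meas, tt); vs <- waveform_at(sim, tt)
  expect_rel_equal(e[["avg"]], mean(abs(vs - vm)) / mean(vm), 1e-9)
  expect_rel_equal(e[["max"]], max(abs(vs - vm)) / mean(vm), 1e-9)
  ## flow normalizer is the measured peak-to-peak amplitude
  qm <- waveform(t, 1e-4 * sin(2 * pi * t)^2, "flow", period = 1)
  qs <- waveform(t, qm$values + 1e-5, "flow", period = 1)
  ef <- compute_relative_errors(qs, qm, align = FALSE)
  expect_rel_equal(ef[["avg"]], 1e-5 / diff(range(waveform_at(qm, tt))),
                   1e-6)
  ## period mismatch beyond tolerance is an error
  expect_error(compute_relative_errors(
    waveform(t * 1.1, meas$values, "pressure", period = 1.1), meas),
    "period mismatch")
})

test_that("a CFL-violating time step fails with a diagnostic", {
  net <- pw_single_segment(mu = 0)
  qin <- make_inflow()
  wk <- list(`1` = windkessel_params(R1 = 1e7, R2 = 1e8, C = 1e-8,
                                     Pout = to_si(33, "mmHg")))
  expect_error(run_simulation(net, qin, wk,
                              solver_config(dt = 0.01, min_cycles = 4,
                                            max_cycles = 4,
                                            monitor = "out")),
               "CFL")
})
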