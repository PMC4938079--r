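## Shared fixtures. The 1D simulations are the expensive part, so every
## object derived from one is built lazily and cached for the whole run.

.pw_cache <- new.env(parent = emptyenv())

pw_cached <- function(name, expr) {
  if (!exists(name, envir = .pw_cache)) {
    assign(name, force(expr), envir = .pw_cache)
  }
  get(name, envir = .pw_cache)
}

pw_gamma <- c(`20` = 0.69, `22` = 0.14, `24` = 0.07, `26` = 0.10)

pw_cfg <- function(...) {
  solver_config(min_cycles = 8, max_cycles = 24, tol_periodicity = 3e-4,
                monitor = "Carotid", ...)
}

## synthetic subject whose diastolic reference pressure is self-consistent
## with its own carotid waveform (one fixed-point pass), matched outlets
pw_subject_matched <- function() pw_cached("subject_matched", {
  qin <- make_inflow()
  Pd <- to_si(75, "mmHg")
  net <- make_upper_aorta_network("foot_to_foot", Pd = Pd)
  wk <- make_reference_windkessel(net, qin, pw_gamma, aortic_rf = 0)
  sim <- run_simulation(net, qin, wk, pw_cfg())
  Pd <- min(sim$P$Carotid$values)
  net <- make_upper_aorta_network("foot_to_foot", Pd = Pd)
  wk <- make_reference_windkessel(net, qin, pw_gamma, aortic_rf = 0)
  ms <- generate_self_consistent_dataset(net, wk, qin, pw_cfg())
  list(net = net, wk = wk, inflow = qin, ms = ms,
       sim = attr(ms, "simulation"))
})

## same subject with a mildly reflective descending aorta (the reference
## configuration for the in-vivo-like session)
pw_subject_reflective <- function() pw_cached("subject_reflective", {
  qin <- make_inflow()
  net <- make_upper_aorta_network("foot_to_foot", Pd = to_si(75, "mmHg"))
  wk <- make_reference_windkessel(net, qin, pw_gamma, aortic_rf = -0.15)
  ms <- generate_self_consistent_dataset(net, wk, qin, pw_cfg())
  list(net = net, wk = wk, inflow = qin, ms = ms,
       sim = attr(ms, "simulation"))
})

## emulated measurement session (40 phases, modality heart rates)
pw_session <- function() pw_cached("session", {
  s <- pw_subject_reflective()
  synthetic_session(s$net, s$wk, s$inflow, pw_cfg(), phases = 40L)
})

pw_scenario_report <- function(preset) pw_cached(paste0("report_", preset), {
  run_scenario(pw_session(), make_upper_aorta_network("foot_to_foot"), preset,
               solver_config(min_cycles = 6, max_cycles = 16,
                             tol_periodicity = 1e-3, monitor = "Carotid"))
})

## uniform single-segment network builder for solver unit tests
pw_single_segment <- function(length = 0.1, r = 0.01, c = 5, mu = 0,
                              Pd = to_si(75, "mmHg"),
                              planes = data.frame(site = c("in", "mid",
                                                           "out"),
                                                  segment = 1L,
                                                  frac = c(0, 0.5, 1))) {
  segs <- data.frame(id = 1L, name = "vessel", length = length,
                     r_in = r, r_out = r, c_in = c, c_out = c,
                     parent = NA_integer_, terminal = TRUE)
  network(segs, fluid_properties(mu = mu), Pd = Pd, planes = planes)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

## closed-loop recovery: calibrate + refine against data generated with
## known parameters (matched outlets, capillary-mode premise)
pw_recovery <- function() pw_cached("recovery", {
  s <- pw_subject_matched()
  g <- compute_flow_fractions(s$ms)
  sc <- scenario_config("capillary_constant", "uniform_foot_to_foot",
                        "all_matched", TRUE)
  cal <- calibrate_windkessel(make_upper_aorta_network("foot_to_foot"),
                              s$inflow, s$ms$pressures, g, sc)
  ref <- refine_windkessel(cal$net, cal$wk, s$inflow,
                           s$ms$pressures$Carotid, cfg = pw_cfg(),
                           max_iters = 8, tol = 2e-3)
  list(gamma = g, cal = cal, ref = ref, truth = s$wk)
})

## refinement from a deliberately perturbed compliance, against the
## model's own carotid pressure
pw_refine_perturbed <- function() pw_cached("refine_perturbed", {
  s <- pw_subject_matched()
  wkp <- s$wk
  for (id in names(wkp)) wkp[[id]]$C <- wkp[[id]]$C * 1.35
  refine_windkessel(s$net, wkp, s$inflow, s$sim$P$Carotid,
                    cfg = pw_cfg(), max_iters = 4, tol = 1e-4)
})

## prominence (mmHg) of the largest diastolic local maximum of a pressure
## wave: the height of the peak above the higher of its flanking minima
pw_diastolic_peak <- function(p) {
  pr <- waveform_resample(p, 512L)
  v <- pr$values; n <- length(v)
  ipk <- which.max(v)
  idx <- ((ipk - 1L + seq(round(0.25 * n), n - 15L)) %% n) + 1L
  vv <- v[idx]
  loc <- which(diff(sign(diff(vv))) < 0) + 1L
  if (!length(loc)) return(0)
  best <- 0
  for (l in loc) {
    left <- min(vv[1:l]); right <- min(vv[l:length(vv)])
    best <- max(best, vv[l] - max(left, right))
  }
  from_si(best, "mmHg")
}

## modelling-assumption comparisons on a session whose inflow carries the
## end-systolic valve-closure dip (needed for dicrotic features)
pw_assumption_study <- function() pw_cached("assumption_study", {
  qin <- make_inflow(dip = 0.08)
  net <- make_upper_aorta_network("foot_to_foot", Pd = to_si(75, "mmHg"))
  wk <- make_reference_windkessel(net, qin, pw_gamma, aortic_rf = -0.15)
  ms <- synthetic_session(net, wk, qin, pw_cfg(), phases = 40L)
  cfgs <- solver_config(min_cycles = 6, max_cycles = 16,
                        tol_periodicity = 1e-3, monitor = "Carotid")
  list(
    ms = ms,
    reflective = run_scenario(ms, make_upper_aorta_network("foot_to_foot"),
                              best_pressure(), cfgs),
    matched = run_scenario(ms, make_upper_aorta_network("foot_to_foot"),
                           scenario_config("fitted_asymptote",
                                           "uniform_foot_to_foot",
                                           "all_matched", TRUE), cfgs),
    uniform_c = run_scenario(ms, make_upper_aorta_network("foot_to_foot"),
                             best_area(), cfgs, refine_iters = 1),
    distributed_c = run_scenario(ms, make_upper_aorta_network("foot_to_foot"),
                                 scenario_config("capillary_constant",
                                                 "distributed_qa_loop",
                                                 "reflective_aorta", TRUE),
                                 cfgs, refine_iters = 1)
  )
})
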