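#' Run the full personalisation and simulation pipeline
#'
#' Executes the complete workflow on a measurement set:
#' 1. reconcile — harmonize heart rates, rescale the network geometry to
#'    the measured diastolic areas, compute terminal flow fractions;
#' 2. pulse wave velocity — foot-to-foot between the ascending and most
#'    distal descending flow waves (uniform mapping) or QA-loop at every
#'    aortic plane with a speed-diameter power-law fit (distributed
#'    mapping), per the scenario;
#' 3. calibrate — all Windkessel outlet parameters;
#' 4. refine — iterative rescaling of distal resistances and compliances
#'    against the measured carotid systolic/diastolic pressures (only in
#'    the capillary outflow-pressure mode, whose compliance estimator is
#'    approximate);
#' 5. simulate and score — run the 1D/0D model to a periodic state and
#'    compute relative error metrics against every measured waveform.
#'
#' @param ms a [measurement_set] (flows and areas at the aortic planes,
#'   pressures led by the carotid site).
#' @param net the uncalibrated [network] (geometry and plane map).
#' @param scenario a [scenario_config] or preset name `"best-area"` /
#'   `"best-pressure"`.
#' @param cfg a [solver_config].
#' @param capillary_pressure assumed capillary pressure, Pa.
#' @param refine_iters refinement iterations in capillary mode.
#' @param rescale_areas rescale the geometry to measured diastolic areas
#'   (default TRUE).
#' @return a list report: `scenario`, `heart_rate`, `gamma`, `pwv`
#'   (estimation details), `calibration` (state), `wk`, `refinement` log,
#'   `simulation`, and `errors` (data.frame of avg/max/sys/dias relative
#'   errors per site and quantity).
#' @export
run_scenario <- function(ms, net, scenario = "best-area",
                         cfg = solver_config(),
                         capillary_pressure = 33 * MMHG_PA,
                         refine_iters = 2L, rescale_areas = TRUE) {
  if (is.character(scenario))
    scenario <- switch(scenario,
                       "best-area" = best_area(),
                       "best-pressure" = best_pressure(),
                       stop("unknown scenario preset: ", scenario))
  if (!scenario$viscous) net$fluid$mu <- 0

  ## 1. reconcile
  h <- harmonize_heart_rate(ms)
  msh <- h$set
  if (rescale_areas && length(msh$areas)) {
    Ad_meas <- vapply(msh$areas, waveform_min, numeric(1))
    net <- rescale_geometry(net, Ad_meas)
  }
  gamma <- compute_flow_fractions(msh)

  ## 2. pulse wave velocity -- estimated from the waves as measured
  ## (harmonization retimes the model inputs, but the transit times and
  ## early-systolic loops of the original recordings carry the speed
  ## information undistorted)
  asc <- msh$flows[["Asc Ao"]]
  desc_names <- grep("^Desc", names(msh$flows), value = TRUE)
  distal <- desc_names[length(desc_names)]
  if (scenario$pwv_mode == "uniform_foot_to_foot") {
    path <- plane_distance(net, "Asc Ao", distal)
    c_ff <- foot_to_foot_speed(ms$flows[["Asc Ao"]], ms$flows[[distal]],
                               path)
    net <- assign_wave_speeds(net, "uniform", speed = c_ff)
    pwv <- list(mode = "uniform_foot_to_foot", speed = c_ff, path = path)
  } else {
    sites <- intersect(names(ms$flows), names(ms$areas))
    d <- cd <- numeric(0)
    for (s in sites) {
      a <- waveform_set_period(ms$areas[[s]], ms$flows[[s]]$period)
      est <- qa_loop_speed(ms$flows[[s]], a)
      d <- c(d, 2 * sqrt(waveform_min(ms$areas[[s]]) / pi))
      cd <- c(cd, est$speed)
    }
    fit <- fit_speed_diameter_power_law(d, cd)
    net <- assign_wave_speeds(net, "distributed", fit = fit)
    pwv <- list(mode = "distributed_qa_loop", fit = fit,
                pairs = data.frame(site = sites, d = d, c_d = cd))
  }

  ## 3. calibrate
  cal <- calibrate_windkessel(net, asc, msh$pressures, gamma, scenario,
                              capillary_pressure = capillary_pressure)
  net <- cal$net
  wk <- cal$wk

  ## 4. refine (capillary mode only; fitted mode is already consistent)
  refinement <- NULL
  sim <- NULL
  carotid <- msh$pressures[[1]]
  if (scenario$pout_mode == "capillary_constant" && refine_iters > 0) {
    ref <- refine_windkessel(net, wk, asc, carotid, cfg = cfg,
                             max_iters = refine_iters)
    wk <- ref$wk
    refinement <- ref$log
    sim <- ref$simulation
  }

  ## 5. simulate and score
  if (is.null(sim)) sim <- run_simulation(net, asc, wk, cfg)
  errors <- NULL
  score <- function(simw, measw, site, quantity) {
    e <- compute_relative_errors(simw, measw)
    data.frame(site = site, quantity = quantity, avg = e[["avg"]],
               max = e[["max"]], sys = e[["sys"]], dias = e[["dias"]])
  }
  for (s in names(msh$flows))
    if (s %in% names(sim$Q))
      errors <- rbind(errors, score(sim$Q[[s]], msh$flows[[s]], s, "flow"))
  for (s in names(msh$areas))
    if (s %in% names(sim$A))
      errors <- rbind(errors, score(sim$A[[s]], msh$areas[[s]], s, "area"))
  if ("Carotid" %in% names(sim$P))
    errors <- rbind(errors,
                    score(sim$P[["Carotid"]], carotid, "Carotid",
                          "pressure"))
  list(scenario = scenario, heart_rate = h$heart_rate, gamma = gamma,
       pwv = pwv, calibration = cal$state, wk = wk,
       refinement = refinement, simulation = sim, errors = errors,
       net = net)
}
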