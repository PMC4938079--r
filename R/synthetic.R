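#' Geometry and pulse wave velocities of the upper-aorta model
#'
#' The 26-segment segment table of the subject-specific upper-aorta
#' network: lengths, diastolic inlet/outlet radii and the diastolic wave
#' speeds obtained by the two estimation methods (a uniform foot-to-foot
#' value and diameter-dependent QA-loop values). The aortic chain is
#' segments 1-20; the brachiocephalic (21-22), left common carotid (23-24)
#' and left subclavian (25-26) arteries leave the arch at the junctions
#' separating the short arch segments 4|5, 5|6 and 6|7. Terminal segments
#' are 20, 22, 24 and 26.
#'
#' @return data.frame with columns `id`, `name`, `length_cm`, `r_in_mm`,
#'   `r_out_mm`, `cff_in_ms`, `cff_out_ms` (foot-to-foot), `cqa_in_ms`,
#'   `cqa_out_ms` (QA-loop), `parent`, `terminal`.
#' @export
upper_aorta_segments <- function() {
  tab <- data.frame(
    id = 1:26,
    name = c(paste0("aorta ", c("I", "II", "III", "IV", "V", "VI", "VII",
                                "VIII", "IX", "X", "XI", "XII", "XIII",
                                "XIV", "XV", "XVI", "XVII", "XVIII", "XIX",
                                "XX")),
             "brachiocephalic I", "brachiocephalic II",
             "left carotid I", "left carotid II",
             "left subclavian I", "left subclavian II"),
    length_cm = c(1.94, 2.06, 2.00, 0.58, 0.57, 0.85, 0.48, 1.52, 2.06,
                  1.94, 2.00, 1.97, 2.03, 2.00, 2.00, 1.10, 2.90, 2.41,
                  1.59, 1.56, 2.00, 2.20, 2.00, 1.23, 2.00, 1.31),
    r_in_mm = c(12.4, 13.2, 13.2, 12.8, 12.3, 11.8, 11.1, 10.9, 10.7,
                10.6, 10.0, 9.3, 9.1, 8.8, 8.6, 8.5, 8.3, 7.8, 7.5, 7.5,
                7.0, 4.5, 5.1, 3.1, 5.3, 3.5),
    r_out_mm = c(13.2, 13.2, 12.8, 12.3, 11.8, 11.1, 10.9, 10.7, 10.6,
                 10.0, 9.3, 9.1, 8.8, 8.6, 8.5, 8.3, 7.8, 7.5, 7.5, 7.5,
                 4.5, 4.3, 3.1, 2.9, 3.5, 3.4),
    cff_in_ms = rep(4.56, 26),
    cff_out_ms = rep(4.56, 26),
    cqa_in_ms = c(4.56, 4.42, 4.42, 4.49, 4.56, 4.66, 4.81, 4.86, 4.91,
                  4.93, 5.08, 5.27, 5.31, 5.41, 5.46, 5.50, 5.57, 5.76,
                  5.87, 5.85, 6.06, 7.54, 7.10, 9.18, 6.97, 8.64),
    cqa_out_ms = c(4.42, 4.42, 4.49, 4.56, 4.66, 4.81, 4.86, 4.91, 4.93,
                   5.08, 5.27, 5.31, 5.41, 5.46, 5.50, 5.57, 5.76, 5.87,
                   5.85, 5.84, 7.54, 7.77, 9.18, 9.43, 8.64, 8.67),
    parent = c(NA, 1:3, 4, 5, 6, 7:19, 4, 21, 5, 23, 6, 25),
    terminal = FALSE
  )
  tab$terminal[c(20, 22, 24, 26)] <- TRUE
  tab
}

#' Default measurement-plane map of the upper-aorta model
#'
#' Five aortic planes (ascending aorta plus four descending sites) and the
#' carotid outlet, located by segment id and axial fraction.
#'
#' @return data.frame with columns `site`, `segment`, `frac`.
#' @export
upper_aorta_planes <- function() {
  data.frame(
    site = c("Asc Ao", "Desc Ao 1", "Desc Ao 2", "Desc Ao 3", "Desc Ao 4",
             "Carotid"),
    segment = c(1L, 9L, 12L, 16L, 20L, 24L),
    frac = c(0, 1, 1, 1, 1, 1)
  )
}

#' Build the 26-segment upper-aorta network
#'
#' @param speeds which wave-speed column to install: `"foot_to_foot"`
#'   (uniform) or `"qa_loop"` (diameter-dependent).
#' @param fluid a [fluid_properties].
#' @param Pd diastolic reference pressure, Pa.
#' @return a [network] with the plane map of [upper_aorta_planes()].
#' @export
make_upper_aorta_network <- function(speeds = c("foot_to_foot", "qa_loop"),
                                fluid = fluid_properties(),
                                Pd = 80 * MMHG_PA) {
  speeds <- match.arg(speeds)
  tab <- upper_aorta_segments()
  segs <- data.frame(
    id = tab$id, name = tab$name,
    length = tab$length_cm * 1e-2,
    r_in = tab$r_in_mm * 1e-3, r_out = tab$r_out_mm * 1e-3,
    c_in = if (speeds == "foot_to_foot") tab$cff_in_ms else tab$cqa_in_ms,
    c_out = if (speeds == "foot_to_foot") tab$cff_out_ms else tab$cqa_out_ms,
    parent = tab$parent, terminal = tab$terminal
  )
  network(segs, fluid = fluid, Pd = Pd, planes = upper_aorta_planes())
}

#' Synthetic aortic-root inflow waveform
#'
#' Smooth periodic flow emulating a PC-MRI ascending-aorta measurement: a
#' skewed systolic ejection pulse, an optional end-systolic backflow dip
#' and a small decaying diastolic flow. The waveform is normalized so its
#' cycle integral equals the stroke volume exactly (trapezoidal rule with
#' periodic closure).
#'
#' @param heart_rate bpm (default 61.2, the reconciled study average).
#' @param stroke_volume_ml stroke volume, ml (default 85).
#' @param systolic_fraction ejection duration as a fraction of the cycle
#'   (default 0.33).
#' @param skew exponential skew of the ejection pulse (larger = earlier
#'   peak; default 0.7).
#' @param diastolic_level diastolic flow as a fraction of the peak
#'   (default 0.01; 0 gives strictly zero diastolic flow).
#' @param dip end-systolic backflow amplitude as a fraction of the peak
#'   (default 0, keeping the waveform non-negative).
#' @param n samples per cycle.
#' @return a flow [waveform] (m^3/s).
#' @export
make_inflow <- function(heart_rate = 61.2, stroke_volume_ml = 85,
                        systolic_fraction = 0.33, skew = 0.7,
                        diastolic_level = 0.01, dip = 0, n = 256L) {
  stopifnot(heart_rate > 0, stroke_volume_ml > 0,
            systolic_fraction > 0, systolic_fraction < 0.6)
  Tp <- 60 / heart_rate
  x <- (seq_len(n) - 1) / n               # cycle phase in [0, 1)
  xs <- systolic_fraction
  q <- numeric(n)
  sys <- x < xs
  q[sys] <- sin(pi * x[sys] / xs) * exp(-skew * x[sys] / xs)
  if (dip > 0) {
    wd <- 0.08
    din <- x >= xs & x < xs + wd
    q[din] <- -dip * sin(pi * (x[din] - xs) / wd)
  }
  dia <- x >= xs + if (dip > 0) 0.08 else 0
  if (diastolic_level > 0)
    q[dia] <- q[dia] + diastolic_level * exp(-5 * (x[dia] - xs))
  w <- waveform(Tp * x, q, "flow", period = Tp)
  scale <- (stroke_volume_ml * 1e-6) / (waveform_mean(w) * Tp)
  waveform(Tp * x, q * scale, "flow", period = Tp)
}

#' A set of multi-modal haemodynamic measurements
#'
#' Container for the waveforms a personalisation workflow consumes: flow
#' and area waveforms at named aortic planes and pressure waveforms at
#' named sites, plus prior flow-fraction weights for the supra-aortic
#' branches.
#'
#' @param flows named list of flow [waveform]s (plane names).
#' @param areas named list of area [waveform]s (plane names).
#' @param pressures named list of pressure [waveform]s (site names).
#' @param priors named numeric of relative supra-aortic flow-split weights
#'   (names = terminal segment ids).
#' @return object of class `measurement_set`.
#' @export
measurement_set <- function(flows = list(), areas = list(),
                            pressures = list(),
                            priors = c(`22` = 0.14, `24` = 0.07,
                                       `26` = 0.10)) {
  for (w in c(flows, areas, pressures))
    stopifnot(inherits(w, "waveform"), w$period > 0)
  for (a in areas) stopifnot(min(a$values) > 0)
  structure(list(flows = flows, areas = areas, pressures = pressures,
                 priors = priors),
            class = "measurement_set")
}

#' Generate a self-consistent synthetic measurement set
#'
#' Runs the 1D solver on a calibrated network and samples flow, area and
#' pressure at the mapped measurement planes, so that every waveform in
#' the returned set is exactly consistent with the generating model. The
#' ground-truth parameters travel with the set for closed-loop recovery
#' tests. Optionally the signals are downsampled to a fixed number of
#' cardiac phases (bin averaging, emulating gated MRI) and perturbed with
#' seeded additive Gaussian noise scaled by each signal's peak-to-peak
#' amplitude.
#'
#' @param net calibrated [network].
#' @param wk named list of [windkessel_params] per terminal id.
#' @param inflow root inflow [waveform].
#' @param cfg a [solver_config].
#' @param phases if not `NULL`, gate every waveform to this many phases.
#' @param noise named fractions `c(flow=, area=, pressure=)` of
#'   peak-to-peak amplitude used as noise standard deviation.
#' @param seed integer seed for the noise generator.
#' @param pressure_sites plane names whose pressure trace is exported as a
#'   tonometry-like measurement (default `"Carotid"`).
#' @return a [measurement_set] with attributes `truth` (list: `net`, `wk`,
#'   `inflow`) and `simulation` (the [run_simulation()] result).
#' @export
generate_self_consistent_dataset <- function(net, wk, inflow,
                                             cfg = solver_config(),
                                             phases = NULL,
                                             noise = c(flow = 0, area = 0,
                                                       pressure = 0),
                                             seed = 1L,
                                             pressure_sites = "Carotid") {
  sim <- run_simulation(net, inflow, wk, cfg)
  aortic <- setdiff(net$planes$site, pressure_sites)
  post <- function(w, frac) {
    if (!is.null(phases)) w <- waveform_gate(w, phases)
    if (frac > 0) {
      amp <- diff(range(w$values))
      w$values <- w$values + stats::rnorm(length(w$values), 0, frac * amp)
    }
    w
  }
  noise <- noise[c("flow", "area", "pressure")]
  noise[is.na(noise)] <- 0
  set.seed(seed)
  ms <- measurement_set(
    flows = lapply(sim$Q[aortic], post, frac = noise[["flow"]]),
    areas = lapply(sim$A[aortic], post, frac = noise[["area"]]),
    pressures = lapply(sim$P[pressure_sites], post,
                       frac = noise[["pressure"]])
  )
  attr(ms, "truth") <- list(net = net, wk = wk, inflow = inflow)
  attr(ms, "simulation") <- sim
  ms
}

#' Emulated in-vivo measurement session with inconsistent heart rates
#'
#' Wraps [generate_self_consistent_dataset()] and then re-times each
#' waveform to emulate a multi-modality session in which PC-MRI flow, cine
#' SSFP area and tonometry pressure acquisitions caught the subject at
#' different heart rates. Defaults reproduce the study conditions: flow
#' 61.5 +/- 3.4 bpm, area 65.2 +/- 1.5 bpm, pressure 59.3 +/- 2.4 bpm
#' (mean +/- sd across the per-modality acquisitions). Brachial and radial
#' pressure sites are emulated from the carotid trace by mild peripheral
#' amplification about the fitted asymptote, so that all three share the
#' same diastolic decay.
#'
#' @inheritParams generate_self_consistent_dataset
#' @param flow_hr,area_hr heart rates (bpm) assigned to the five aortic
#'   flow and area waveforms (defaults: evenly spaced with the stated
#'   modality mean and standard deviation).
#' @param pressure_hr heart rates (bpm) of the carotid, brachial and
#'   radial pressure recordings.
#' @param amplification peripheral systolic amplification factors for the
#'   brachial and radial emulations.
#' @return a [measurement_set] (with `truth` attribute).
#' @export
synthetic_session <- function(net, wk, inflow, cfg = solver_config(),
                              phases = 40L,
                              noise = c(flow = 0, area = 0, pressure = 0),
                              seed = 1L,
                              flow_hr = 61.5 + 3.4 * c(-2, -1, 0, 1, 2) / sqrt(2.5),
                              area_hr = 65.2 + 1.5 * c(-2, -1, 0, 1, 2) / sqrt(2.5),
                              pressure_hr = c(56.9, 59.3, 61.7),
                              amplification = c(1.08, 1.15)) {
  ms <- generate_self_consistent_dataset(net, wk, inflow, cfg,
                                         phases = phases, noise = noise,
                                         seed = seed)
  stopifnot(length(flow_hr) == length(ms$flows),
            length(area_hr) == length(ms$areas))
  ## a heart-rate change mostly lengthens or shortens diastole: keep the
  ## first part of the cycle (systole and early diastole) untouched and
  ## stretch the remainder, so feet and upstrokes stay where physiology
  ## puts them
  retime <- function(w, hr, keep = 0.5) {
    Tn <- 60 / hr
    ts <- w$times[1] + keep * w$period
    stopifnot(Tn > keep * w$period)
    f <- (Tn - keep * w$period) / ((1 - keep) * w$period)
    tt <- ifelse(w$times <= ts, w$times, ts + (w$times - ts) * f)
    waveform(tt, w$values, w$quantity, period = Tn)
  }
  for (i in seq_along(ms$flows))
    ms$flows[[i]] <- retime(ms$flows[[i]], flow_hr[i])
  for (i in seq_along(ms$areas))
    ms$areas[[i]] <- retime(ms$areas[[i]], area_hr[i])
  car <- ms$pressures[["Carotid"]]
  dec <- fit_diastolic_decay(car)
  amplify <- function(f) {
    waveform(car$times, dec$P_inf + (car$values - dec$P_inf) * f,
             "pressure", period = car$period)
  }
  ms$pressures <- list(Carotid = car, Brachial = amplify(amplification[1]),
                       Radial = amplify(amplification[2]))
  for (i in seq_along(ms$pressures))
    ms$pressures[[i]] <- waveform_set_period(ms$pressures[[i]],
                                             60 / pressure_hr[i])
  ms
}

#' Reference Windkessel parameters for the synthetic subject
#'
#' Builds a ground-truth outlet parameter set from nominal circulation
#' targets using the same lumped relations the calibration chain uses:
#' total resistance from a target mean pressure, total compliance from a
#' target diastolic time constant, matched supra-aortic proximal
#' resistances and a mildly reflective descending aorta. These are the
#' generating parameters for closed-loop recovery experiments.
#'
#' @param net a [network] with wave speeds assigned.
#' @param inflow root inflow [waveform].
#' @param gamma named flow fractions per terminal id.
#' @param mean_pressure target mean arterial pressure, Pa (default
#'   90 mmHg).
#' @param tau target diastolic decay time constant, s (default 1.3).
#' @param pout outflow pressure, Pa (default 33 mmHg).
#' @param aortic_rf reflection coefficient of the descending-aorta outlet
#'   (default -0.15, a mildly negative reflector).
#' @param aortic_terminal terminal id of the descending aorta.
#' @return named list of [windkessel_params] per terminal id.
#' @export
make_reference_windkessel <- function(net, inflow, gamma,
                                      mean_pressure = 90 * MMHG_PA,
                                      tau = 1.3, pout = 33 * MMHG_PA,
                                      aortic_rf = -0.15,
                                      aortic_terminal = NULL) {
  term_ids <- network_terminal_ids(net)
  aortic_terminal <- aortic_terminal %||%
    term_ids[which.max(net$segments$r_out[match(term_ids,
                                                net$segments$id)])]
  gamma <- gamma[as.character(term_ids)]
  RT <- total_resistance(mean_pressure, pout, waveform_mean(inflow))
  RTj <- terminal_total_resistances(RT, gamma)
  CT <- tau / RT
  Cc <- conduit_compliance(net)
  rho <- net$fluid$rho
  Z0 <- vapply(term_ids, function(id) {
    m <- segment_material_at(net, id, 1)
    characteristic_impedance(seg_row(net, id)$c_out, m$Ad, rho)
  }, numeric(1))
  names(Z0) <- as.character(term_ids)
  R1 <- Z0
  R1[as.character(aortic_terminal)] <-
    Z0[[as.character(aortic_terminal)]] * (1 + aortic_rf) / (1 - aortic_rf)
  dist <- distribute_compliances(CT - Cc, gamma, RTj, R1)
  wk <- stats::setNames(vector("list", length(term_ids)),
                        as.character(term_ids))
  for (id in as.character(term_ids))
    wk[[id]] <- windkessel_params(R1[[id]], RTj[[id]] - R1[[id]],
                                  dist$C[[id]], pout)
  wk
}
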