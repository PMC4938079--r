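#' Scenario configuration
#'
#' The four modelling assumptions explored when personalising the model:
#' how the outflow pressure is chosen, how pulse wave velocity is mapped to
#' the network, whether the descending-aorta outlet is reflective or
#' matched, and whether blood is viscous.
#'
#' @param pout_mode `"capillary_constant"` (one assumed capillary pressure
#'   at every outlet) or `"fitted_asymptote"` (the asymptote of the
#'   diastolic decay fit, subject-specific).
#' @param pwv_mode `"uniform_foot_to_foot"` or `"distributed_qa_loop"`.
#' @param r1_mode `"reflective_aorta"` (supra-aortic outlets matched,
#'   descending aorta reflective) or `"all_matched"`.
#' @param viscous logical; `FALSE` sets blood viscosity to zero.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(pout_mode = c("capillary_constant",
                                          "fitted_asymptote"),
                            pwv_mode = c("uniform_foot_to_foot",
                                         "distributed_qa_loop"),
                            r1_mode = c("reflective_aorta", "all_matched"),
                            viscous = TRUE) {
  structure(list(pout_mode = match.arg(pout_mode),
                 pwv_mode = match.arg(pwv_mode),
                 r1_mode = match.arg(r1_mode),
                 viscous = isTRUE(viscous)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @details `best_area()` is the preset that best reproduces aortic area
#'   waveforms (capillary outflow pressure); `best_pressure()` best
#'   reproduces the carotid pressure waveform (fitted asymptotic outflow
#'   pressure). The outflow pressure is the only independent parameter in
#'   which the two presets differ.
#' @export
best_area <- function() scenario_config("capillary_constant",
                                        "uniform_foot_to_foot",
                                        "reflective_aorta", TRUE)

#' @rdname scenario_config
#' @export
best_pressure <- function() scenario_config("fitted_asymptote",
                                            "uniform_foot_to_foot",
                                            "reflective_aorta", TRUE)

#' Calibrate all Windkessel outlet parameters
#'
#' Implements the complete outlet personalisation chain: outflow pressure
#' (capillary constant or fitted asymptote), root total resistance from
#' mean carotid pressure and mean inflow, per-terminal total resistances
#' from the flow fractions, total systemic compliance (decay time constant
#' or inflow-extrema estimator depending on the outflow-pressure mode),
#' conduit/peripheral compliance split, proximal resistances
#' (matched supra-aortic branches; reflective or matched descending
#' aorta) and the three-element compliance conversion.
#'
#' @param net a [network] with wave speeds assigned.
#' @param inflow aortic-root inflow [waveform].
#' @param pressures named list of pressure [waveform]s; the first is the
#'   carotid calibration wave, all are used for the decay fit (their
#'   fitted time constants and asymptotes are averaged).
#' @param gamma named flow fractions per terminal id (summing to 1).
#' @param scenario a [scenario_config].
#' @param capillary_pressure assumed capillary pressure, Pa (used in
#'   `capillary_constant` mode; default 33 mmHg).
#' @param aortic_terminal terminal id of the descending aorta (default:
#'   the terminal with the largest outlet radius).
#' @return list with `wk` (named list of [windkessel_params]), `state`
#'   (all intermediate global quantities) and `net` (with `Pd` reset to
#'   the measured diastolic pressure).
#' @export
calibrate_windkessel <- function(net, inflow, pressures, gamma,
                                 scenario = best_area(),
                                 capillary_pressure = 33 * MMHG_PA,
                                 aortic_terminal = NULL) {
  stopifnot(length(pressures) >= 1)
  carotid <- pressures[[1]]
  feats <- carotid_features_safe(carotid)
  net$Pd <- feats$p_dias

  term_ids <- network_terminal_ids(net)
  aortic_terminal <- aortic_terminal %||%
    term_ids[which.max(net$segments$r_out[match(term_ids,
                                                net$segments$id)])]
  gamma <- gamma[as.character(term_ids)]
  if (any(is.na(gamma))) stop("gamma must be named by terminal ids")

  ## outflow pressure and decay fit
  decay <- NULL
  if (scenario$pout_mode == "fitted_asymptote") {
    fits <- lapply(pressures, fit_diastolic_decay)
    decay <- list(P_inf = mean(vapply(fits, `[[`, numeric(1), "P_inf")),
                  tau = mean(vapply(fits, `[[`, numeric(1), "tau")),
                  fits = fits)
    Pout <- decay$P_inf
  } else {
    Pout <- capillary_pressure
    ## the decay fit is still needed for a reflective aortic R1
    if (scenario$r1_mode == "reflective_aorta")
      decay <- fit_diastolic_decay(carotid)
  }

  Qbar <- waveform_mean(inflow)
  RT <- total_resistance(feats$p_mean, Pout, Qbar)
  RTj <- terminal_total_resistances(RT, gamma)

  Cc <- conduit_compliance(net)
  CT <- if (scenario$pout_mode == "fitted_asymptote") {
    total_compliance("fitted", RT = RT, tau = decay$tau)
  } else {
    total_compliance("capillary", inflow = inflow,
                     p_sys = feats$p_sys, p_dias = feats$p_dias)
  }
  Cp <- CT - Cc
  if (Cp <= 0)
    stop("conduit compliance exceeds the total systemic compliance")

  ## proximal resistances
  rho <- net$fluid$rho
  Z0 <- vapply(term_ids, function(id) {
    m <- segment_material_at(net, id, 1)
    characteristic_impedance(seg_row(net, id)$c_out, m$Ad, rho)
  }, numeric(1))
  names(Z0) <- as.character(term_ids)
  R1 <- Z0
  if (scenario$r1_mode == "reflective_aorta") {
    R1[as.character(aortic_terminal)] <-
      reflective_aortic_R1(Z0[[as.character(aortic_terminal)]],
                           feats$p_sys, feats$p_infl, decay)
  }
  dist <- distribute_compliances(Cp, gamma, RTj, R1)
  wk <- stats::setNames(vector("list", length(term_ids)),
                        as.character(term_ids))
  for (id in as.character(term_ids)) {
    wk[[id]] <- windkessel_params(R1 = R1[[id]],
                                  R2 = RTj[[id]] - R1[[id]],
                                  C = dist$C[[id]], Pout = Pout)
  }
  state <- list(RT = RT, RTj = RTj, CT = CT, Cc = Cc, Cp = Cp,
                Cpj = dist$Cpj, gamma = gamma, Pout = Pout,
                Z0 = Z0, R1 = R1,
                Rf = reflection_coefficient(unname(R1), unname(Z0)),
                decay = decay, carotid = feats,
                mean_inflow = Qbar,
                aortic_terminal = aortic_terminal)
  list(wk = wk, state = state, net = net)
}

## carotid features, tolerating waveforms without a detectable systolic
## decay inflection (p_infl is then NA; only reflective R1 needs it)
carotid_features_safe <- function(p) {
  f <- try(carotid_features(p), silent = TRUE)
  if (!inherits(f, "try-error")) return(f)
  pr <- waveform_resample(p, 512L)
  list(p_sys = max(pr$values), p_dias = min(pr$values),
       p_mean = waveform_mean(pr), p_infl = NA_real_, t_infl = NA_real_)
}

#' Iterative refinement of Windkessel compliances and resistances
#'
#' Runs the 1D/0D model and rescales the outlet parameters until the
#' simulated carotid systolic and diastolic pressures match the measured
#' targets: distal resistances are rescaled multiplicatively to correct
#' the pressure-level mismatch (mean of systolic and diastolic, above the
#' outflow pressure) and compliances to correct the pulse-pressure
#' mismatch.
#'
#' @param net calibrated [network].
#' @param wk named list of [windkessel_params] (the starting point).
#' @param inflow root inflow [waveform].
#' @param target pressure [waveform] measured at `site`.
#' @param site plane name compared against `target` (default "Carotid").
#' @param cfg a [solver_config].
#' @param max_iters maximum refinement iterations (default 4).
#' @param tol relative systolic/diastolic error accepted as converged
#'   (default 0.01).
#' @return list with `wk` (refined), `log` (data.frame per iteration:
#'   systolic/diastolic relative errors and scale factors applied) and
#'   `simulation` (the last [run_simulation()] result).
#' @export
refine_windkessel <- function(net, wk, inflow, target, site = "Carotid",
                              cfg = solver_config(), max_iters = 4L,
                              tol = 0.01) {
  tgt_sys <- waveform_max(target)
  tgt_dias <- waveform_min(target)
  Cc <- conduit_compliance(net)
  log <- NULL
  worse <- 0L
  best_err <- Inf
  sim <- NULL
  lsc <- 0      # cumulative log compliance scale (for the secant update)
  hist <- NULL  # (lsc, log PP) pairs across iterations
  for (it in seq_len(max_iters + 1L)) {
    sim <- run_simulation(net, inflow, wk, cfg)
    p <- sim$P[[site]]
    e_sys <- (waveform_max(p) - tgt_sys) / tgt_sys
    e_dias <- (waveform_min(p) - tgt_dias) / tgt_dias
    err <- max(abs(e_sys), abs(e_dias))
    log <- rbind(log, data.frame(iteration = it - 1L, e_sys = e_sys,
                                 e_dias = e_dias))
    if (err < tol) break
    if (err >= best_err) worse <- worse + 1L else worse <- 0L
    best_err <- min(best_err, err)
    if (worse >= 3L)
      stop("Windkessel refinement diverging; log:\n",
           paste(utils::capture.output(print(log)), collapse = "\n"))
    if (it > max_iters) break
    ## pressure level -> distal resistances; pulse pressure -> total
    ## compliance (the pulse pressure responds to conduit plus peripheral
    ## compliance, so the ratio is applied to their sum and the
    ## peripheral share rescaled accordingly); once two iterates exist,
    ## a secant step on log pulse pressure vs log compliance replaces
    ## the unit-gain rule, which converges much faster when the pulse
    ## pressure responds sublinearly to the peripheral compliance
    Pout <- wk[[1]]$Pout
    PP <- waveform_max(p) - waveform_min(p)
    hist <- rbind(hist, c(lsc, log(PP)))
    kR <- (tgt_sys + tgt_dias - 2 * Pout) /
      (waveform_max(p) + waveform_min(p) - 2 * Pout)
    kCT <- PP / (tgt_sys - tgt_dias)
    CT_now <- Cc + sum(vapply(wk, function(w)
      w$C * (w$R2 / (w$R1 + w$R2))^2, numeric(1)))
    kC <- (kCT * CT_now - Cc) / (CT_now - Cc)
    if (kC <= 0) kC <- kCT
    if (nrow(hist) >= 2L) {
      dls <- diff(hist[, 1], lag = 1)
      dlp <- diff(hist[, 2], lag = 1)
      i <- length(dls)
      if (abs(dls[i]) > 1e-6) {
        slope <- dlp[i] / dls[i]                    # d log PP / d log Cp
        slope <- max(min(slope, -0.02), -3)
        kC2 <- exp(log((tgt_sys - tgt_dias) / PP) / slope)
        if (is.finite(kC2) && kC2 > 0)
          kC <- max(min(kC2, 4), 0.25)
      }
    }
    lsc <- lsc + log(kC)
    for (id in names(wk)) {
      RTj <- wk[[id]]$R1 + wk[[id]]$R2
      R2 <- RTj * kR - wk[[id]]$R1
      if (R2 <= 0) R2 <- wk[[id]]$R2 * kR
      wk[[id]] <- windkessel_params(wk[[id]]$R1, R2,
                                    wk[[id]]$C * kC, Pout)
    }
  }
  list(wk = wk, log = log, simulation = sim)
}
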