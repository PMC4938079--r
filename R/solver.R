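#' Solver configuration
#'
#' @param dx target axial cell size, m (default 2.5 mm; every segment gets
#'   at least 3 nodes).
#' @param cfl Courant number used to pick the time step from the diastolic
#'   wave speeds plus a velocity headroom (default 0.5).
#' @param u_headroom velocity headroom added to the diastolic wave speed in
#'   the time-step bound, m/s (default 2).
#' @param dt explicit time step, s (overrides the CFL choice).
#' @param min_cycles minimum number of cardiac cycles simulated (default 4).
#' @param max_cycles maximum number of cycles (default 12).
#' @param tol_periodicity relative L2 change of the monitored pressure
#'   between consecutive cycles accepted as periodic (default 0.01).
#' @param monitor name of the plane used for the periodicity check
#'   (default: the last plane of the network's map).
#' @param n_out samples per cycle retained in the returned waveforms
#'   (default 512).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dx = 2.5e-3, cfl = 0.5, u_headroom = 2,
                          dt = NULL, min_cycles = 4L, max_cycles = 12L,
                          tol_periodicity = 0.01, monitor = NULL,
                          n_out = 512L) {
  stopifnot(dx > 0, cfl > 0, cfl < 1, min_cycles >= 4L,
            max_cycles >= min_cycles, tol_periodicity > 0)
  structure(list(dx = dx, cfl = cfl, u_headroom = u_headroom, dt = dt,
                 min_cycles = as.integer(min_cycles),
                 max_cycles = as.integer(max_cycles),
                 tol_periodicity = tol_periodicity, monitor = monitor,
                 n_out = as.integer(n_out)),
            class = "solver_config")
}

## discretize the network: per-segment node counts, dx, nodal Ad and beta
discretize_network <- function(net, dx_target) {
  ids <- net$segments$id
  segs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    L <- net$segments$length[k]
    ## cells: target size, but also limit the per-cell radius change in
    ## strongly tapered segments (boundary-coupling accuracy degrades with
    ## the taper per cell)
    n_len <- as.integer(round(L / dx_target)) + 1L
    taper <- abs(log(net$segments$r_out[k] / net$segments$r_in[k]))
    n_tap <- as.integer(ceiling(taper / 0.02)) + 1L
    n <- max(3L, n_len, n_tap)
    frac <- (seq_len(n) - 1) / (n - 1)
    m <- segment_material_at(net, ids[k], frac)
    segs[[k]] <- list(n = n, dx = L / (n - 1), Ad = m$Ad, beta = m$beta)
  }
  segs
}

#' Run a 1D pulse-wave simulation
#'
#' Solves the nonlinear 1D equations (mass and momentum with the tube-law
#' closure and a polynomial-profile friction term) on the network, with the
#' measured flow waveform prescribed at the root (its outgoing
#' characteristic absorbed, i.e. a non-reflective inflow) and a
#' three-element Windkessel at every terminal. Cycles are repeated until
#' the pressure at the monitored plane changes by less than the periodicity
#' tolerance between consecutive cycles.
#'
#' @param net a [network] with wave speeds assigned and a plane map.
#' @param inflow periodic flow [waveform] prescribed at the root (m^3/s).
#' @param wk named list of [windkessel_params], names = terminal segment
#'   ids.
#' @param cfg a [solver_config].
#' @return object of class `simulation_result`: per-plane lists `P`, `Q`,
#'   `A` of [waveform]s over the final cycle, `convergence` (per-cycle
#'   relative L2 change), `cycles`, `converged`, `max_junction_residual`
#'   (relative to peak inflow), and the final-cycle volume balance
#'   `volume_in`, `volume_out`, `volume_stored` (m^3).
#' @export
run_simulation <- function(net, inflow, wk, cfg = solver_config()) {
  stopifnot(inherits(net, "pw_network"), inherits(inflow, "waveform"))
  if (is.null(net$planes)) stop("network needs a measurement-plane map")
  ids <- net$segments$id
  term_ids <- network_terminal_ids(net)
  if (!all(as.character(term_ids) %in% names(wk)))
    stop("Windkessel parameters missing for terminals: ",
         paste(setdiff(as.character(term_ids), names(wk)), collapse = ", "))
  segs <- discretize_network(net, cfg$dx)

  parent0 <- match(net$segments$parent, ids) - 1L
  parent0[is.na(parent0)] <- -1L
  children0 <- lapply(ids, function(id)
    as.integer(match(network_children(net, id), ids) - 1L))
  terminal_of <- rep(-1L, length(ids))
  wkm <- matrix(0, nrow = length(term_ids), ncol = 4)
  for (j in seq_along(term_ids)) {
    terminal_of[match(term_ids[j], ids)] <- j - 1L
    w <- wk[[as.character(term_ids[j])]]
    wkm[j, ] <- c(w$R1, w$R2, w$C, w$Pout)
  }

  ## time step from diastolic wave speeds + headroom
  dt <- cfg$dt
  if (is.null(dt)) {
    bound <- Inf
    for (k in seq_along(segs)) {
      cmax <- max(wave_speed(segs[[k]]$Ad, segs[[k]]$Ad, segs[[k]]$beta,
                             net$fluid$rho))
      bound <- min(bound, segs[[k]]$dx / (cmax + cfg$u_headroom))
    }
    dt <- cfg$cfl * bound
  }

  qin <- waveform_resample(inflow, 2048L)
  planes <- net$planes
  pm <- matrix(0L, nrow = nrow(planes), ncol = 2)
  for (p in seq_len(nrow(planes))) {
    si <- match(planes$segment[p], ids)
    pm[p, 1] <- si - 1L
    pm[p, 2] <- as.integer(round(planes$frac[p] * (segs[[si]]$n - 1L)))
  }
  monitor <- cfg$monitor %||% planes$site[nrow(planes)]
  mi <- match(monitor, planes$site)
  if (is.na(mi)) stop("monitor plane not in the plane map: ", monitor)

  out <- solve_1d_cpp(segs, parent0, children0, terminal_of, wkm,
                      qin$values, qin$times[1], qin$period,
                      net$fluid$rho, net$fluid$mu, net$fluid$zeta,
                      net$Pd, dt, cfg$min_cycles, cfg$max_cycles,
                      cfg$tol_periodicity, pm, mi - 1L)
  if (!isTRUE(out$ok))
    stop("1D solver failed (", out$error, ") at t = ",
         signif(out$time, 4), " s")

  ## retain a uniform subsample of the final cycle
  m <- length(out$t)
  keep <- unique(as.integer(round(seq(1, m, length.out = min(cfg$n_out, m)))))
  t0 <- qin$times[1]
  mk <- function(v, q) waveform(t0 + out$t[keep], v[keep], q,
                                period = qin$period)
  res <- list(
    sites = planes$site,
    P = stats::setNames(lapply(out$P, mk, q = "pressure"), planes$site),
    Q = stats::setNames(lapply(out$Q, mk, q = "flow"), planes$site),
    A = stats::setNames(lapply(out$A, mk, q = "area"), planes$site),
    convergence = out$convergence,
    cycles = out$cycles,
    converged = out$converged,
    max_junction_residual = out$max_junction_residual,
    volume_in = out$volume_in,
    volume_out = stats::setNames(as.numeric(out$volume_out),
                                 as.character(term_ids)),
    volume_stored = out$volume_stored,
    dt = out$dt)
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_result> %d planes, %d cycles (%s), dt %.3g s\n",
           "  final periodicity metric %.3g, junction residual %.3g\n",
           "  cycle volume balance: in %.4g ml, out %.4g ml, stored %.4g ml\n"),
    length(x$sites), x$cycles,
    if (x$converged) "periodic" else "NOT periodic", x$dt,
    x$convergence[length(x$convergence)], x$max_junction_residual,
    1e6 * x$volume_in, 1e6 * sum(x$volume_out), 1e6 * x$volume_stored))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative error metrics between simulated and measured waveforms
#'
#' The two waveforms are phase-aligned at their feet and resampled onto a
#' common grid; then
#' * `avg`: cycle mean of |sim - meas| / normalizer,
#' * `max`: cycle max of the same,
#' * `sys`, `dias`: relative errors of the cycle maximum and minimum values
#'   (relative to the measured extremum itself).
#'
#' The normalizer is the measured cycle mean for pressure and area, and the
#' measured peak-to-peak amplitude for flow (whose mean can be near zero).
#'
#' @param sim,meas [waveform]s of the same quantity.
#' @param n comparison grid size.
#' @param period_tol admissible relative period mismatch (default 2%).
#' @param align phase-align at the feet before comparing (default TRUE).
#' @return named numeric `c(avg, max, sys, dias)` (dimensionless fractions).
#' @export
compute_relative_errors <- function(sim, meas, n = 256L,
                                    period_tol = 0.02, align = TRUE) {
  if (sim$quantity != meas$quantity)
    stop("waveforms measure different quantities")
  if (abs(sim$period - meas$period) > period_tol * meas$period)
    stop("period mismatch beyond tolerance: ",
         signif(sim$period, 4), " vs ", signif(meas$period, 4), " s")
  Tm <- meas$period
  shift <- 0
  if (align) {
    fs <- detect_foot(sim)$foot_time
    fm <- detect_foot(meas)$foot_time
    shift <- fs - fm
  }
  tt <- meas$times[1] + Tm * (seq_len(n) - 1) / n
  vm <- waveform_at(meas, tt)
  vs <- waveform_at(sim, tt * sim$period / Tm + shift)
  norm <- if (meas$quantity == "flow") diff(range(vm)) else mean(vm)
  if (abs(norm) <= 0) stop("degenerate measured waveform: zero normalizer")
  c(avg = mean(abs(vs - vm)) / abs(norm),
    max = max(abs(vs - vm)) / abs(norm),
    sys = abs(max(vs) - max(vm)) / abs(max(vm)),
    dias = abs(min(vs) - min(vm)) / abs(min(vm)))
}
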