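#' Heart-rate summary of a measurement set
#'
#' Per-modality mean and standard deviation of the heart rates implied by
#' each waveform's period.
#'
#' @param ms a [measurement_set].
#' @return data.frame with columns `modality`, `n`, `mean_bpm`, `sd_bpm`.
#' @export
heart_rate_summary <- function(ms) {
  hr <- function(ws) vapply(ws, waveform_heart_rate, numeric(1))
  mods <- list(flow = hr(ms$flows), area = hr(ms$areas),
               pressure = hr(ms$pressures))
  mods <- mods[vapply(mods, length, integer(1)) > 0]
  data.frame(
    modality = names(mods),
    n = vapply(mods, length, integer(1)),
    mean_bpm = vapply(mods, mean, numeric(1)),
    sd_bpm = vapply(mods, function(x) if (length(x) > 1) stats::sd(x) else 0,
                    numeric(1)),
    row.names = NULL
  )
}

#' Harmonize heart rates across all measurements
#'
#' Non-concurrent acquisitions catch the subject at different heart rates.
#' A common HR representative of all measurements is computed as the
#' (equally weighted) mean of every waveform's HR, and each waveform's
#' time axis is rescaled affinely so that its period equals `60/HR`. The
#' affine substitution leaves every cycle-mean value unchanged, and the
#' operation is idempotent.
#'
#' @param ms a [measurement_set].
#' @return list with `set` (the harmonized [measurement_set]) and
#'   `heart_rate` (common HR, bpm).
#' @export
harmonize_heart_rate <- function(ms) {
  all_w <- c(ms$flows, ms$areas, ms$pressures)
  if (!length(all_w)) stop("empty measurement set")
  hrs <- vapply(all_w, waveform_heart_rate, numeric(1))
  hr <- mean(hrs)
  Tp <- 60 / hr
  retime <- function(ws) lapply(ws, waveform_set_period, period = Tp)
  ms$flows <- retime(ms$flows)
  ms$areas <- retime(ms$areas)
  ms$pressures <- retime(ms$pressures)
  list(set = ms, heart_rate = hr)
}

#' Rescale network geometry to measured diastolic areas
#'
#' The dynamic (cine) area acquisitions resolve the true diastolic lumen
#' better than the anatomy scan used to build the network, so the model
#' radii are corrected to match them. At each aortic measurement plane the
#' area scale factor is the ratio of the measured diastolic area to the
#' model's diastolic area there; between planes the factor is linearly
#' interpolated in the axial coordinate, beyond the outermost planes the
#' nearest factor is held constant, and the supra-aortic branches are
#' scaled with the average aortic factor. Radii scale with the square root
#' of the area factor; lengths and wave-speed columns are untouched.
#'
#' @param net a [network] with a plane map.
#' @param measured_areas named numeric of diastolic areas (m^2) at aortic
#'   plane sites.
#' @return the rescaled [network].
#' @export
rescale_geometry <- function(net, measured_areas) {
  if (any(measured_areas <= 0)) stop("non-positive measured area")
  sites <- names(measured_areas)
  aortic_ids <- aortic_chain_ids(net)
  ## axial coordinate of each plane and each aortic segment endpoint
  x_of <- function(id, frac) {
    i <- match(id, aortic_ids)
    sum(net$segments$length[match(aortic_ids[seq_len(i - 1)],
                                  net$segments$id)]) +
      frac * seg_row(net, id)$length
  }
  xp <- fp <- numeric(length(sites))
  for (k in seq_along(sites)) {
    loc <- plane_location(net, sites[k])
    if (!(loc$segment %in% aortic_ids))
      stop("plane ", sites[k], " is not on the aortic chain")
    xp[k] <- x_of(loc$segment, loc$frac)
    model_Ad <- segment_material_at(net, loc$segment, loc$frac)$Ad
    fp[k] <- measured_areas[[k]] / model_Ad
  }
  o <- order(xp); xp <- xp[o]; fp <- fp[o]
  factor_at <- function(x) stats::approx(xp, fp, xout = x, rule = 2)$y
  s <- net$segments
  for (id in aortic_ids) {
    i <- match(id, s$id)
    s$r_in[i] <- s$r_in[i] * sqrt(factor_at(x_of(id, 0)))
    s$r_out[i] <- s$r_out[i] * sqrt(factor_at(x_of(id, 1)))
  }
  fbranch <- sqrt(mean(fp))
  for (i in which(!(s$id %in% aortic_ids))) {
    s$r_in[i] <- s$r_in[i] * fbranch
    s$r_out[i] <- s$r_out[i] * fbranch
  }
  net$segments <- s
  net
}

## segments on the root-to-terminal aortic path (largest terminal radius)
aortic_chain_ids <- function(net, aortic_terminal = NULL) {
  term <- aortic_terminal %||% {
    tid <- network_terminal_ids(net)
    tid[which.max(net$segments$r_out[match(tid, net$segments$id)])]
  }
  path <- term
  while (!is.na(seg_row(net, path[1])$parent))
    path <- c(seg_row(net, path[1])$parent, path)
  path
}

#' Flow fractions at the terminal branches
#'
#' The fraction of cardiac output leaving the descending aorta is the mean
#' of the descending-plane mean flows divided by the ascending mean flow
#' (averaging the descending planes mitigates the unphysical
#' proximal-to-distal increase that inconsistent acquisitions can show).
#' The remaining fraction is split among the supra-aortic branches in
#' proportion to the prior weights.
#'
#' @param ms a [measurement_set] whose `flows` include the ascending plane
#'   and at least one descending plane.
#' @param ascending name of the ascending-aorta flow plane.
#' @param descending names of the descending-aorta flow planes.
#' @param aortic_terminal terminal segment id fed by the descending aorta.
#' @param tol maximum tolerated excess of a descending mean flow over the
#'   ascending mean (relative; default 0.08) before the data are flagged
#'   unphysical.
#' @return named numeric of flow fractions per terminal id, summing to 1.
#' @export
compute_flow_fractions <- function(ms, ascending = "Asc Ao",
                                   descending = grep("^Desc",
                                                     names(ms$flows),
                                                     value = TRUE),
                                   aortic_terminal = 20L, tol = 0.08) {
  if (!ascending %in% names(ms$flows))
    stop("ascending flow plane not found: ", ascending)
  if (!length(descending)) stop("no descending flow planes found")
  qasc <- waveform_mean(ms$flows[[ascending]])
  qdesc <- vapply(ms$flows[descending], waveform_mean, numeric(1))
  if (any(qdesc > qasc * (1 + tol)))
    stop("descending mean flow exceeds ascending mean by more than ",
         round(100 * tol), "%: unphysical data")
  g_aorta <- min(mean(qdesc) / qasc, 0.95)
  pri <- ms$priors / sum(ms$priors)
  gamma <- c(g_aorta, (1 - g_aorta) * pri)
  names(gamma) <- c(as.character(aortic_terminal), names(pri))
  gamma
}
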