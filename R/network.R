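#' Build a 1D arterial network
#'
#' A network is a tree of deformable vessel segments, each described by its
#' length, diastolic radii and diastolic wave speeds at the proximal
#' (`_in`) and distal (`_out`) ends. Radii vary linearly with the axial
#' coordinate (circular cross sections, so `Ad(x) = pi * r(x)^2`); the
#' elastic parameter `beta` is interpolated linearly between its endpoint
#' values.
#'
#' @param segments data.frame with columns `id` (integer), `name`,
#'   `length` (m), `r_in`, `r_out` (m), `c_in`, `c_out` (m/s), `parent`
#'   (integer id, `NA` for the root) and `terminal` (logical).
#' @param fluid a [fluid_properties] object.
#' @param Pd diastolic reference pressure, Pa (default 80 mmHg; normally
#'   reset to the diastolic value of the calibration pressure waveform).
#' @param planes optional data.frame mapping named measurement planes to
#'   network locations: columns `site`, `segment` (id), `frac` (axial
#'   position as a fraction of segment length from the proximal end).
#' @return an object of class `pw_network`.
#' @export
network <- function(segments, fluid = fluid_properties(),
                    Pd = 80 * MMHG_PA, planes = NULL) {
  req <- c("id", "name", "length", "r_in", "r_out", "c_in", "c_out",
           "parent", "terminal")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table lacks columns: ",
                         paste(miss, collapse = ", "))
  segments <- as.data.frame(segments)[, req]
  validate_segments(segments)
  if (!is.null(planes)) {
    stopifnot(all(c("site", "segment", "frac") %in% names(planes)),
              !anyDuplicated(planes$site),
              all(planes$segment %in% segments$id),
              all(planes$frac >= 0 & planes$frac <= 1))
  }
  structure(
    list(segments = segments, fluid = fluid, Pd = Pd, planes = planes,
         wk = NULL),
    class = "pw_network"
  )
}

validate_segments <- function(s) {
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    if (!is.finite(row$length) || row$length <= 0)
      stop("segment row ", i, " (id ", row$id, "): non-positive length")
    if (row$r_in <= 0 || row$r_out <= 0)
      stop("segment row ", i, " (id ", row$id, "): non-positive radius")
    if (row$c_in <= 0 || row$c_out <= 0)
      stop("segment row ", i, " (id ", row$id, "): non-positive wave speed")
  }
  if (anyDuplicated(s$id)) stop("duplicate segment ids")
  roots <- which(is.na(s$parent))
  if (length(roots) != 1L) stop("network must have exactly one root segment")
  if (!all(s$parent[!is.na(s$parent)] %in% s$id))
    stop("parent ids must reference existing segments")
  ## tree check: every segment reaches the root without cycles
  idx <- stats::setNames(seq_len(nrow(s)), s$id)
  for (i in seq_len(nrow(s))) {
    seen <- integer(0); j <- i
    while (!is.na(s$parent[j])) {
      if (j %in% seen) stop("cycle detected in network topology")
      seen <- c(seen, j)
      j <- idx[[as.character(s$parent[j])]]
    }
  }
  kids <- table(factor(s$parent, levels = s$id))
  if (any(kids[as.character(s$id[s$terminal])] > 0))
    stop("a terminal segment cannot have children")
  if (!all(kids[as.character(s$id[!s$terminal])] > 0))
    stop("a non-terminal leaf segment found: mark it terminal")
  invisible(s)
}

#' @export
print.pw_network <- function(x, ...) {
  cat(sprintf(
    "<pw_network> %d segments, %d terminals, total length %.1f cm\n",
    nrow(x$segments), sum(x$segments$terminal),
    100 * sum(x$segments$length)))
  invisible(x)
}

network_root_id <- function(net) net$segments$id[is.na(net$segments$parent)]

network_terminal_ids <- function(net) net$segments$id[net$segments$terminal]

network_children <- function(net, id) {
  net$segments$id[!is.na(net$segments$parent) & net$segments$parent == id]
}

seg_row <- function(net, id) net$segments[match(id, net$segments$id), ]

#' Per-segment material at an axial position
#'
#' Diastolic area and elastic parameter at axial fraction `frac` of a
#' segment: the radius is linear in x and `beta` is linear between its
#' endpoint values `2*rho*c^2*sqrt(Ad)` evaluated at each end.
#'
#' @param net a [network].
#' @param id segment id.
#' @param frac axial fraction in \[0, 1\] (vectorised).
#' @return list with `Ad` (m^2), `beta` (Pa m), `r` (m).
#' @keywords internal
segment_material_at <- function(net, id, frac) {
  s <- seg_row(net, id)
  rho <- net$fluid$rho
  r <- s$r_in + (s$r_out - s$r_in) * frac
  Ad_in <- pi * s$r_in^2; Ad_out <- pi * s$r_out^2
  b_in <- beta_from_speed(s$c_in, Ad_in, rho)
  b_out <- beta_from_speed(s$c_out, Ad_out, rho)
  list(Ad = pi * r^2, beta = b_in + (b_out - b_in) * frac, r = r)
}

#' Assign diastolic wave speeds to every segment
#'
#' Two strategies for mapping measured pulse wave velocity onto the
#' network, mirroring the two estimation methods:
#' * `"uniform"` writes a single speed to every segment endpoint (the
#'   foot-to-foot strategy);
#' * `"distributed"` evaluates a fitted speed-diameter power law
#'   \eqn{c = a d^b} at each endpoint's local diastolic diameter (the
#'   QA-loop strategy).
#'
#' @param net a [network].
#' @param mode `"uniform"` or `"distributed"`.
#' @param speed uniform diastolic speed, m/s (uniform mode).
#' @param fit a [fit_speed_diameter_power_law()] result (distributed mode).
#' @return the network with updated `c_in`, `c_out` columns.
#' @export
assign_wave_speeds <- function(net, mode = c("uniform", "distributed"),
                               speed = NULL, fit = NULL) {
  mode <- match.arg(mode)
  s <- net$segments
  if (mode == "uniform") {
    if (is.null(speed) || speed <= 0) stop("uniform mode needs a speed > 0")
    s$c_in <- rep(speed, nrow(s))
    s$c_out <- rep(speed, nrow(s))
  } else {
    if (is.null(fit)) stop("distributed mode needs a power-law fit")
    s$c_in <- predict_power_law(fit, 2 * s$r_in)
    s$c_out <- predict_power_law(fit, 2 * s$r_out)
  }
  net$segments <- s
  net
}

#' Locate a named measurement plane
#' @param net a [network] with a plane map.
#' @param site plane name.
#' @return list with `segment` id and `frac`.
#' @export
plane_location <- function(net, site) {
  if (is.null(net$planes)) stop("network has no plane map")
  i <- match(site, net$planes$site)
  if (is.na(i)) stop("unknown measurement plane: ", site)
  list(segment = net$planes$segment[i], frac = net$planes$frac[i])
}

#' Centreline distance between two measurement planes
#'
#' Arc length along the tree path connecting two plane locations (both must
#' lie on a common root-to-leaf path).
#'
#' @param net a [network] with a plane map.
#' @param from,to plane names, `from` proximal to `to`.
#' @return distance in metres.
#' @export
plane_distance <- function(net, from, to) {
  a <- plane_location(net, from); b <- plane_location(net, to)
  path <- function(id) {
    out <- id
    while (!is.na(seg_row(net, id)$parent)) {
      id <- seg_row(net, id)$parent
      out <- c(id, out)
    }
    out
  }
  pb <- path(b$segment)
  if (!(a$segment %in% pb))
    stop("planes do not lie on a common root-to-leaf path")
  i <- match(a$segment, pb)
  between <- pb[-seq_len(i)]
  la <- seg_row(net, a$segment)$length
  d <- la * (1 - a$frac) +
    sum(net$segments$length[match(between, net$segments$id)])
  lb <- seg_row(net, b$segment)$length
  d - lb * (1 - b$frac)
}
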