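#' Bound-state series between a TAG molecule and a site
#'
#' The pair is bound at a sample when the smallest minimum-image distance
#' between the TAG molecule's particles and the site's particles is at or
#' below `cutoff_bind`.
#'
#' @param traj a [trajectory()].
#' @param tag_molecule_id molecule id of the TAG (from the topology).
#' @param site_id molecule id of the SITE group member (or a residue
#'   number when `site_is_residue = TRUE`).
#' @param cutoff_bind binding distance cutoff in nm (default 0.5, the
#'   contact cutoff; configurable for coarse inputs).
#' @param stride analysis stride in ns (default 1).
#' @param site_is_residue interpret `site_id` as a residue number of the
#'   RESIDUE group instead of a SITE molecule id.
#' @return An object of class `bound_series`: list with `times`, `bound`
#'   (logical), `tag_molecule_id`, `site_id`, `stride`.
#' @export
bound_series <- function(traj, tag_molecule_id, site_id, cutoff_bind = 0.5,
                         stride = 1, site_is_residue = FALSE) {
  top <- traj$topology
  tag_ids <- tag_molecule_particle_ids(top, tag_molecule_id)
  site_ids <- if (site_is_residue) {
    residue_particle_ids(top, site_id)
  } else {
    ids <- top$particle_id[top$group == "SITE" & top$molecule_id == site_id]
    if (length(ids) == 0L) stop("site ", site_id, " not present in topology")
    ids
  }
  idx <- stride_frame_index(traj$times, stride)
  bound <- logical(length(idx))
  for (k in seq_along(idx)) {
    bound[k] <- min_group_distance(traj, idx[k], tag_ids, site_ids) <=
      cutoff_bind
  }
  structure(list(times = traj$times[idx], bound = bound,
                 tag_molecule_id = tag_molecule_id, site_id = site_id,
                 stride = stride),
            class = "bound_series")
}

#' Dwell-time statistics from a bound-state series
#'
#' Maximal runs of bound samples become binding events; unbound gaps of at
#' most `gap_tolerance` samples between bound runs are merged into one
#' event.  Events truncated by either trajectory end are flagged censored;
#' the mean lifetime averages uncensored events only (censoring would bias
#' it downward), while the survival curve `S(t)` (fraction of events with
#' dwell `>= t`) keeps all events.
#'
#' @param series a [bound_series()], or a logical vector (then `times`
#'   must be supplied).
#' @param gap_tolerance maximum number of consecutive unbound samples to
#'   bridge (default 0: the literal single-crossing reading).
#' @param times sample times in ns when `series` is a bare logical vector.
#' @return An object of class `dwell_statistics`: list with `events`
#'   (data.frame `tag_id,site_id,start_ns,end_ns,dwell_ns,censored`),
#'   `mean_lifetime` (ns, uncensored events only; `NA` when none),
#'   `mean_dwell_all` (naive mean over all events, censored included),
#'   `n_events`, `survival` (data.frame `t_ns,survival`).
#' @export
extract_dwell_statistics <- function(series, gap_tolerance = 0L,
                                     times = NULL) {
  if (inherits(series, "bound_series")) {
    bound <- series$bound
    times <- series$times
    tag_id <- series$tag_molecule_id
    site_id <- series$site_id
  } else {
    bound <- as.logical(series)
    if (is.null(times)) times <- seq_along(bound) - 1
    tag_id <- NA_integer_
    site_id <- NA_integer_
  }
  if (length(bound) == 0L) stop("empty bound series")
  spacing <- if (length(times) > 1L) times[2] - times[1] else 1
  merged <- merge_gaps(bound, gap_tolerance)
  r <- rle(merged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ev <- lapply(runs, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    censored <- (i0 == 1L) || (i1 == length(bound))
    data.frame(tag_id = tag_id, site_id = site_id,
               start_ns = times[i0],
               end_ns = times[i1] + spacing,
               dwell_ns = (i1 - i0 + 1L) * spacing,
               censored = censored)
  })
  events <- if (length(ev) > 0L) do.call(rbind, ev) else
    data.frame(tag_id = integer(0), site_id = integer(0),
               start_ns = numeric(0), end_ns = numeric(0),
               dwell_ns = numeric(0), censored = logical(0))
  unc <- events$dwell_ns[!events$censored]
  mean_lifetime <- if (length(unc) > 0L) mean(unc) else NA_real_
  mean_dwell_all <- if (nrow(events) > 0L) mean(events$dwell_ns) else
    NA_real_
  surv <- if (nrow(events) > 0L) {
    tgrid <- sort(unique(c(0, events$dwell_ns)))
    data.frame(t_ns = tgrid,
               survival = vapply(tgrid, function(t) {
                 mean(events$dwell_ns >= t)
               }, numeric(1)))
  } else data.frame(t_ns = numeric(0), survival = numeric(0))
  structure(list(events = events, mean_lifetime = mean_lifetime,
                 mean_dwell_all = mean_dwell_all,
                 n_events = nrow(events), survival = surv,
                 gap_tolerance = gap_tolerance),
            class = "dwell_statistics")
}

# bridge FALSE runs of length <= gap_tolerance that sit between TRUE runs
merge_gaps <- function(bound, gap_tolerance) {
  if (gap_tolerance <= 0L || !any(bound)) return(bound)
  r <- rle(bound)
  nr <- length(r$values)
  for (j in seq_len(nr)) {
    if (!r$values[j] && r$lengths[j] <= gap_tolerance &&
        j > 1L && j < nr) {
      r$values[j] <- TRUE
    }
  }
  inverse.rle(r)
}

#' @export
print.dwell_statistics <- function(x, ...) {
  cat("dwell_statistics:", x$n_events, "event(s),",
      sum(x$events$censored), "censored\n")
  cat("  mean lifetime (uncensored):",
      if (is.na(x$mean_lifetime)) "NA" else
        paste0(signif(x$mean_lifetime, 4), " ns"), "\n")
  invisible(x)
}

#' Write dwell events and survival curve to CSV
#'
#' @param stats a [extract_dwell_statistics()] result.
#' @param events_path path for the event table
#'   (`tag_id,site_id,start_ns,end_ns,dwell_ns,censored`).
#' @param survival_path optional path for the survival curve
#'   (`t_ns,survival`).
#' @return `events_path`, invisibly.
#' @export
write_dwell_csv <- function(stats, events_path, survival_path = NULL) {
  utils::write.csv(stats$events, events_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(survival_path)) {
    utils::write.csv(stats$survival, survival_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(events_path)
}

#' Geometric hydrogen-bond criterion
#'
#' True when the donor-acceptor minimum-image distance is at most `d_max`
#' and the donor-hydrogen-acceptor angle is at least `angle_min`.  The
#' default thresholds (0.35 nm, 150 degrees) are the standard geometric
#' values for atomistic structures.
#'
#' @param traj a [trajectory()] in atomistic mode (one particle per atom).
#' @param frame_index 1-based frame index.
#' @param donor,hydrogen,acceptor 0-based particle ids, all distinct.
#' @param d_max donor-acceptor cutoff in nm.
#' @param angle_min minimum donor-H-acceptor angle in degrees (0, 180].
#' @return logical scalar.
#' @export
hbond_geometric <- function(traj, frame_index, donor, hydrogen, acceptor,
                            d_max = 0.35, angle_min = 150) {
  stopifnot(d_max > 0, angle_min > 0, angle_min <= 180)
  ids <- c(donor, hydrogen, acceptor)
  if (anyDuplicated(ids)) stop("donor, hydrogen and acceptor must differ")
  xyz <- frame_coords(traj, frame_index)
  box <- traj$box[frame_index, ]
  mi <- function(v) v - box * round(v / box)
  d_pos <- xyz[donor + 1L, ]
  h_pos <- xyz[hydrogen + 1L, ]
  a_pos <- xyz[acceptor + 1L, ]
  da <- mi(d_pos - a_pos)
  hd <- mi(d_pos - h_pos)
  ha <- mi(a_pos - h_pos)
  if (sqrt(sum(hd^2)) == 0 || sqrt(sum(ha^2)) == 0) {
    stop("coincident particles: donor-H-acceptor angle undefined")
  }
  dist_da <- sqrt(sum(da^2))
  cosang <- sum(hd * ha) / (sqrt(sum(hd^2)) * sqrt(sum(ha^2)))
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dist_da <= d_max && angle >= angle_min
}
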