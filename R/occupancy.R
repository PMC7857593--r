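#' Per-residue TAG contact series
#'
#' For each sampled frame, the residue is in contact when the smallest
#' minimum-image distance between any of its particles and any TAG particle
#' is at or below `cutoff` (a distance exactly equal to the cutoff counts
#' as contact).
#'
#' Sampling follows the analysis stride: when frames are finer than
#' `stride` the frame nearest to each stride grid point is used; when they
#' are coarser, every frame is used and a warning is logged.
#'
#' @param traj a [trajectory()] whose topology has RESIDUE and TAG groups.
#' @param residue_number residue to analyse (e.g. 166).
#' @param cutoff contact cutoff in nm (default 0.5).
#' @param stride analysis stride in ns (default 1).
#' @return An object of class `contact_series`: list with `residue_number`,
#'   `times` (ns), `contacts` (logical), `stride`.
#' @export
contact_series <- function(traj, residue_number, cutoff = 0.5, stride = 1) {
  res_ids <- residue_particle_ids(traj$topology, residue_number)
  tag_ids <- topology_group_ids(traj$topology, "TAG")
  if (length(tag_ids) == 0L) stop("topology has no TAG group")
  idx <- stride_frame_index(traj$times, stride)
  contacts <- logical(length(idx))
  for (k in seq_along(idx)) {
    d <- min_group_distance(traj, idx[k], res_ids, tag_ids)
    contacts[k] <- d <= cutoff
  }
  structure(list(residue_number = residue_number, times = traj$times[idx],
                 contacts = contacts, stride = stride),
            class = "contact_series")
}

# frame indices nearest to the stride grid; all frames (with a warning)
# when the trajectory is sampled coarser than the stride
stride_frame_index <- function(times, stride) {
  if (length(times) == 1L) return(1L)
  spacing <- stats::median(diff(times))
  if (spacing > stride * (1 + 1e-9)) {
    warning("frame spacing (", signif(spacing, 3),
            " ns) is coarser than the analysis stride (", stride,
            " ns); using every frame")
    return(seq_along(times))
  }
  grid <- seq(times[1], times[length(times)], by = stride)
  idx <- vapply(grid, function(t) which.min(abs(times - t)), integer(1))
  unique(idx)
}

#' Windowed occupancy per residue
#'
#' Occupancy is the fraction of sampled frames in the half-open window
#' `[t0, t1)` in which the residue is in TAG contact.  Windows are
#' half-open so that consecutive windows (e.g. 0-1000 ns and
#' 4000-5000 ns of a longer trajectory) partition cleanly.
#'
#' @param series_set a single `contact_series` or a list of them (one per
#'   residue).
#' @param window numeric `(t0, t1)` in ns, `t0 < t1`; must overlap the
#'   sampled time range.
#' @return An object of class `occupancy_profile`: list with
#'   `residue_numbers`, `window`, `occupancy` (named numeric in `[0, 1]`),
#'   `n_samples`, `n_replicates = 1`, `replicate_stats = NULL`.
#' @export
occupancy_profile <- function(series_set, window) {
  if (inherits(series_set, "contact_series")) series_set <- list(series_set)
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("window must be (t0, t1) with t0 < t1")
  }
  res <- vapply(series_set, function(s) s$residue_number, numeric(1))
  occ <- numeric(length(series_set))
  nsamp <- integer(length(series_set))
  for (k in seq_along(series_set)) {
    s <- series_set[[k]]
    in_win <- s$times >= window[1] & s$times < window[2]
    if (!any(in_win)) {
      stop("window [", window[1], ", ", window[2],
           ") contains no samples for residue ", s$residue_number)
    }
    occ[k] <- mean(s$contacts[in_win])
    nsamp[k] <- sum(in_win)
  }
  names(occ) <- res
  structure(list(residue_numbers = res, window = window, occupancy = occ,
                 n_samples = nsamp, n_replicates = 1L,
                 replicate_stats = NULL),
            class = "occupancy_profile")
}

#' Aggregate occupancy profiles across replicates
#'
#' Per residue, reports the mean occupancy and its standard error
#' (SEM = sd / sqrt(n), sample standard deviation with n - 1 denominator)
#' over replicate trajectories.  With a single replicate the SEM is `NA`.
#'
#' @param profiles list of [occupancy_profile()] objects with identical
#'   residue sets and windows.
#' @return An `occupancy_profile` whose `occupancy` holds the replicate
#'   mean and whose `replicate_stats` is a data.frame with columns
#'   `residue_number`, `mean`, `sem`, `n`.
#' @export
aggregate_replicates <- function(profiles) {
  if (inherits(profiles, "occupancy_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  ref <- profiles[[1]]
  for (p in profiles) {
    if (!identical(sort(p$residue_numbers), sort(ref$residue_numbers))) {
      stop("replicate profiles cover different residue sets")
    }
    if (!isTRUE(all.equal(p$window, ref$window))) {
      stop("replicate profiles cover different windows")
    }
  }
  res <- sort(ref$residue_numbers)
  n <- length(profiles)
  vals <- sapply(profiles, function(p) p$occupancy[as.character(res)])
  vals <- matrix(vals, nrow = length(res))
  mu <- rowMeans(vals)
  sem <- if (n > 1L) apply(vals, 1L, stats::sd) / sqrt(n) else rep(NA_real_,
                                                                   length(res))
  occ <- mu
  names(occ) <- res
  structure(list(residue_numbers = res, window = ref$window, occupancy = occ,
                 n_samples = NULL, n_replicates = n,
                 replicate_stats = data.frame(residue_number = res, mean = mu,
                                              sem = sem, n = n)),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("occupancy_profile: window [", x$window[1], ",", x$window[2],
      ") ns, ", length(x$residue_numbers), " residue(s), n_replicates = ",
      x$n_replicates, "\n", sep = "")
  print(utils::head(if (is.null(x$replicate_stats)) {
    data.frame(residue_number = x$residue_numbers, occupancy = x$occupancy)
  } else x$replicate_stats, 10))
  invisible(x)
}

#' Write an occupancy profile to CSV
#'
#' Columns: `residue_number,window_t0_ns,window_t1_ns,occupancy_mean,`
#' `occupancy_sem,n_replicates`.
#'
#' @param profile an [occupancy_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_csv <- function(profile, path) {
  sem <- if (is.null(profile$replicate_stats)) rep(NA_real_,
    length(profile$residue_numbers)) else profile$replicate_stats$sem
  df <- data.frame(
    residue_number = profile$residue_numbers,
    window_t0_ns = profile$window[1], window_t1_ns = profile$window[2],
    occupancy_mean = unname(profile$occupancy), occupancy_sem = sem,
    n_replicates = profile$n_replicates
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
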