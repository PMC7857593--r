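#' Generator configuration for the synthetic membrane
#'
#' Parameters of the overdamped-Langevin (Brownian-dynamics) membrane
#' generator.  TAG molecules are point particles diffusing in a periodic
#' 2D box, with a smooth short-range pairwise attraction and, optionally,
#' a ring of binding sites ("trap") that captures one TAG per site, slows
#' its diffusion to `D_bound`, and releases it as a Poisson process with
#' rate `k_off`.  The trap models an 11-subunit protein ring; each site
#' stands for one S166-like binding residue.
#'
#' Units: nm, ns, kT = 1 (the attraction depth `epsilon` is in kT).
#'
#' @param box `(Lx, Ly)` nm.
#' @param n_lipid_equivalents number of membrane lipids the box stands
#'   for; sets the mol% denominator.
#' @param tag_molpercent TAG concentration in mol% of lipids (presets use
#'   1.25, 2.5 and 4.85).
#' @param D_free,D_bound free / site-bound diffusion coefficients
#'   (nm^2/ns); default contrast 3x.
#' @param epsilon pairwise attraction depth (kT).
#' @param attraction_range attraction range (nm).
#' @param trap_enabled place the ring trap.
#' @param trap_center `(x, y)` nm; default box center.
#' @param ring_radius trap ring radius (nm).
#' @param n_sites number of trap sites (default 11).
#' @param capture_radius capture/tether radius per site (nm).
#' @param k_off unbinding rate (ns^-1); default `1/500` (0.5 us mean
#'   lifetime).
#' @param dt integration step (ns).
#' @param n_steps number of integration steps.
#' @param save_stride trajectory output interval (ns).
#' @param seed base RNG seed.
#' @param n_replicates replicate count for [simulate_replicates()].
#' @param seeded_cluster start with a preformed TAG cluster inside the
#'   ring (used by the `replenished_4_85` preset); the surplus above
#'   `free_molpercent` is placed in the ring.
#' @param free_molpercent mol% of initially free TAG when
#'   `seeded_cluster = TRUE`.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(box = c(40, 40), n_lipid_equivalents = 4800L,
                             tag_molpercent = 2.5, D_free = 0.009,
                             D_bound = 0.003, epsilon = 2,
                             attraction_range = 0.6, trap_enabled = FALSE,
                             trap_center = NULL, ring_radius = 1.05,
                             n_sites = 11L, capture_radius = 0.6,
                             k_off = 1 / 500, dt = 0.1, n_steps = 200000L,
                             save_stride = 1, seed = 1L,
                             n_replicates = 10L, seeded_cluster = FALSE,
                             free_molpercent = 2.5) {
  if (is.null(trap_center)) trap_center <- box / 2
  cfg <- structure(list(
    box = as.numeric(box), n_lipid_equivalents = as.integer(n_lipid_equivalents),
    tag_molpercent = tag_molpercent, D_free = D_free, D_bound = D_bound,
    epsilon = epsilon, attraction_range = attraction_range,
    trap_enabled = isTRUE(trap_enabled), trap_center = as.numeric(trap_center),
    ring_radius = ring_radius, n_sites = as.integer(n_sites),
    capture_radius = capture_radius, k_off = k_off, dt = dt,
    n_steps = as.integer(n_steps), save_stride = save_stride,
    seed = as.integer(seed), n_replicates = as.integer(n_replicates),
    seeded_cluster = isTRUE(seeded_cluster), free_molpercent = free_molpercent
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param config a `generator_config`.
#' @export
validate_generator_config <- function(config) {
  with(config, {
    stopifnot(all(box > 0), n_lipid_equivalents > 0, tag_molpercent > 0,
              D_free > 0, D_bound > 0, epsilon >= 0, attraction_range > 0,
              ring_radius > 0, n_sites > 0, capture_radius > 0, k_off > 0,
              dt > 0, n_steps > 0, save_stride > 0, n_replicates > 0)
  })
  if (n_tag_molecules(config) < 1L) {
    stop("tag_molpercent x n_lipid_equivalents yields no TAG molecules")
  }
  # stability: per-step motion must stay well below the attraction range
  fmax <- 8 / (3 * sqrt(3)) * config$epsilon / config$attraction_range
  step_scale <- sqrt(2 * config$D_free * config$dt) +
    config$D_free * fmax * config$dt
  if (step_scale > config$attraction_range / 2) {
    stop("dt too large for stable integration: per-step motion ",
         signif(step_scale, 3), " nm exceeds half the attraction range")
  }
  save_every <- config$save_stride / config$dt
  if (abs(save_every - round(save_every)) > 1e-9) {
    stop("save_stride must be a multiple of dt")
  }
  invisible(config)
}

n_tag_molecules <- function(config) {
  as.integer(round(config$tag_molpercent / 100 * config$n_lipid_equivalents))
}

#' Preset generator configurations
#'
#' The four study conditions the analyses are exercised under:
#' \describe{
#'   \item{`no_trap_2_5`}{2.5 mol% TAG, no trap: above the clustering
#'     threshold, TAGs aggregate spontaneously.}
#'   \item{`no_trap_1_25`}{1.25 mol% TAG, no trap: below threshold, TAGs
#'     stay mostly monomeric/dimeric.}
#'   \item{`trap_1_25`}{1.25 mol% TAG with the 11-site ring trap: the trap
#'     nucleates a cluster at a concentration that alone would not
#'     cluster.}
#'   \item{`replenished_4_85`}{a preformed cluster inside the ring plus
#'     2.5 mol% free TAG elsewhere, 4.85 mol% total.}
#' }
#' The attraction depth `epsilon` is frozen by the calibration script
#' shipped in `inst/scripts/calibrate_attraction.R`.
#'
#' @param name preset name.
#' @return a [generator_config()].
#' @export
preset_config <- function(name = c("no_trap_2_5", "no_trap_1_25",
                                   "trap_1_25", "replenished_4_85")) {
  name <- match.arg(name)
  switch(name,
    no_trap_2_5 = generator_config(tag_molpercent = 2.5,
                                   trap_enabled = FALSE),
    no_trap_1_25 = generator_config(tag_molpercent = 1.25,
                                    trap_enabled = FALSE),
    trap_1_25 = generator_config(tag_molpercent = 1.25,
                                 trap_enabled = TRUE),
    replenished_4_85 = generator_config(tag_molpercent = 4.85,
                                        trap_enabled = TRUE,
                                        seeded_cluster = TRUE,
                                        free_molpercent = 2.5)
  )
}

# site positions on the trap ring
trap_site_positions <- function(config) {
  ang <- 2 * pi * (seq_len(config$n_sites) - 1L) / config$n_sites
  cbind(config$trap_center[1] + config$ring_radius * cos(ang),
        config$trap_center[2] + config$ring_radius * sin(ang))
}

#' Simulate a synthetic membrane trajectory
#'
#' Runs the seeded Brownian-dynamics generator and returns the trajectory
#' together with the ground truth every estimator can be checked against.
#' The topology contains one particle per TAG molecule, one SITE particle
#' per trap site, RESIDUE probe particles at the trap sites (all carrying
#' residue number 166, one per subunit, so that the residue's contact
#' series pools all subunits) and four distal RESIDUE probes
#' (residue numbers 1-4) far from the ring.
#'
#' Identical seeds give bit-identical output.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed (default `config$seed`).
#' @param replicate_id replicate label stored in the trajectory.
#' @return list with `trajectory` (a [trajectory()]) and `ground_truth`:
#'   list with `states` (matrix frames x TAGs; site index 1..n_sites or
#'   `NA` when free), `times`, `events` (data.frame
#'   `tag_molecule_id,site_id,start_ns,end_ns,dwell_ns,censored`),
#'   `bound_intervals` (per-TAG list of `(start, end)` matrices),
#'   `D_free`, `D_bound`, `seed`, `config`.
#' @export
simulate_membrane <- function(config, seed = config$seed,
                              replicate_id = 1L) {
  validate_generator_config(config)
  set.seed(seed)
  n_tag <- n_tag_molecules(config)
  Lx <- config$box[1]; Ly <- config$box[2]
  sites <- if (config$trap_enabled) trap_site_positions(config) else
    matrix(numeric(0), 0L, 2L)

  xy0 <- matrix(0, n_tag, 2L)
  if (config$seeded_cluster && config$trap_enabled) {
    n_free <- as.integer(round(config$free_molpercent / 100 *
                                 config$n_lipid_equivalents))
    n_free <- min(n_free, n_tag)
    n_in <- n_tag - n_free
    # preformed cluster: uniform in a disk of the ring radius
    r <- config$ring_radius * sqrt(stats::runif(n_in))
    th <- stats::runif(n_in, 0, 2 * pi)
    xy0[seq_len(n_in), ] <- cbind(config$trap_center[1] + r * cos(th),
                                  config$trap_center[2] + r * sin(th))
    xy0[n_in + seq_len(n_free), ] <- cbind(stats::runif(n_free, 0, Lx),
                                           stats::runif(n_free, 0, Ly))
  } else {
    xy0 <- cbind(stats::runif(n_tag, 0, Lx), stats::runif(n_tag, 0, Ly))
  }
  xy0 <- wrap_into_box(xy0, config$box)

  save_every <- as.integer(round(config$save_stride / config$dt))
  sim <- cpp_bd_simulate(xy0, Lx, Ly, config$D_free, config$D_bound,
                         config$epsilon, config$attraction_range, sites,
                         config$capture_radius, config$k_off, config$dt,
                         config$n_steps, save_every)

  n_save <- nrow(sim$x)
  times <- (seq_len(n_save) - 1L) * config$save_stride
  z0 <- 5
  Lz <- 10

  # static particles: sites, ring probes (residue 166), distal probes
  n_sites <- nrow(sites)
  distal <- rbind(c(Lx * 0.125, Ly * 0.125), c(Lx * 0.125, Ly * 0.875),
                  c(Lx * 0.875, Ly * 0.125), c(Lx * 0.875, Ly * 0.875))
  static_xy <- rbind(sites, sites, distal)
  n_static <- nrow(static_xy)
  np <- n_tag + n_static

  top <- topology(
    particle_id = seq_len(np) - 1L,
    name = c(rep("TAG", n_tag), rep("SITE", n_sites), rep("S166", n_sites),
             paste0("PRB", seq_len(4L))),
    group = c(rep("TAG", n_tag), rep("SITE", n_sites),
              rep("RESIDUE", n_sites), rep("RESIDUE", 4L)),
    molecule_id = c(seq_len(n_tag) - 1L, seq_len(n_sites) - 1L,
                    seq_len(n_sites) - 1L, seq_len(4L) - 1L),
    residue_number = c(rep(NA_integer_, n_tag + n_sites),
                       rep(166L, n_sites), 1:4)
  )

  coords <- array(0, dim = c(np, 3L, n_save))
  for (k in seq_len(n_save)) {
    coords[seq_len(n_tag), 1L, k] <- sim$x[k, ]
    coords[seq_len(n_tag), 2L, k] <- sim$y[k, ]
    if (n_static > 0L) {
      coords[n_tag + seq_len(n_static), 1L, k] <- static_xy[, 1]
      coords[n_tag + seq_len(n_static), 2L, k] <- static_xy[, 2]
    }
    coords[, 3L, k] <- z0
  }
  traj <- trajectory(top, coords, times, c(Lx, Ly, Lz),
                     replicate_id = replicate_id)

  states <- sim$state + 1L
  states[states == 0L] <- NA_integer_
  events <- data.frame(
    tag_molecule_id = sim$ev_particle,
    site_id = sim$ev_site + 1L,
    start_ns = sim$ev_start * config$dt,
    end_ns = sim$ev_end * config$dt,
    censored = sim$ev_censored == 1L
  )
  events$dwell_ns <- events$end_ns - events$start_ns
  events <- events[order(events$tag_molecule_id, events$start_ns), ,
                   drop = FALSE]
  rownames(events) <- NULL
  bound_intervals <- lapply(seq_len(n_tag) - 1L, function(m) {
    ev <- events[events$tag_molecule_id == m, , drop = FALSE]
    if (nrow(ev) == 0L) matrix(numeric(0), 0L, 2L) else
      cbind(ev$start_ns, ev$end_ns)
  })
  gt <- list(states = states, times = times, events = events,
             bound_intervals = bound_intervals, D_free = config$D_free,
             D_bound = config$D_bound, seed = seed, config = config)
  list(trajectory = traj, ground_truth = gt)
}

#' Simulate a set of replicate trajectories
#'
#' Replicate `r` uses seed `config$seed + r - 1`; this per-replicate seed
#' derivation is the package's documented convention, so replicate sets
#' are reproducible from the single base seed.
#'
#' @param config a [generator_config()].
#' @param n number of replicates (default `config$n_replicates`).
#' @return list of [simulate_membrane()] results.
#' @export
simulate_replicates <- function(config, n = config$n_replicates) {
  lapply(seq_len(n), function(r) {
    simulate_membrane(config, seed = config$seed + r - 1L,
                      replicate_id = r)
  })
}

#' Draw displacement magnitudes from the free-diffusion distribution
#'
#' Samples n in-plane displacement magnitudes from
#' `P(dr) = dr/(2 D dt) exp(-dr^2/(4 D dt))` by inverse-CDF sampling.
#' Serves as the sampling oracle for [estimate_D()].
#'
#' @param D diffusion coefficient (nm^2/ns).
#' @param lag lag time (ns).
#' @param n sample size.
#' @param seed RNG seed.
#' @return a `displacement_sample`.
#' @export
sample_displacements <- function(D, lag = 1, n, seed = 1L) {
  stopifnot(D > 0, lag > 0, n > 0)
  set.seed(seed)
  r <- sqrt(-4 * D * lag * log(stats::runif(n)))
  structure(list(lag = lag, values = r, n = n, ids = NULL,
                 time_range = NULL),
            class = "displacement_sample")
}

#' Write generator ground truth to CSV
#'
#' Long format `particle_id,t_ns,state,site_id` (state `FREE`/`BOUND`).
#'
#' @param ground_truth the `ground_truth` element of
#'   [simulate_membrane()]'s result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(ground_truth, path) {
  st <- ground_truth$states
  n_tag <- ncol(st)
  df <- data.frame(
    particle_id = rep(seq_len(n_tag) - 1L, each = nrow(st)),
    t_ns = rep(ground_truth$times, n_tag),
    state = ifelse(is.na(as.vector(st)), "FREE", "BOUND"),
    site_id = ifelse(is.na(as.vector(st)), NA_integer_, as.vector(st))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generator config echo (structured text)
#'
#' @param config a [generator_config()].
#' @param path output path (YAML-style key: value text).
#' @return `path`, invisibly.
#' @export
write_config_echo <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
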