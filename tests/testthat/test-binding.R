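# fixture: one single-particle TAG and one site, fixed separation
pair_traj <- function(dist, n_frames = 20L) {
  coords <- array(0, dim = c(2, 3, n_frames))
  coords[1, , ] <- c(3 + dist, 3, 5)
  coords[2, , ] <- c(3, 3, 5)
  top <- topology(0:1, c("TAG", "SITE"), c("TAG", "SITE"),
                  molecule_id = c(0L, 0L))
  trajectory(top, coords, seq_len(n_frames) - 1, c(10, 10, 10))
}

test_that("bound series reflects the binding cutoff", {
  expect_true(all(bound_series(pair_traj(0.3), 0L, 0L,
                               cutoff_bind = 0.5)$bound))
  expect_false(any(bound_series(pair_traj(0.8), 0L, 0L,
                                cutoff_bind = 0.5)$bound))
  expect_error(bound_series(pair_traj(0.3), 5L, 0L), "not present")
  expect_error(bound_series(pair_traj(0.3), 0L, 9L), "not present")
})

test_that("run-length extraction and gap merging reproduce exactly", {
  series <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  st0 <- extract_dwell_statistics(series, gap_tolerance = 0,
                                  times = 0:8)
  expect_equal(st0$n_events, 2L)
  expect_equal(st0$events$dwell_ns, c(3, 3))
  expect_equal(st0$mean_dwell_all, 3)

  st3 <- extract_dwell_statistics(series, gap_tolerance = 3, times = 0:8)
  expect_equal(st3$n_events, 1L)
  expect_equal(st3$events$dwell_ns, 9)
})

test_that("events touching the trajectory ends are censored", {
  series <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)
  st <- extract_dwell_statistics(series, times = 0:6)
  expect_equal(st$events$censored, c(TRUE, FALSE, TRUE))
  # the mean lifetime uses uncensored events only
  expect_equal(st$mean_lifetime, 1)
  # the survival curve keeps every event
  expect_equal(st$survival$survival[st$survival$t_ns == 0], 1)
})

test_that("dwells plus gaps account for the full series duration", {
  set.seed(41)
  for (k in 1:20) {
    series <- runif(200) < 0.4
    st <- extract_dwell_statistics(series, gap_tolerance = 0)
    expect_equal(sum(st$events$dwell_ns), sum(series))
  }
})

test_that("dwell extraction is invariant to padding with unbound samples", {
  set.seed(43)
  series <- runif(100) < 0.3
  series[1] <- FALSE; series[100] <- FALSE
  base <- extract_dwell_statistics(series, times = 0:99)
  padded <- extract_dwell_statistics(c(FALSE, FALSE, series, FALSE),
                                     times = -2:100)
  expect_equal(padded$events$dwell_ns, base$events$dwell_ns)
  expect_equal(padded$events$start_ns, base$events$start_ns)
  expect_equal(padded$mean_lifetime, base$mean_lifetime)
})

test_that("exponential dwell durations are recovered within 10%", {
  set.seed(47)
  dwells <- pmax(1, round(rexp(1000, 1 / 100)))
  gaps <- pmax(1, round(rexp(1000, 1 / 50)))
  series <- logical(0)
  for (i in seq_len(1000)) {
    series <- c(series, rep(TRUE, dwells[i]), rep(FALSE, gaps[i]))
  }
  series <- c(FALSE, series)  # uncensored on the left
  st <- extract_dwell_statistics(series, times = seq_along(series) - 1)
  expect_equal(st$mean_lifetime, mean(dwells), tolerance = 1e-9)
  expect_equal(st$mean_lifetime, 100, tolerance = 0.1)
})

test_that("distance-based bound series matches generator ground truth", {
  # well-separated sites so that site identity is unambiguous from
  # geometry; fast free diffusion so post-unbinding escape is brief
  cfg <- generator_config(tag_molpercent = 2.5, epsilon = 0,
                          trap_enabled = TRUE, n_sites = 3L,
                          ring_radius = 3, D_free = 0.05,
                          D_bound = 0.05 / 3, k_off = 0.002,
                          n_steps = 50000L)
  sim <- simulate_membrane(cfg, seed = 61)
  gt <- sim$ground_truth
  # the most-bound TAG over the run
  m <- which.max(colSums(!is.na(gt$states))) - 1L
  truth_site <- gt$states[, m + 1L]
  agree <- 0L; total <- 0L
  for (s in sort(unique(truth_site[!is.na(truth_site)]))) {
    bs <- bound_series(sim$trajectory, m, s - 1L,
                       cutoff_bind = cfg$capture_radius)
    truth <- !is.na(truth_site) & truth_site == s
    agree <- agree + sum(bs$bound == truth)
    total <- total + length(truth)
  }
  expect_gte(agree / total, 0.99)
})

test_that("a 5x unbinding-rate contrast is recovered from state series", {
  mean_dwell_from_states <- function(k_off, seed) {
    cfg <- generator_config(tag_molpercent = 2.5, trap_enabled = TRUE,
                            k_off = k_off, n_steps = 100000L)
    sim <- simulate_membrane(cfg, seed = seed)
    gt <- sim$ground_truth
    dwells <- numeric(0)
    for (p in seq_len(ncol(gt$states))) {
      col <- gt$states[, p]
      for (s in unique(col[!is.na(col)])) {
        st <- extract_dwell_statistics(!is.na(col) & col == s,
                                       times = gt$times)
        dwells <- c(dwells, st$events$dwell_ns[!st$events$censored])
      }
    }
    c(mean(dwells), length(dwells))
  }
  fast <- mean_dwell_from_states(0.05, seed = 71)
  slow <- mean_dwell_from_states(0.01, seed = 72)
  expect_gte(fast[2], 500)
  expect_gte(slow[2], 500)
  expect_equal(slow[1] / fast[1], 5, tolerance = 0.25)
})

test_that("the geometric hydrogen-bond criterion applies both thresholds", {
  place <- function(r_ha, angle_deg) {
    # hydrogen at origin, donor 0.1 nm along +x, acceptor at the given
    # H-A distance and D-H-A angle
    th <- angle_deg * pi / 180
    coords <- rbind(c(0.1, 0, 0),                      # donor
                    c(0, 0, 0),                        # hydrogen
                    c(r_ha * cos(th), r_ha * sin(th), 0)) # acceptor
    coords <- coords + 2  # keep clear of the box origin
    make_traj(coords, box = c(10, 10, 10))
  }
  # d(D,A) ~ 0.289 nm, angle 170 deg: both thresholds satisfied
  expect_true(hbond_geometric(place(0.19, 170), 1L, 0L, 1L, 2L))
  # d(D,A) ~ 0.400 nm, angle 175 deg: distance fails
  expect_false(hbond_geometric(place(0.30, 175), 1L, 0L, 1L, 2L))
  # d(D,A) ~ 0.298 nm, angle 120 deg: angle fails
  expect_false(hbond_geometric(place(0.235, 120), 1L, 0L, 1L, 2L))

  expect_error(hbond_geometric(place(0.19, 170), 1L, 0L, 0L, 2L),
               "differ")
})
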