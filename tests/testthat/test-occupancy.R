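# two-particle fixture: one residue particle at the origin, one TAG at a
# fixed distance, replicated over n frames
contact_fixture <- function(dist, n_frames = 100L) {
  coords <- array(0, dim = c(2, 3, n_frames))
  coords[1, , ] <- c(1, 1, 1)
  coords[2, , ] <- c(1 + dist, 1, 1)
  top <- topology(0:1, c("S166", "TAG"), c("RESIDUE", "TAG"),
                  molecule_id = c(0L, 0L),
                  residue_number = c(166L, NA))
  trajectory(top, coords, seq_len(n_frames) - 1, c(10, 10, 10))
}

test_that("the 0.5-nm contact rule includes the boundary", {
  expect_true(all(contact_series(contact_fixture(0.4), 166)$contacts))
  expect_false(any(contact_series(contact_fixture(0.6), 166)$contacts))
  # a distance of exactly 0.5 nm counts as contact ("0.5 nm or less")
  expect_true(all(contact_series(contact_fixture(0.5), 166)$contacts))
})

test_that("contact series errors on missing residue or TAG group", {
  traj <- contact_fixture(0.4)
  expect_error(contact_series(traj, 99), "not present")
  no_tag <- traj
  no_tag$topology$group[2] <- "OTHER"
  expect_error(contact_series(no_tag, 166), "TAG")
})

test_that("windowed occupancy is the in-window contact fraction", {
  set.seed(5)
  contacts <- rep(FALSE, 1000)
  contacts[sample(1000, 370)] <- TRUE
  s <- structure(list(residue_number = 166, times = 0:999,
                      contacts = contacts, stride = 1),
                 class = "contact_series")
  prof <- occupancy_profile(s, c(0, 1000))
  expect_equal(unname(prof$occupancy), 0.37)

  all_true <- structure(list(residue_number = 1, times = 0:99,
                             contacts = rep(TRUE, 100), stride = 1),
                        class = "contact_series")
  expect_equal(unname(occupancy_profile(all_true, c(0, 100))$occupancy), 1)
  all_false <- all_true
  all_false$contacts <- rep(FALSE, 100)
  expect_equal(unname(occupancy_profile(all_false, c(0, 100))$occupancy), 0)

  expect_error(occupancy_profile(s, c(500, 500)), "t0 < t1")
  expect_error(occupancy_profile(s, c(5000, 6000)), "no samples")
})

test_that("occupancy over a union of disjoint windows is the weighted mean", {
  set.seed(6)
  s <- structure(list(residue_number = 166, times = 0:999,
                      contacts = runif(1000) < 0.3, stride = 1),
                 class = "contact_series")
  w1 <- c(0, 300); w2 <- c(300, 1000)
  o1 <- unname(occupancy_profile(s, w1)$occupancy)
  o2 <- unname(occupancy_profile(s, w2)$occupancy)
  o_all <- unname(occupancy_profile(s, c(0, 1000))$occupancy)
  expect_equal(o_all, (300 * o1 + 700 * o2) / 1000)
})

test_that("replicate aggregation computes mean and SEM correctly", {
  mk <- function(vals) {
    structure(list(residue_numbers = c(1, 2), window = c(0, 10),
                   occupancy = stats::setNames(vals, c(1, 2)),
                   n_samples = c(10L, 10L), n_replicates = 1L,
                   replicate_stats = NULL),
              class = "occupancy_profile")
  }
  same <- aggregate_replicates(rep(list(mk(c(0.5, 0.8))), 10))
  expect_equal(same$replicate_stats$sem, c(0, 0))
  expect_equal(unname(same$occupancy), c(0.5, 0.8))

  two <- aggregate_replicates(list(mk(c(0.2, 0.2)), mk(c(0.4, 0.4))))
  expect_equal(two$replicate_stats$mean, c(0.3, 0.3))
  expect_equal(two$replicate_stats$sem, c(0.1, 0.1))

  one <- aggregate_replicates(list(mk(c(0.2, 0.3))))
  expect_true(all(is.na(one$replicate_stats$sem)))

  expect_error(aggregate_replicates(list(mk(c(0.1, 0.1)), {
    p <- mk(c(0.1, 0.1)); p$residue_numbers <- c(1, 3)
    names(p$occupancy) <- c(1, 3); p
  })), "different residue sets")
})

test_that("contact series agrees with the periodic all-pairs brute force", {
  traj <- make_random_fixture(n_tag = 47L, n_res = 3L, n_frames = 20L,
                              seed = 21)
  got <- contact_series(traj, 166, cutoff = 0.9)
  tag_rows <- which(traj$topology$group == "TAG")
  res_rows <- which(traj$topology$group == "RESIDUE")
  for (f in seq_len(20)) {
    d <- bf_group_min(traj$coords[res_rows, , f],
                      traj$coords[tag_rows, , f], traj$box[f, ])
    expect_identical(got$contacts[f], d <= 0.9)
  }
})

test_that("trap-adjacent probe residues out-occupy distal probes", {
  # ring probes (residue 166) sit on the trap sites; residues 1-4 are far
  # from the ring.  Over several seeds the ring occupancy must dominate.
  ring <- numeric(5)
  distal <- numeric(5)
  for (s in 1:5) {
    cfg <- generator_config(tag_molpercent = 1.25, trap_enabled = TRUE,
                            n_steps = 30000L)
    sim <- simulate_membrane(cfg, seed = 500 + s)
    series <- lapply(c(166, 1, 2, 3, 4), function(r) {
      contact_series(sim$trajectory, r, stride = 10)
    })
    prof <- occupancy_profile(series, c(0, 3000))
    ring[s] <- prof$occupancy["166"]
    distal[s] <- mean(prof$occupancy[c("1", "2", "3", "4")])
  }
  expect_true(all(ring > distal))
  expect_gt(mean(ring) - mean(distal), 0.1)
})

test_that("occupancy CSV has the documented columns", {
  s <- structure(list(residue_number = 166, times = 0:9,
                      contacts = rep(TRUE, 10), stride = 1),
                 class = "contact_series")
  prof <- aggregate_replicates(rep(list(occupancy_profile(s, c(0, 10))), 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occupancy_csv(prof, path)
  df <- read.csv(path)
  expect_named(df, c("residue_number", "window_t0_ns", "window_t1_ns",
                     "occupancy_mean", "occupancy_sem", "n_replicates"))
  expect_equal(df$occupancy_mean, 1)
  expect_equal(df$n_replicates, 3)
})
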