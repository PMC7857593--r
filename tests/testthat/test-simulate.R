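test_that("identical seeds give bit-identical trajectories", {
  cfg <- generator_config(tag_molpercent = 1.25, trap_enabled = TRUE,
                          n_steps = 5000L)
  a <- simulate_membrane(cfg, seed = 9)
  b <- simulate_membrane(cfg, seed = 9)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$ground_truth$states, b$ground_truth$states)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  c <- simulate_membrane(cfg, seed = 10)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("particles stay inside the box and counts are conserved", {
  cfg <- generator_config(tag_molpercent = 2.5, trap_enabled = TRUE,
                          n_steps = 5000L)
  sim <- simulate_membrane(cfg, seed = 3)
  traj <- sim$trajectory
  expect_equal(dim(traj$coords)[1], nrow(traj$topology))
  xy <- traj$coords[traj$topology$group == "TAG", 1:2, ]
  expect_true(all(xy >= 0))
  expect_true(all(xy[, 1, ] < cfg$box[1] & xy[, 2, ] < cfg$box[2]))
  expect_equal(sum(traj$topology$group == "TAG"), 120L)  # 2.5% of 4800
  expect_equal(sum(traj$topology$group == "SITE"), 11L)
})

test_that("bound states respect the capture-radius invariant", {
  cfg <- generator_config(tag_molpercent = 2.5, trap_enabled = TRUE,
                          n_steps = 20000L)
  sim <- simulate_membrane(cfg, seed = 5)
  gt <- sim$ground_truth
  top <- sim$trajectory$topology
  sites <- sim$trajectory$coords[top$group == "SITE", 1:2, 1]
  tag_rows <- which(top$group == "TAG")
  checked <- 0L
  bad <- 0L
  for (f in seq(1, nrow(gt$states), by = 37)) {
    for (p in which(!is.na(gt$states[f, ]))) {
      sp <- sites[gt$states[f, p], ]
      xy <- sim$trajectory$coords[tag_rows[p], 1:2, f]
      # trap sits mid-box, far from the boundary: no wrapping needed
      if (sqrt(sum((xy - sp)^2)) > cfg$capture_radius + 1e-9) bad <- bad + 1L
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100)
  expect_identical(bad, 0L)
})

test_that("free diffusion is recovered when attraction and trap are off", {
  cfg <- generator_config(tag_molpercent = 2.5, epsilon = 0,
                          trap_enabled = FALSE, n_steps = 10000L)
  sim <- simulate_membrane(cfg, seed = 21)
  s <- collect_displacements(sim$trajectory, lag = 1)
  expect_gte(s$n, 1e4)
  est <- estimate_D(s)
  se <- cfg$D_free / sqrt(s$n)
  expect_lt(abs(est$D - cfg$D_free), 3 * se)
})

test_that("ground-truth dwell times are exponential with rate k_off", {
  dwells <- numeric(0)
  for (s in 1:10) {
    cfg <- generator_config(tag_molpercent = 2.5, trap_enabled = TRUE,
                            n_steps = 50000L)
    sim <- simulate_membrane(cfg, seed = 900 + s)
    ev <- sim$ground_truth$events
    dwells <- c(dwells, ev$dwell_ns[!ev$censored])
  }
  expect_gt(length(dwells), 300)
  ks <- suppressWarnings(stats::ks.test(dwells, stats::pexp,
                                        rate = 1 / 500))
  expect_gt(ks$p.value, 0.01)
})

test_that("without attraction or trap, 1.25 mol% stays unclustered", {
  finals <- vapply(1:10, function(s) {
    cfg <- generator_config(tag_molpercent = 1.25, epsilon = 0,
                            trap_enabled = FALSE, n_steps = 5000L)
    sim <- simulate_membrane(cfg, seed = 700 + s)
    cs <- clustered_fraction_series(sim$trajectory, stride = 100)
    cs$clustered_fraction[length(cs$times)]
  }, numeric(1))
  expect_lt(mean(finals), 0.1)
})

test_that("sampled displacement magnitudes follow the 2D diffusion law", {
  s <- sample_displacements(0.5, 1, 1e5, seed = 31)
  expect_equal(mean(s$values^2), 4 * 0.5 * 1, tolerance = 0.01)
  one <- sample_displacements(0.5, 1, 1, seed = 1)
  expect_length(one$values, 1)
  expect_gte(one$values, 0)
  expect_identical(sample_displacements(0.2, 1, 50, seed = 5)$values,
                   sample_displacements(0.2, 1, 50, seed = 5)$values)
})

test_that("presets encode the study concentrations and trap geometry", {
  p1 <- preset_config("no_trap_2_5")
  expect_equal(p1$tag_molpercent, 2.5)
  expect_false(p1$trap_enabled)

  p2 <- preset_config("trap_1_25")
  expect_equal(p2$tag_molpercent, 1.25)
  expect_true(p2$trap_enabled)
  expect_equal(p2$n_sites, 11L)

  p3 <- preset_config("replenished_4_85")
  expect_equal(p3$tag_molpercent, 4.85)
  expect_true(p3$seeded_cluster)
  expect_equal(p3$free_molpercent, 2.5)
  # the seeded cluster starts inside the ring: clustered from frame one
  sim <- simulate_membrane(
    generator_config(tag_molpercent = 4.85, trap_enabled = TRUE,
                     seeded_cluster = TRUE, n_steps = 1000L), seed = 2)
  cc <- connected_components(sim$trajectory, 1L,
                             trap_center = p3$trap_center)
  expect_gt(cc$largest_size, 50)
  expect_lt(cc$centroid_dist_to_trap, p3$ring_radius + 0.6)

  expect_error(preset_config("bogus"))
})

test_that("config validation flags unstable step sizes", {
  expect_error(generator_config(D_free = 0.5, epsilon = 20, dt = 1),
               "dt too large")
  expect_error(generator_config(tag_molpercent = 1e-4), "no TAG")
  expect_error(generator_config(save_stride = 0.25, dt = 0.1),
               "multiple of dt")
})

test_that("ground-truth CSV and config echo round-trip", {
  cfg <- generator_config(tag_molpercent = 1.25, trap_enabled = TRUE,
                          n_steps = 2000L)
  sim <- simulate_membrane(cfg, seed = 4)
  gt_path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth_csv(sim$ground_truth, gt_path)
  df <- read.csv(gt_path)
  expect_named(df, c("particle_id", "t_ns", "state", "site_id"))
  expect_setequal(unique(df$state), c("FREE", "BOUND"))

  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  write_config_echo(cfg, cfg_path)
  echo <- yaml::read_yaml(cfg_path)
  expect_equal(echo$tag_molpercent, 1.25)
  expect_equal(echo$n_sites, 11)
})
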