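# build a single-frame trajectory of single-particle TAG molecules at the
# given in-plane positions
tag_frame <- function(xy, box = c(20, 20, 10)) {
  coords <- cbind(xy, 5)
  make_traj(coords, box = box, group = "TAG",
            molecule_id = seq_len(nrow(xy)) - 1L)
}

test_that("neighbor counts follow the molecule-molecule cutoff rule", {
  clique <- tag_frame(cbind(c(5, 5.3, 5.15, 5.1, 5.2),
                            c(5, 5, 5.25, 5.4, 5.15)))
  expect_equal(unname(tag_neighbor_counts(clique, 1L)), rep(4L, 5))

  lonely <- tag_frame(rbind(c(1, 1), c(10, 10)))
  expect_equal(unname(tag_neighbor_counts(lonely, 1L)), c(0L, 0L))
})

test_that("the clustered fraction excludes monomers and dimers", {
  # dimer among ten TAGs: fraction exactly 0
  xy <- rbind(c(1, 1), c(1.3, 1), c(4, 4), c(6, 2), c(8, 8), c(12, 3),
              c(14, 14), c(17, 5), c(3, 17), c(10, 12))
  cs <- clustered_fraction_series(tag_frame(xy))
  expect_identical(cs$clustered_fraction, 0)

  # chain A-B-C with only consecutive contacts: only B has >= 2 neighbors
  chain <- tag_frame(rbind(c(5, 5), c(5.4, 5), c(5.8, 5)))
  expect_equal(clustered_fraction_series(chain)$clustered_fraction, 1 / 3)

  # complete 5-clique: everyone clustered
  clique <- tag_frame(cbind(c(5, 5.3, 5.15, 5.1, 5.2),
                            c(5, 5, 5.25, 5.4, 5.15)))
  expect_equal(clustered_fraction_series(clique)$clustered_fraction, 1)
})

test_that("connected components match path and separated-clique cases", {
  chain <- tag_frame(rbind(c(5, 5), c(5.4, 5), c(5.8, 5)))
  cc <- connected_components(chain, 1L)
  expect_equal(cc$n_components, 1L)
  expect_equal(cc$largest_size, 3L)

  two_tri <- tag_frame(rbind(c(2, 2), c(2.3, 2), c(2.15, 2.3),
                             c(12, 12), c(12.3, 12), c(12.15, 12.3)))
  cc2 <- connected_components(two_tri, 1L)
  expect_equal(cc2$n_components, 2L)
  expect_equal(sort(cc2$sizes), c(3L, 3L))
})

test_that("neighbor counts and components match brute-force oracles", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 200L
    box <- c(12, 12, 6)
    xy <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
    traj <- tag_frame(xy, box = box)
    counts <- tag_neighbor_counts(traj, 1L)
    bf <- bf_neighbor_counts(cbind(xy, 3), seq_len(n) - 1L, box, 0.5)
    expect_identical(unname(counts), as.integer(bf))

    cc <- connected_components(traj, 1L)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i != j && bf_min_image(c(xy[i, ], 3), c(xy[j, ], 3), box) <= 0.5)
        adj[i, j] <- TRUE
    }
    bf_lab <- bf_components(adj)
    # labels must induce the same partition (up to renaming)
    expect_equal(length(unique(cc$labels)), length(unique(bf_lab)))
    expect_true(all(tapply(bf_lab, cc$labels,
                           function(v) length(unique(v))) == 1))
    set.seed(31 + rep)
  }
})

test_that("clustered fraction is invariant to relabeling and translation", {
  set.seed(33)
  box <- c(15, 15, 10)
  xy <- cbind(runif(40, 0, 15), runif(40, 0, 15))
  base <- clustered_fraction_series(tag_frame(xy, box))$clustered_fraction

  perm <- sample(40)
  relabeled <- clustered_fraction_series(tag_frame(xy[perm, ], box))
  expect_equal(relabeled$clustered_fraction, base)

  shift <- (xy + matrix(rep(c(3.7, 8.1), each = 40), ncol = 2)) %% 15
  translated <- clustered_fraction_series(tag_frame(shift, box))
  expect_equal(translated$clustered_fraction, base)
})

test_that("per-TAG rule is bounded by membership in size >= 3 components", {
  set.seed(34)
  for (rep in 1:10) {
    xy <- cbind(runif(60, 0, 10), runif(60, 0, 10))
    traj <- tag_frame(xy, box = c(10, 10, 10))
    counts <- tag_neighbor_counts(traj, 1L)
    cc <- connected_components(traj, 1L)
    in_big <- sum(cc$sizes[cc$labels] >= 3)
    expect_lte(sum(counts >= 2), in_big)
  }
})

test_that("periodic centroid handles clusters straddling the boundary", {
  xy <- rbind(c(0.1, 5), c(19.9, 5), c(0.3, 5))
  cen <- periodic_centroid(xy, c(20, 20))
  # the correct periodic mean sits near x = 0.1, never near the box middle
  expect_lt(min(cen[1], 20 - cen[1]), 1)
  expect_equal(cen[2], 5, tolerance = 1e-6)

  cc <- connected_components(tag_frame(xy), 1L,
                             trap_center = c(0, 5))
  expect_lt(cc$centroid_dist_to_trap, 1)
})

test_that("cluster CSV has the documented columns", {
  cs <- clustered_fraction_series(tag_frame(rbind(c(5, 5), c(5.4, 5),
                                                  c(5.8, 5))),
                                  trap_center = c(5.4, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_csv(cs, path)
  expect_named(read.csv(path),
               c("time_ns", "clustered_fraction", "n_clusters",
                 "largest_cluster_size", "centroid_x", "centroid_y",
                 "centroid_dist_to_trap"))
})
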