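# Brute-force oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (explicit loops, 27-image enumeration,
# hand-rolled BFS) and independent of the package's computational paths.

# minimum-image distance by enumerating all 27 periodic images
bf_min_image <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- a - (b + c(ix, iy, iz) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# all-pairs minimum distance between two coordinate sets, via bf_min_image
bf_group_min <- function(A, B, box) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    best <- min(best, bf_min_image(A[i, ], B[j, ], box))
  }
  best
}

# per-molecule neighbor counts by scanning every particle pair
bf_neighbor_counts <- function(xyz, mol, box, cutoff) {
  mols <- sort(unique(mol))
  n <- length(mols)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(xyz))) for (j in seq_len(nrow(xyz))) {
    gi <- match(mol[i], mols); gj <- match(mol[j], mols)
    if (gi == gj) next
    if (bf_min_image(xyz[i, ], xyz[j, ], box) <= cutoff) {
      adj[gi, gj] <- TRUE
    }
  }
  rowSums(adj)
}

# connected components by breadth-first search on the neighbor graph
bf_components <- function(adj) {
  n <- nrow(adj)
  labels <- rep(0L, n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  labels
}

# trajectory with explicit coordinates: coords is n x 3 (static across
# frames) or an n x 3 x nf array
make_traj <- function(coords, box = c(10, 10, 10), times = NULL,
                      group = "OTHER", molecule_id = NA_integer_,
                      residue_number = NA_integer_, nframes = NULL) {
  if (length(dim(coords)) == 2L) {
    nf <- nframes %||% 1L
    coords <- array(rep(coords, nf), dim = c(nrow(coords), 3L, nf))
  }
  np <- dim(coords)[1]
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq_len(nf) - 1
  top <- topology(particle_id = seq_len(np) - 1L,
                  name = rep_len("X", np),
                  group = rep_len(group, np),
                  molecule_id = rep_len(molecule_id, np),
                  residue_number = rep_len(residue_number, np))
  trajectory(top, coords, times, box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random membrane-like fixture: n_tag single-particle TAGs plus one
# residue of n_res particles, uniformly placed, static or random walk
make_random_fixture <- function(n_tag = 50L, n_res = 3L, n_frames = 20L,
                                box = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  np <- n_tag + n_res
  coords <- array(stats::runif(np * 3L * n_frames, 0, box[1]),
                  dim = c(np, 3L, n_frames))
  top <- topology(
    particle_id = seq_len(np) - 1L,
    name = c(rep("TAG", n_tag), rep("RES", n_res)),
    group = c(rep("TAG", n_tag), rep("RESIDUE", n_res)),
    molecule_id = c(seq_len(n_tag) - 1L, rep(0L, n_res)),
    residue_number = c(rep(NA_integer_, n_tag), rep(166L, n_res))
  )
  trajectory(top, coords, seq_len(n_frames) - 1, box)
}

# flat bilayer fixture: two head-group sheets at +/- z_sep/2 with noise
make_bilayer_traj <- function(n_per_leaflet = 400L, n_frames = 5L,
                              box = c(20, 20, 10), z_sep = 4,
                              z_noise = 0.05, seed = 1,
                              height_fun = NULL) {
  set.seed(seed)
  np <- 2L * n_per_leaflet
  coords <- array(NA_real_, dim = c(np, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    x <- stats::runif(np, 0, box[1])
    y <- stats::runif(np, 0, box[2])
    z0 <- rep(c(box[3] / 2 + z_sep / 2, box[3] / 2 - z_sep / 2),
              each = n_per_leaflet)
    dz <- if (is.null(height_fun)) 0 else height_fun(x, y)
    coords[, , f] <- cbind(x, y, z0 + dz + stats::rnorm(np, 0, z_noise))
  }
  top <- topology(particle_id = seq_len(np) - 1L,
                  name = "PO4", group = "HEADGROUP",
                  molecule_id = seq_len(np) - 1L,
                  leaflet = rep(c("UPPER", "LOWER"), each = n_per_leaflet))
  trajectory(top, coords, seq_len(n_frames) - 1, box)
}
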