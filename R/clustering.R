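#' Per-TAG neighbor counts in one frame
#'
#' Counts, for each TAG molecule, the number of other TAG molecules whose
#' molecule-molecule minimum-image particle distance is at or below
#' `cutoff`.  The relation is symmetric by construction.
#'
#' @param traj a [trajectory()] with a TAG group.
#' @param frame_index 1-based frame index.
#' @param cutoff contact cutoff in nm (default 0.5).
#' @return named integer vector, one entry per TAG `molecule_id`.
#' @export
tag_neighbor_counts <- function(traj, frame_index, cutoff = 0.5) {
  dm <- tag_molecule_dist_matrix(traj, frame_index)
  out <- as.integer(rowSums(dm <= cutoff) - 1L)  # exclude self (diagonal 0)
  names(out) <- rownames(dm)
  out
}

# molecule-molecule minimum distance matrix for the TAG group
tag_molecule_dist_matrix <- function(traj, frame_index) {
  top <- traj$topology
  tag <- top$group == "TAG"
  if (!any(tag)) stop("topology has no TAG group")
  mols <- sort(unique(top$molecule_id[tag]))
  grp <- match(top$molecule_id[tag], mols) - 1L
  xyz <- frame_coords(traj, frame_index)[tag, , drop = FALSE]
  dm <- cpp_group_min_dist(xyz, grp, length(mols), traj$box[frame_index, ])
  dimnames(dm) <- list(mols, mols)
  dm
}

#' Clustered-fraction time series
#'
#' A TAG molecule counts as clustered when it has at least two other TAG
#' molecules within the contact cutoff; the clustered fraction is the
#' fraction of TAGs satisfying this rule, so monomeric and dimeric TAGs
#' contribute zero by construction.  Connected components of the neighbor
#' graph are computed alongside for cluster geometry (size and periodic
#' centroid of the largest cluster).
#'
#' @param traj a [trajectory()] with a TAG group.
#' @param cutoff contact cutoff in nm (default 0.5).
#' @param stride analysis stride in ns (default 1).
#' @param trap_center optional `(x, y)` nm; when given, the minimum-image
#'   distance from the largest-cluster centroid to this point is reported.
#' @return An object of class `cluster_series`: list with `times`,
#'   `neighbor_counts` (matrix samples x TAGs), `clustered_fraction`,
#'   `n_clusters`, `largest_cluster_size`, `largest_cluster_centroid`
#'   (matrix samples x 2), `centroid_dist_to_trap` (or `NA`),
#'   `component_labels` (matrix samples x TAGs).
#' @export
clustered_fraction_series <- function(traj, cutoff = 0.5, stride = 1,
                                      trap_center = NULL) {
  idx <- stride_frame_index(traj$times, stride)
  n_tag <- length(unique(traj$topology$molecule_id[
    traj$topology$group == "TAG"]))
  if (n_tag == 0L) stop("topology has no TAG group")
  ns <- length(idx)
  counts <- matrix(NA_integer_, ns, n_tag)
  labels <- matrix(NA_integer_, ns, n_tag)
  frac <- numeric(ns)
  ncl <- integer(ns)
  lsize <- integer(ns)
  centroid <- matrix(NA_real_, ns, 2L)
  dist_trap <- rep(NA_real_, ns)
  for (k in seq_len(ns)) {
    i <- idx[k]
    dm <- tag_molecule_dist_matrix(traj, i)
    counts[k, ] <- as.integer(rowSums(dm <= cutoff) - 1L)
    frac[k] <- mean(counts[k, ] >= 2L)
    cc <- components_from_dist(dm, cutoff)
    labels[k, ] <- cc$labels
    ncl[k] <- cc$n_components
    big <- which.max(cc$sizes)
    lsize[k] <- cc$sizes[big]
    members <- which(cc$labels == big)
    xy <- tag_molecule_centroids(traj, i)[members, , drop = FALSE]
    centroid[k, ] <- periodic_centroid(xy, traj$box[i, 1:2])
    if (!is.null(trap_center)) {
      d <- centroid[k, ] - trap_center
      L <- traj$box[i, 1:2]
      d <- d - L * round(d / L)
      dist_trap[k] <- sqrt(sum(d^2))
    }
  }
  structure(list(times = traj$times[idx], neighbor_counts = counts,
                 clustered_fraction = frac, n_clusters = ncl,
                 largest_cluster_size = lsize,
                 largest_cluster_centroid = centroid,
                 centroid_dist_to_trap = dist_trap,
                 component_labels = labels, cutoff = cutoff),
            class = "cluster_series")
}

#' @export
print.cluster_series <- function(x, ...) {
  n <- length(x$times)
  cat("cluster_series:", n, "samples,", ncol(x$neighbor_counts), "TAGs\n")
  cat("  clustered fraction: first", signif(x$clustered_fraction[1], 3),
      "final", signif(x$clustered_fraction[n], 3), "\n")
  cat("  final largest cluster size:", x$largest_cluster_size[n], "\n")
  invisible(x)
}

#' Connected components of the TAG neighbor graph in one frame
#'
#' Components of the graph whose edges join TAG molecules within `cutoff`.
#' The centroid of the largest component uses the periodic (circular-mean)
#' convention so clusters straddling the box boundary are handled.
#'
#' @inheritParams tag_neighbor_counts
#' @param trap_center optional `(x, y)` nm reference point.
#' @return list with `labels` (integer per TAG, by ascending molecule_id),
#'   `sizes`, `n_components`, `largest_size`, `largest_centroid` (x, y nm)
#'   and `centroid_dist_to_trap` (`NA` without a reference point).
#' @export
connected_components <- function(traj, frame_index, cutoff = 0.5,
                                 trap_center = NULL) {
  dm <- tag_molecule_dist_matrix(traj, frame_index)
  cc <- components_from_dist(dm, cutoff)
  big <- which.max(cc$sizes)
  members <- which(cc$labels == big)
  xy <- tag_molecule_centroids(traj, frame_index)[members, , drop = FALSE]
  cen <- periodic_centroid(xy, traj$box[frame_index, 1:2])
  dist_trap <- NA_real_
  if (!is.null(trap_center)) {
    d <- cen - trap_center
    L <- traj$box[frame_index, 1:2]
    d <- d - L * round(d / L)
    dist_trap <- sqrt(sum(d^2))
  }
  list(labels = cc$labels, sizes = cc$sizes,
       n_components = cc$n_components, largest_size = cc$sizes[big],
       largest_centroid = cen, centroid_dist_to_trap = dist_trap)
}

# igraph components on the thresholded distance matrix
components_from_dist <- function(dm, cutoff) {
  adj <- (dm <= cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cc <- igraph::components(g)
  list(labels = as.integer(cc$membership), sizes = as.integer(cc$csize),
       n_components = cc$no)
}

# in-plane centroid of each TAG molecule (circular mean over its particles)
tag_molecule_centroids <- function(traj, frame_index) {
  top <- traj$topology
  tag <- top$group == "TAG"
  mols <- sort(unique(top$molecule_id[tag]))
  xyz <- frame_coords(traj, frame_index)
  L <- traj$box[frame_index, 1:2]
  out <- matrix(NA_real_, length(mols), 2L)
  for (m in seq_along(mols)) {
    ids <- which(tag & top$molecule_id == mols[m])
    out[m, ] <- periodic_centroid(xyz[ids, 1:2, drop = FALSE], L)
  }
  out
}

#' Periodic centroid of points in an orthorhombic box
#'
#' Mean position computed per dimension through the circular-mean mapping
#' (each coordinate is mapped to an angle on `[0, 2*pi)`, averaged as a
#' unit vector, and mapped back), so point sets straddling the periodic
#' boundary average correctly.
#'
#' @param xy numeric matrix `n x k` of wrapped coordinates (nm).
#' @param box numeric length-`k` box lengths (nm).
#' @return numeric length-`k` centroid, wrapped into the box.
#' @export
periodic_centroid <- function(xy, box) {
  xy <- matrix(xy, ncol = length(box))
  out <- numeric(length(box))
  for (d in seq_along(box)) {
    theta <- xy[, d] / box[d] * 2 * pi
    ang <- atan2(mean(sin(theta)), mean(cos(theta)))
    out[d] <- (ang / (2 * pi) * box[d]) %% box[d]
  }
  out
}

#' Write a cluster series to CSV
#'
#' Columns: `time_ns,clustered_fraction,n_clusters,largest_cluster_size,`
#' `centroid_x,centroid_y,centroid_dist_to_trap`.
#'
#' @param series a [clustered_fraction_series()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_csv <- function(series, path) {
  df <- data.frame(
    time_ns = series$times,
    clustered_fraction = series$clustered_fraction,
    n_clusters = series$n_clusters,
    largest_cluster_size = series$largest_cluster_size,
    centroid_x = series$largest_cluster_centroid[, 1],
    centroid_y = series$largest_cluster_centroid[, 2],
    centroid_dist_to_trap = series$centroid_dist_to_trap
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
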