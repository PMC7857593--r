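#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between two points under the minimum-image convention.
#'
#' @param a,b numeric length-3 points (nm).
#' @param box numeric length-3 box lengths (nm), all positive.
#' @return distance in nm.
#' @export
#' @examples
#' min_image_distance(c(0.1, 0, 0), c(9.9, 0, 0), c(10, 10, 10)) # 0.2
min_image_distance <- function(a, b, box) {
  stopifnot(length(a) == 3L, length(b) == 3L, length(box) == 3L)
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- a - b
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

#' Minimum distance between two particle groups in a frame
#'
#' Minimum over all cross pairs of [min_image_distance()].  This is the
#' nearest-particle distance used to decide residue-TAG and TAG-TAG
#' contacts.
#'
#' @param traj a [trajectory()].
#' @param frame_index 1-based frame index.
#' @param ids_a,ids_b 0-based particle id vectors; non-empty and disjoint.
#' @return distance in nm.
#' @export
min_group_distance <- function(traj, frame_index, ids_a, ids_b) {
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop("both particle groups must be non-empty")
  }
  if (length(intersect(ids_a, ids_b)) > 0L) {
    stop("particle groups must be disjoint")
  }
  xyz <- frame_coords(traj, frame_index)
  d <- cpp_cross_min_dist(xyz[ids_a + 1L, , drop = FALSE],
                          xyz[ids_b + 1L, , drop = FALSE],
                          traj$box[frame_index, ])
  min(d)
}

#' Unwrap periodic coordinates into continuous in-plane paths
#'
#' Removes box-crossing jumps from the x/y coordinates of the selected
#' particles so that displacements can be measured.  Assumes every true
#' per-frame displacement is below half the box length in each dimension;
#' frames where the minimum-image step reaches L/2 (ambiguous crossing) are
#' flagged and a warning is logged.
#'
#' @param traj a [trajectory()].
#' @param ids 0-based particle ids (default: all TAG particles, or all
#'   particles when no TAG group exists).
#' @return list with `ids`, `times`, `paths` (array `length(ids) x 2 x
#'   n_frames` of unwrapped x/y, nm) and `flagged` (logical
#'   `n_frames x length(ids)`; `TRUE` marks a frame reached via an
#'   ambiguous jump).
#' @export
unwrap_coordinates <- function(traj, ids = NULL) {
  if (is.null(ids)) {
    ids <- topology_group_ids(traj$topology, "TAG")
    if (length(ids) == 0L) ids <- traj$topology$particle_id
  }
  nf <- n_frames(traj)
  ni <- length(ids)
  paths <- array(NA_real_, dim = c(ni, 2L, nf))
  flagged <- matrix(FALSE, nf, ni)
  xy <- traj$coords[ids + 1L, 1:2, , drop = FALSE]
  paths[, , 1] <- xy[, , 1]
  if (nf > 1L) {
    for (k in 2:nf) {
      L <- traj$box[k, 1:2]
      step <- xy[, , k] - xy[, , k - 1L]
      if (ni == 1L) step <- matrix(step, 1L, 2L)
      step <- step - rep(L, each = ni) * round(step / rep(L, each = ni))
      flagged[k, ] <- abs(step[, 1]) >= L[1] / 2 | abs(step[, 2]) >= L[2] / 2
      paths[, , k] <- paths[, , k - 1L] + step
    }
  }
  if (any(flagged)) {
    warning(sum(flagged), " particle-frame step(s) at or beyond half the ",
            "box; unwrapping is ambiguous for the flagged frames")
  }
  list(ids = ids, times = traj$times, paths = paths, flagged = flagged)
}

# wrap a coordinate matrix (n x k) into [0, L) per dimension
wrap_into_box <- function(xy, box) {
  for (d in seq_len(ncol(xy))) {
    xy[, d] <- xy[, d] - box[d] * floor(xy[, d] / box[d])
  }
  xy
}
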