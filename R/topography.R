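#' Assign head groups to leaflets
#'
#' Splits head-group particles into UPPER/LOWER leaflets by their z
#' position relative to the head-group median plane of the chosen frame.
#' Deterministic; particles exactly on the median go to LOWER.
#'
#' @param traj a [trajectory()].
#' @param frame_index 1-based frame index (default 1).
#' @param ids 0-based head-group particle ids (default: the HEADGROUP
#'   group).
#' @param min_separation minimum z spread (nm) below which the sheet is
#'   considered a single coplanar layer and an error is raised.
#' @return character vector (`"UPPER"`/`"LOWER"`) named by particle id.
#' @export
assign_leaflets <- function(traj, frame_index = 1L, ids = NULL,
                            min_separation = 0.5) {
  if (is.null(ids)) ids <- topology_group_ids(traj$topology, "HEADGROUP")
  if (length(ids) < 2L) stop("need at least two head-group particles")
  z <- frame_coords(traj, frame_index)[ids + 1L, 3L]
  if (diff(range(z)) < min_separation) {
    stop("head groups are coplanar within ", min_separation,
         " nm: cannot assign leaflets")
  }
  zmed <- stats::median(z)
  lab <- ifelse(z > zmed, "UPPER", "LOWER")
  names(lab) <- ids
  lab
}

#' Time-averaged leaflet height field
#'
#' Bins the head-group z positions of one leaflet onto an `nx x ny` grid
#' over the box, averages over all frames in the half-open time window,
#' applies periodic Gaussian smoothing by normalized convolution (which
#' also interpolates cells without data), and removes the spatial mean so
#' heights are relative to the leaflet's own mean plane.
#'
#' @param traj a [trajectory()].
#' @param leaflet `"UPPER"` or `"LOWER"`.
#' @param grid integer `(nx, ny)`, both at least 4 (default `c(64, 64)`).
#' @param smoothing_sigma Gaussian smoothing length in nm (default 1; 0
#'   disables smoothing, in which case empty cells are filled with the
#'   mean height and flagged).
#' @param window `(t0, t1)` ns, half-open; default: the full time range.
#' @param ids head-group particle ids; default: HEADGROUP particles whose
#'   topology leaflet matches, or, when the topology carries no leaflet
#'   labels, an automatic [assign_leaflets()] split of the first frame.
#' @return An object of class `height_field`: list with `leaflet`, `grid`,
#'   `spacing` (nm), `box` (Lx, Ly), `h` (nx x ny matrix, nm, zero spatial
#'   mean), `counts`, `interpolated` (logical matrix: cells with no
#'   observations), `window`.
#' @export
height_field <- function(traj, leaflet = c("UPPER", "LOWER"),
                         grid = c(64L, 64L), smoothing_sigma = 1,
                         window = NULL, ids = NULL) {
  leaflet <- match.arg(leaflet)
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  if (nx < 4L || ny < 4L) stop("grid must be at least 4 x 4")
  top <- traj$topology
  if (is.null(ids)) {
    hg <- topology_group_ids(top, "HEADGROUP")
    if (length(hg) == 0L) stop("topology has no HEADGROUP group")
    labs <- top$leaflet[hg + 1L]
    if (all(labs == "UNASSIGNED")) {
      labs <- assign_leaflets(traj, 1L, hg)
    }
    ids <- hg[labs == leaflet]
    if (length(ids) == 0L) stop("no head groups in the ", leaflet,
                                " leaflet")
  }
  if (is.null(window)) {
    window <- c(traj$times[1], traj$times[length(traj$times)] +
                  min(diff(c(traj$times, traj$times[length(traj$times)] + 1))))
  }
  in_win <- which(traj$times >= window[1] & traj$times < window[2])
  if (length(in_win) == 0L) stop("window contains no frames")
  Lx <- traj$box[in_win[1], 1]; Ly <- traj$box[in_win[1], 2]
  zsum <- matrix(0, nx, ny)
  counts <- matrix(0, nx, ny)
  for (f in in_win) {
    xyz <- frame_coords(traj, f)[ids + 1L, , drop = FALSE]
    ix <- pmin(floor(xyz[, 1] / Lx * nx) %% nx + 1L, nx)
    iy <- pmin(floor(xyz[, 2] / Ly * ny) %% ny + 1L, ny)
    for (p in seq_along(ix)) {
      zsum[ix[p], iy[p]] <- zsum[ix[p], iy[p]] + xyz[p, 3]
      counts[ix[p], iy[p]] <- counts[ix[p], iy[p]] + 1
    }
  }
  empty <- counts == 0
  if (mean(empty) > 0.5) {
    stop(sprintf(paste0("%.0f%% of grid cells received no head groups; ",
                        "use a coarser grid"), 100 * mean(empty)))
  }
  if (smoothing_sigma > 0) {
    w <- periodic_gauss_smooth(counts, smoothing_sigma / (Lx / nx),
                               smoothing_sigma / (Ly / ny))
    num <- periodic_gauss_smooth(zsum, smoothing_sigma / (Lx / nx),
                                 smoothing_sigma / (Ly / ny))
    h <- num / w
    h[w < 1e-12] <- mean(h[w >= 1e-12])
  } else {
    h <- zsum / pmax(counts, 1)
    h[empty] <- mean(h[!empty])
  }
  h <- h - mean(h)
  structure(list(leaflet = leaflet, grid = c(nx, ny),
                 spacing = c(Lx / nx, Ly / ny), box = c(Lx, Ly), h = h,
                 counts = counts, interpolated = empty, window = window),
            class = "height_field")
}

# periodic Gaussian smoothing via FFT; sigmas in grid cells
periodic_gauss_smooth <- function(M, sigma_x, sigma_y) {
  nx <- nrow(M); ny <- ncol(M)
  dx <- pmin(0:(nx - 1), nx - (0:(nx - 1)))
  dy <- pmin(0:(ny - 1), ny - (0:(ny - 1)))
  gx <- exp(-dx^2 / (2 * sigma_x^2))
  gy <- exp(-dy^2 / (2 * sigma_y^2))
  g <- outer(gx, gy)
  g <- g / sum(g)
  Re(stats::fft(stats::fft(M) * stats::fft(g), inverse = TRUE)) / (nx * ny)
}

#' Construct a height field directly from a matrix
#'
#' Convenience constructor for analytic test surfaces and external data.
#'
#' @param h numeric matrix of heights (nm); the spatial mean is removed.
#' @param box `(Lx, Ly)` nm.
#' @param leaflet leaflet label (default `"LOWER"`).
#' @return a `height_field`.
#' @export
height_field_from_matrix <- function(h, box, leaflet = "LOWER") {
  nx <- nrow(h); ny <- ncol(h)
  structure(list(leaflet = leaflet, grid = c(nx, ny),
                 spacing = c(box[1] / nx, box[2] / ny), box = box,
                 h = h - mean(h), counts = matrix(1, nx, ny),
                 interpolated = matrix(FALSE, nx, ny), window = c(NA, NA)),
            class = "height_field")
}

#' Mean curvature of a leaflet height field
#'
#' Computes the mean curvature H (nm^-1) of the height surface with
#' periodic finite differences.  `small_slope` uses
#' `H = -(hxx + hyy) / 2`; `full` uses the exact divergence form
#' `H = -div(grad h / sqrt(1 + |grad h|^2)) / 2`.  The sign is oriented so
#' that H is positive where the leaflet bulges toward the bilayer
#' midplane: for the LOWER leaflet an upward bump is positive, for the
#' UPPER leaflet the sign is flipped accordingly.
#'
#' @param field a [height_field()].
#' @param mode `"small_slope"` or `"full"`.
#' @return An object of class `curvature_map`: list with `H` (matrix,
#'   nm^-1), `leaflet`, `mode`,
#'   `sign_convention = "positive_toward_midplane"`.
#' @export
mean_curvature <- function(field, mode = c("small_slope", "full")) {
  mode <- match.arg(mode)
  h <- field$h
  dx <- field$spacing[1]; dy <- field$spacing[2]
  orient <- if (identical(field$leaflet, "UPPER")) -1 else 1
  if (mode == "small_slope") {
    H <- -(d2_periodic(h, 1L, dx) + d2_periodic(h, 2L, dy)) / 2
  } else {
    p <- d1_periodic(h, 1L, dx)
    q <- d1_periodic(h, 2L, dy)
    w <- sqrt(1 + p^2 + q^2)
    H <- -(d1_periodic(p / w, 1L, dx) + d1_periodic(q / w, 2L, dy)) / 2
  }
  structure(list(H = orient * H, leaflet = field$leaflet, mode = mode,
                 sign_convention = "positive_toward_midplane",
                 spacing = field$spacing),
            class = "curvature_map")
}

# periodic central first difference along margin 1 (rows ~ x) or 2
d1_periodic <- function(M, margin, spacing) {
  if (margin == 1L) {
    up <- rbind(M[-1, , drop = FALSE], M[1, , drop = FALSE])
    dn <- rbind(M[nrow(M), , drop = FALSE], M[-nrow(M), , drop = FALSE])
  } else {
    up <- cbind(M[, -1, drop = FALSE], M[, 1, drop = FALSE])
    dn <- cbind(M[, ncol(M), drop = FALSE], M[, -ncol(M), drop = FALSE])
  }
  (up - dn) / (2 * spacing)
}

# periodic central second difference
d2_periodic <- function(M, margin, spacing) {
  if (margin == 1L) {
    up <- rbind(M[-1, , drop = FALSE], M[1, , drop = FALSE])
    dn <- rbind(M[nrow(M), , drop = FALSE], M[-nrow(M), , drop = FALSE])
  } else {
    up <- cbind(M[, -1, drop = FALSE], M[, 1, drop = FALSE])
    dn <- cbind(M[, ncol(M), drop = FALSE], M[, -ncol(M), drop = FALSE])
  }
  (up - 2 * M + dn) / spacing^2
}

#' Write a curvature map (long-format CSV)
#'
#' Columns: `ix,iy,x_nm,y_nm,H_per_nm`; cell centers in nm.
#'
#' @param cmap a [mean_curvature()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curvature_csv <- function(cmap, path) {
  nx <- nrow(cmap$H); ny <- ncol(cmap$H)
  df <- data.frame(
    ix = rep(seq_len(nx), ny), iy = rep(seq_len(ny), each = nx),
    x_nm = (rep(seq_len(nx), ny) - 0.5) * cmap$spacing[1],
    y_nm = (rep(seq_len(ny), each = nx) - 0.5) * cmap$spacing[2],
    H_per_nm = as.vector(cmap$H)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
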