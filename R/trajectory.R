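#' Membrane trajectory container
#'
#' A trajectory is a time-ordered stack of frames over a fixed particle set.
#' Coordinates are stored in nm, times in ns, and boxes are orthorhombic
#' (`Lx, Ly, Lz` in nm, one row per frame).  All coordinates are kept
#' wrapped into the box.
#'
#' @param topology a [topology()] table.
#' @param coords numeric array `n_particles x 3 x n_frames` (nm).
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param box numeric matrix `n_frames x 3` of box lengths (nm), or a length-3
#'   vector recycled to all frames.
#' @param replicate_id integer replicate label (default 1).
#'
#' @return An object of class `tag_trajectory`: a list with elements
#'   `topology`, `coords`, `times`, `box`, `replicate_id`.
#' @export
trajectory <- function(topology, coords, times, box, replicate_id = 1L) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), each = length(times)),
                  nrow = length(times), ncol = 3L)
  }
  traj <- structure(
    list(topology = topology, coords = coords, times = as.numeric(times),
         box = box, replicate_id = as.integer(replicate_id)),
    class = "tag_trajectory"
  )
  validate_trajectory(traj)
  traj
}

#' Validate a trajectory
#'
#' Enforces the container invariants: strictly increasing frame times,
#' constant particle count equal to the topology size, positive box lengths,
#' and matching frame counts across `coords`, `times` and `box`.
#'
#' @param traj a [trajectory()].
#' @return `traj`, invisibly.
#' @export
validate_trajectory <- function(traj) {
  validate_topology(traj$topology)
  d <- dim(traj$coords)
  if (length(d) != 3L || d[2] != 3L) {
    stop("coords must be an n_particles x 3 x n_frames array")
  }
  if (d[1] != nrow(traj$topology)) {
    stop("coordinate count (", d[1], ") does not match topology particle count (",
         nrow(traj$topology), ")")
  }
  if (d[3] != length(traj$times) || nrow(traj$box) != length(traj$times)) {
    stop("frame count mismatch between coords, times and box")
  }
  if (length(traj$times) > 1L && any(diff(traj$times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (any(traj$box <= 0)) stop("box lengths must be positive")
  invisible(traj)
}

#' @export
print.tag_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("tag_trajectory:", d[1], "particles,", d[3], "frames\n")
  cat("  time range:", x$times[1], "-", x$times[length(x$times)], "ns\n")
  cat("  box (first frame):", paste(signif(x$box[1, ], 4), collapse = " x "),
      "nm\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$topology$group)),
                                 table(x$topology$group)), collapse = ", "),
      "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
n_particles <- function(traj) dim(traj$coords)[1]

# coordinates of frame i as an n x 3 matrix
frame_coords <- function(traj, i) traj$coords[, , i, drop = FALSE][, , 1]

#' Read a trajectory file
#'
#' Supported dialects:
#' \describe{
#'   \item{`gro`}{Multi-frame GROMACS GRO.  Fixed columns, coordinates in nm;
#'     a `t=` tag on the title line is read as the frame time in ps and
#'     converted to ns (GROMACS writes times in ps).  Only orthorhombic box
#'     lines (3 values) are accepted.}
#'   \item{`xyz`}{Extended XYZ whose comment line carries
#'     `time_ns=<t> box_nm=<Lx,Ly,Lz>`; coordinates in nm.}
#'   \item{`csv`}{Long format with header `frame,time_ns,particle_id,x,y,z`,
#'     coordinates in nm.}
#' }
#'
#' @param path file path.
#' @param format one of `"gro"`, `"xyz"`, `"csv"`; default guesses from the
#'   file extension.
#' @param topology optional [topology()] to attach; when absent a minimal
#'   all-`OTHER` topology is built from the first frame's particle names.
#' @param replicate_id integer replicate label.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("guess", "gro", "xyz", "csv"),
                            topology = NULL, replicate_id = 1L) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     gro = "gro", xyz = "xyz", csv = "csv",
                     stop("cannot guess trajectory format from extension: ",
                          path))
  }
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  parsed <- switch(format,
                   gro = read_gro_frames(path),
                   xyz = read_xyz_frames(path),
                   csv = read_csv_frames(path))
  nf <- length(parsed$times)
  np <- nrow(parsed$coords[[1]])
  for (i in seq_len(nf)) {
    if (nrow(parsed$coords[[i]]) != np) {
      stop("inconsistent particle count across frames: frame ", i, " has ",
           nrow(parsed$coords[[i]]), ", expected ", np)
    }
  }
  coords <- array(0, dim = c(np, 3L, nf))
  for (i in seq_len(nf)) coords[, , i] <- parsed$coords[[i]]
  if (is.null(topology)) {
    topology <- topology(
      particle_id = seq_len(np) - 1L,
      name = parsed$names %||% rep("X", np),
      group = "OTHER"
    )
  }
  trajectory(topology, coords, parsed$times, do.call(rbind, parsed$box),
             replicate_id = replicate_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_gro_frames <- function(path) {
  lines <- readLines(path)
  times <- numeric(); boxes <- list(); coords <- list(); nms <- NULL
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) {
      stop("GRO parse error at line ", i + 1L, ": expected atom count")
    }
    if (i + 1L + natoms + 1L > length(lines)) {
      stop("GRO parse error at line ", i + 1L, ": truncated frame")
    }
    # 't=' tag (GROMACS convention, ps) -> ns
    t_ns <- {
      m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
      if (length(m) == 1L) as.numeric(sub("t=\\s*", "", m)) / 1000 else k
    }
    atoms <- lines[(i + 2L):(i + 1L + natoms)]
    xyz <- matrix(NA_real_, natoms, 3L)
    frame_names <- character(natoms)
    for (j in seq_len(natoms)) {
      ln <- atoms[j]
      if (nchar(ln) < 44L) {
        stop("GRO parse error at line ", i + 1L + j, ": record too short")
      }
      frame_names[j] <- trimws(substr(ln, 11L, 15L))
      xyz[j, ] <- suppressWarnings(as.numeric(c(
        substr(ln, 21L, 28L), substr(ln, 29L, 36L), substr(ln, 37L, 44L))))
      if (anyNA(xyz[j, ])) {
        stop("GRO parse error at line ", i + 1L + j, ": bad coordinate field")
      }
    }
    box_fields <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]]))
    if (anyNA(box_fields) || length(box_fields) < 3L) {
      stop("GRO parse error at line ", i + 2L + natoms, ": bad box line")
    }
    if (length(box_fields) > 3L && any(box_fields[4:length(box_fields)] != 0)) {
      stop("triclinic GRO box not supported (off-diagonal box elements ",
           "present at line ", i + 2L + natoms, ")")
    }
    k <- k + 1L
    times[k] <- t_ns
    boxes[[k]] <- box_fields[1:3]
    coords[[k]] <- xyz
    if (is.null(nms)) nms <- frame_names
    i <- i + 3L + natoms
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (k == 0L) stop("GRO parse error: no frames found in ", path)
  list(times = times, box = boxes, coords = coords, names = nms)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  times <- numeric(); boxes <- list(); coords <- list(); nms <- NULL
  i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms)) {
      stop("XYZ parse error at line ", i, ": expected atom count")
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexpr("time_ns=\\s*[-0-9.eE+]+", comment))
    bm <- regmatches(comment,
                     regexpr("box_nm=\\s*[-0-9.eE+]+,[-0-9.eE+]+,[-0-9.eE+]+",
                             comment))
    if (length(tm) != 1L || length(bm) != 1L) {
      stop("XYZ parse error at line ", i + 1L,
           ": comment must carry time_ns=<t> box_nm=<Lx,Ly,Lz>")
    }
    t_ns <- as.numeric(sub("time_ns=\\s*", "", tm))
    box <- as.numeric(strsplit(sub("box_nm=\\s*", "", bm), ",")[[1]])
    if (i + 1L + natoms > length(lines)) {
      stop("XYZ parse error at line ", i, ": truncated frame")
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    xyz <- matrix(NA_real_, natoms, 3L)
    frame_names <- character(natoms)
    for (j in seq_len(natoms)) {
      if (length(rows[[j]]) < 4L) {
        stop("XYZ parse error at line ", i + 1L + j, ": expected name x y z")
      }
      frame_names[j] <- rows[[j]][1]
      xyz[j, ] <- suppressWarnings(as.numeric(rows[[j]][2:4]))
      if (anyNA(xyz[j, ])) {
        stop("XYZ parse error at line ", i + 1L + j, ": bad coordinate")
      }
    }
    k <- k + 1L
    times[k] <- t_ns; boxes[[k]] <- box; coords[[k]] <- xyz
    if (is.null(nms)) nms <- frame_names
    i <- i + 2L + natoms
  }
  if (k == 0L) stop("XYZ parse error: no frames found in ", path)
  list(times = times, box = boxes, coords = coords, names = nms)
}

read_csv_frames <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "time_ns", "particle_id", "x", "y", "z")
  if (!all(req %in% names(df))) {
    stop("CSV trajectory must have header ", paste(req, collapse = ","))
  }
  frames <- sort(unique(df$frame))
  times <- numeric(length(frames)); coords <- list(); boxes <- list()
  has_box <- all(c("box_x", "box_y", "box_z") %in% names(df))
  for (k in seq_along(frames)) {
    sub <- df[df$frame == frames[k], ]
    sub <- sub[order(sub$particle_id), ]
    times[k] <- sub$time_ns[1]
    coords[[k]] <- cbind(sub$x, sub$y, sub$z)
    boxes[[k]] <- if (has_box) c(sub$box_x[1], sub$box_y[1], sub$box_z[1])
      else c(max(df$x) - min(df$x) + 1, max(df$y) - min(df$y) + 1,
             max(df$z) - min(df$z) + 1)
  }
  if (!has_box) {
    warning("CSV trajectory has no box_x/box_y/box_z columns; ",
            "box inferred from coordinate extent")
  }
  list(times = times, box = boxes, coords = coords, names = NULL)
}

#' Write a trajectory file
#'
#' Inverse of [read_trajectory()]; round trips preserve coordinates to the
#' format precision (3 decimals for GRO, 6 for XYZ/CSV).  The CSV dialect
#' adds `box_x,box_y,box_z` columns so the box survives the round trip.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param format one of `"gro"`, `"xyz"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("gro", "xyz", "csv")) {
  format <- match.arg(format)
  validate_trajectory(traj)
  if (n_frames(traj) == 0L) stop("cannot write a trajectory with no frames")
  con <- file(path, "w")
  on.exit(close(con))
  np <- n_particles(traj)
  nm <- traj$topology$name
  if (format == "gro") {
    for (i in seq_len(n_frames(traj))) {
      xyz <- frame_coords(traj, i)
      writeLines(sprintf("tagtraj frame t= %.4f", traj$times[i] * 1000), con)
      writeLines(sprintf("%5d", np), con)
      resid <- (traj$topology$molecule_id %% 100000L)
      resid[is.na(resid)] <- 0L
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         (resid + 1L) %% 100000L,
                         substr(traj$topology$group, 1L, 5L),
                         substr(nm, 1L, 5L),
                         (traj$topology$particle_id + 1L) %% 100000L,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[i, 1], traj$box[i, 2],
                         traj$box[i, 3]), con)
    }
  } else if (format == "xyz") {
    for (i in seq_len(n_frames(traj))) {
      xyz <- frame_coords(traj, i)
      writeLines(sprintf("%d", np), con)
      writeLines(sprintf("time_ns=%.6f box_nm=%.6f,%.6f,%.6f", traj$times[i],
                         traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]), con)
      writeLines(sprintf("%-6s %12.6f %12.6f %12.6f", nm, xyz[, 1], xyz[, 2],
                         xyz[, 3]), con)
    }
  } else {
    writeLines("frame,time_ns,particle_id,x,y,z,box_x,box_y,box_z", con)
    for (i in seq_len(n_frames(traj))) {
      xyz <- frame_coords(traj, i)
      writeLines(sprintf("%d,%.6f,%d,%.6f,%.6f,%.6f,%.6f,%.6f,%.6f",
                         i - 1L, traj$times[i], traj$topology$particle_id,
                         xyz[, 1], xyz[, 2], xyz[, 3],
                         traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]), con)
    }
  }
  invisible(path)
}
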