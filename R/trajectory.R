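# Trajectory containers and trajectory I/O (multi-frame GRO, CHARMM DCD).
# Coordinates are stored as an N x 3 x F array in Angstrom, with per-frame
# orthorhombic boxes and times (ps).

#' Construct a single coordinate frame
#'
#' @param coords N x 3 matrix of coordinates (A).
#' @param box Length-3 orthorhombic box (A).
#' @param time Timestamp (ps).
#' @export
traj_frame <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  box <- check_box(box)
  structure(list(coords = coords, box = box, time = as.numeric(time)),
            class = "traj_frame")
}

#' Construct a trajectory
#'
#' @param topology A [bead_topology()] with N beads.
#' @param coords N x 3 x F array (A), or a list of N x 3 matrices.
#' @param box F x 3 matrix (A) or length-3 vector recycled to all frames.
#' @param times Length-F times (ps), strictly increasing.
#' @export
trajectory <- function(topology, coords, box, times = NULL) {
  if (is.list(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an N x 3 x F array")
  nf <- dim(coords)[3]
  if (dim(coords)[1] != nrow(topology))
    stop(sprintf("bead count mismatch: topology has %d beads, coordinates have %d",
                 nrow(topology), dim(coords)[1]))
  if (is.null(dim(box))) box <- matrix(rep(as.numeric(box), length.out = 3 * nf),
                                       nf, 3, byrow = TRUE)
  times <- times %||% (seq_len(nf) - 1)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords, box = as.matrix(box),
                 times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d beads x %d frames, t = %.4g..%.4g ps, box %s A\n",
              dim(x$coords)[1], n_frames(x), x$times[1],
              x$times[n_frames(x)],
              paste(sprintf("%.4g", x$box[1, ]), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @export
get_frame <- function(traj, i) {
  traj_frame(traj$coords[, , i], traj$box[i, ], traj$times[i])
}

#' Restrict a trajectory to a subset of frames
#' @param traj A [trajectory()].
#' @param idx Frame indices (1-based, increasing).
#' @export
subset_frames <- function(traj, idx) {
  trajectory(traj$topology, traj$coords[, , idx, drop = FALSE],
             traj$box[idx, , drop = FALSE], traj$times[idx])
}

# ---- multi-frame GRO ------------------------------------------------------

read_traj_gro <- function(path, topology, stride, callback) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(0)
  pos <- 1L; iframe <- 0L
  while (pos + 2L <= length(lines)) {
    b <- tryCatch(parse_gro_block(lines[pos:length(lines)]),
                  error = function(e) NULL)
    if (is.null(b)) {
      warning("truncated GRO trajectory: stopping after ", length(times), " frames")
      break
    }
    if (nrow(b$coords) != nrow(topology))
      stop(sprintf("bead count mismatch: expected %d beads, found %d",
                   nrow(topology), nrow(b$coords)))
    iframe <- iframe + 1L
    if ((iframe - 1L) %% stride == 0L) {
      if (is.null(callback)) {
        frames[[length(frames) + 1L]] <- b$coords
        boxes[[length(boxes) + 1L]] <- b$box
        times <- c(times, b$time)
      } else {
        callback(traj_frame(b$coords, b$box, b$time))
      }
    }
    pos <- pos + b$nlines
  }
  if (!is.null(callback)) return(invisible(NULL))
  list(frames = frames, boxes = boxes, times = times)
}

# ---- DCD (CHARMM-style binary, native endianness) -------------------------

write_record <- function(con, payload_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4)
  payload_writer()
  writeBin(as.integer(nbytes), con, size = 4)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Binary DCD with a unit-cell record per frame (orthorhombic). Coordinates
#' in Angstrom, single precision.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); nat <- dim(traj$coords)[1]
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  write_record(con, function() {
    writeChar("CORD", con, 4, eos = NULL)
    ic <- integer(20)
    ic[1] <- nf; ic[2] <- 1L; ic[3] <- 1L; ic[4] <- nf
    writeBin(ic[1:9], con, size = 4)
    writeBin(as.numeric(dt), con, size = 4)     # delta, float32
    writeBin(c(1L, integer(8), 24L), con, size = 4)  # cell flag; version
  }, 84)
  title <- sprintf("%-80s", "memtraj trajectory")
  write_record(con, function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, 80, eos = NULL)
  }, 84)
  write_record(con, function() writeBin(as.integer(nat), con, size = 4), 4)
  for (i in seq_len(nf)) {
    b <- traj$box[i, ]
    write_record(con, function() {
      writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), con, size = 8)
    }, 48)
    for (k in 1:3)
      write_record(con, function() {
        writeBin(as.numeric(traj$coords[, k, i]), con, size = 4)
      }, 4 * nat)
  }
  invisible(path)
}

read_record <- function(con) {
  n <- readBin(con, "integer", 1, size = 4)
  if (length(n) == 0) return(NULL)
  payload <- readBin(con, "raw", n)
  tail <- readBin(con, "integer", 1, size = 4)
  if (length(payload) < n || length(tail) == 0 || tail != n) return(NULL)
  payload
}

read_traj_dcd <- function(path, topology, stride, callback) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_record(con)
  if (is.null(hdr) || rawToChar(hdr[1:4]) != "CORD")
    stop("malformed DCD file: bad header")
  ic <- readBin(hdr[5:84], "integer", 20, size = 4)
  has_cell <- ic[11] != 0
  invisible(read_record(con))            # title block
  natrec <- read_record(con)
  nat <- readBin(natrec, "integer", 1, size = 4)
  if (nat != nrow(topology))
    stop(sprintf("bead count mismatch: expected %d beads, found %d",
                 nrow(topology), nat))
  frames <- list(); boxes <- list(); times <- numeric(0)
  dt <- readBin(hdr[41:44], "numeric", 1, size = 4)
  if (!is.finite(dt) || dt <= 0) dt <- 1
  iframe <- 0L
  repeat {
    box <- c(0, 0, 0)
    if (has_cell) {
      cellrec <- read_record(con)
      if (is.null(cellrec)) break
      cell <- readBin(cellrec, "numeric", 6, size = 8)
      box <- cell[c(1, 3, 6)]
    }
    xr <- read_record(con); yr <- read_record(con); zr <- read_record(con)
    if (is.null(xr) || is.null(yr) || is.null(zr)) {
      if (!is.null(xr) || !is.null(yr))
        warning("truncated DCD: stopping after ", length(times), " frames")
      break
    }
    co <- cbind(readBin(xr, "numeric", nat, size = 4),
                readBin(yr, "numeric", nat, size = 4),
                readBin(zr, "numeric", nat, size = 4))
    iframe <- iframe + 1L
    if ((iframe - 1L) %% stride == 0L) {
      tm <- (iframe - 1L) * dt
      if (is.null(callback)) {
        frames[[length(frames) + 1L]] <- co
        boxes[[length(boxes) + 1L]] <- box
        times <- c(times, tm)
      } else callback(traj_frame(co, box, tm))
    }
  }
  if (!is.null(callback)) return(invisible(NULL))
  list(frames = frames, boxes = boxes, times = times)
}

#' Read a trajectory file (multi-frame GRO or DCD)
#'
#' Frames are parsed strictly in file order. Supplying `callback` streams
#' frames one at a time (each as a [traj_frame()]) without accumulating the
#' trajectory in memory; otherwise a [trajectory()] is returned. A truncated
#' final frame yields the frames read so far plus a warning.
#'
#' @param path Path to a `.gro` (multi-frame) or `.dcd` file.
#' @param topology A [bead_topology()]; bead count must match the file.
#' @param stride Keep every `stride`-th frame (default 1).
#' @param format `"auto"` (by extension), `"gro"` or `"dcd"`.
#' @param callback Optional `function(frame)` for streaming access.
#' @export
read_trajectory <- function(path, topology, stride = 1L,
                            format = c("auto", "gro", "dcd"),
                            callback = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "gro"
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  res <- if (format == "gro") read_traj_gro(path, topology, stride, callback)
         else read_traj_dcd(path, topology, stride, callback)
  if (is.null(res)) return(invisible(NULL))
  if (!length(res$frames)) stop("no frames read from ", path)
  trajectory(topology, res$frames, do.call(rbind, res$boxes), res$times)
}

#' Write a trajectory (multi-frame GRO or DCD)
#'
#' @param traj A [trajectory()].
#' @param path Output path; format chosen by extension unless given.
#' @param format `"auto"`, `"gro"` or `"dcd"`.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "gro", "dcd")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "gro"
  if (format == "gro") write_gro(traj$topology, traj, path) else write_dcd(traj, path)
}
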