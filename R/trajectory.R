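#' @section Trajectory:
#' A `pg_trajectory` couples a topology with per-frame coordinates stored
#' as an `n_atoms x 3 x n_frames` array in Angstrom, plus optional frame
#' times in ns. Frames and atoms are 0-based in all public interfaces.
#' @name poregate-trajectory
NULL

new_trajectory <- function(topology, coords, frame_times = NULL) {
  stopifnot(inherits(topology, "pg_topology"))
  d <- dim(coords)
  if (length(d) != 3L || d[2L] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (d[1L] != topology$n_atoms)
    stop(sprintf("coordinate frames have %d atoms but topology has %d",
                 d[1L], topology$n_atoms))
  if (!all(is.finite(coords))) stop("coordinates contain non-finite values")
  n_frames <- d[3L]
  if (is.null(frame_times)) frame_times <- seq_len(n_frames) - 1
  structure(list(topology = topology, coords = coords,
                 n_frames = n_frames, frame_times = as.numeric(frame_times)),
            class = "pg_trajectory")
}

#' @export
print.pg_trajectory <- function(x, ...) {
  cat(sprintf("<pg_trajectory> %d frames x %d atoms\n",
              x$n_frames, x$topology$n_atoms))
  invisible(x)
}

# 0-based frame f of a trajectory as an n x 3 matrix.
frame_coords <- function(traj, frame) {
  m <- traj$coords[, , frame + 1L, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Analysis frame window
#'
#' Half-open 0-based frame range `[start, end)` with a stride, the unit
#' in which every analysis states its extent (the production analyses of
#' channel trajectories conventionally discard an initial equilibration
#' span, e.g. the first fifth of a 1 us run).
#'
#' @param start first frame (0-based, inclusive).
#' @param end one past the last frame; `NULL` means the trajectory end.
#' @param stride frame stride, >= 1.
#' @return a `pg_window`.
#' @export
frame_window <- function(start = 0L, end = NULL, stride = 1L) {
  start <- as.integer(start); stride <- as.integer(stride)
  if (!is.null(end)) end <- as.integer(end)
  if (start < 0L) stop("window start must be >= 0")
  if (stride < 1L) stop("window stride must be >= 1")
  if (!is.null(end) && end <= start) stop("window end must exceed start")
  structure(list(start = start, end = end, stride = stride),
            class = "pg_window")
}

# Resolve a window against a trajectory -> 0-based frame indices.
window_frames <- function(traj, window = NULL) {
  if (is.null(window)) window <- frame_window()
  end <- if (is.null(window$end)) traj$n_frames else window$end
  if (end > traj$n_frames)
    stop(sprintf("window end %d exceeds trajectory length %d",
                 end, traj$n_frames))
  if (window$start >= end) stop("window start beyond trajectory end")
  seq.int(window$start, end - 1L, by = window$stride)
}

#' Read a trajectory
#'
#' Reads per-frame coordinates for an existing topology from a DCD file,
#' a multi-model PDB, or an XTC file. Output coordinates are always in
#' Angstrom (XTC's nm are converted). The XTC route shells out to the
#' system `python` with MDAnalysis to transcode to DCD, since no native R
#' decoder of the xdrfile compressed-coordinate codec exists.
#'
#' @param topology a `pg_topology` the frames must match.
#' @param path trajectory file.
#' @param format `"dcd"`, `"pdb"` (multi-model) or `"xtc"`; default
#'   guessed from the file extension.
#' @param dt_ns time between stored frames in ns used to populate
#'   `frame_times` (default 0.1, i.e. one frame per 100 ps).
#' @return a `pg_trajectory`.
#' @export
read_trajectory <- function(topology, path, format = NULL, dt_ns = 0.1) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("dcd", "pdb", "xtc"))
  coords <- switch(format,
    dcd = read_dcd_coords(path),
    pdb = read_multimodel_pdb_coords(topology, path),
    xtc = read_xtc_coords(path)
  )
  if (dim(coords)[1L] != topology$n_atoms)
    stop(sprintf("trajectory frames have %d atoms but topology has %d",
                 dim(coords)[1L], topology$n_atoms))
  new_trajectory(topology, coords,
                 frame_times = (seq_len(dim(coords)[3L]) - 1) * dt_ns)
}

## ---- DCD (CHARMM/NAMD binary) ----

read_dcd_coords <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  m <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (!identical(m, 84L)) {
    endian <- "big"
    seek(con, 0L)
    m <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (!identical(m, 84L)) stop("not a DCD file (bad header record): ", path)
  }
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a coordinate DCD file: ", path)
  icntrl <- readBin(con, "integer", 20L, size = 4L, endian = endian)
  readBin(con, "integer", 1L, size = 4L, endian = endian)  # trailing marker
  has_cell <- icntrl[11L] == 1L
  ntitle_len <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  readBin(con, "raw", ntitle_len)
  readBin(con, "integer", 1L, size = 4L, endian = endian)
  readBin(con, "integer", 1L, size = 4L, endian = endian)  # natom record
  natoms <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  readBin(con, "integer", 1L, size = 4L, endian = endian)
  frames <- list()
  repeat {
    frame <- tryCatch(
      read_dcd_frame(con, natoms, has_cell, endian),
      truncated_dcd = function(e) NULL
    )
    if (is.null(frame)) break
    frames[[length(frames) + 1L]] <- frame
  }
  if (!length(frames)) stop("DCD file contains no complete frame: ", path)
  array(unlist(frames, use.names = FALSE), dim = c(natoms, 3L, length(frames)))
}

read_dcd_frame <- function(con, natoms, has_cell, endian) {
  truncated <- function() {
    cond <- structure(class = c("truncated_dcd", "condition"),
                      list(message = "truncated frame", call = NULL))
    stop(cond)
  }
  read_record <- function(what, n, size) {
    len <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (length(len) == 0L) truncated()
    dat <- readBin(con, what, n, size = size, endian = endian)
    if (length(dat) < n) truncated()
    tail <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (length(tail) == 0L) truncated()
    dat
  }
  if (has_cell) read_record("double", 6L, 8L)
  x <- read_record("double", natoms, 4L)
  y <- read_record("double", natoms, 4L)
  z <- read_record("double", natoms, 4L)
  cbind(x, y, z)
}

#' Write a trajectory to a DCD file
#'
#' CHARMM-style DCD with 4-byte floats, no unit cell block.
#'
#' @param traj a `pg_trajectory`.
#' @param path output path.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  icntrl <- integer(20L)
  icntrl[1L] <- traj$n_frames
  icntrl[2L] <- 1L
  icntrl[3L] <- 1L
  icntrl[20L] <- 24L
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wint(icntrl)
  wint(84L)
  title <- sprintf("%-80s", "Created by poregate")
  wint(4L + 80L)
  wint(1L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  wint(4L + 80L)
  wint(4L); wint(traj$topology$n_atoms); wint(4L)
  nb <- 4L * traj$topology$n_atoms
  for (f in seq_len(traj$n_frames)) {
    for (k in 1:3) {
      wint(nb)
      writeBin(as.numeric(traj$coords[, k, f]), con, size = 4L,
               endian = "little")
      wint(nb)
    }
  }
  invisible(path)
}

## ---- multi-model PDB ----

read_multimodel_pdb_coords <- function(topology, path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) {
    parsed <- parse_pdb_atom_lines(lines, first_model_only = TRUE)
    if (!nrow(parsed$atoms)) stop("no atoms in trajectory PDB: ", path)
    return(array(as.matrix(parsed$atoms[, c("x", "y", "z")]),
                 dim = c(nrow(parsed$atoms), 3L, 1L)))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) < length(model_starts))
    stop(sprintf("truncated multi-model PDB: last complete frame index %d",
                 length(model_ends) - 1L))
  frames <- lapply(seq_along(model_starts), function(i) {
    blk <- lines[(model_starts[i] + 1L):(model_ends[i] - 1L)]
    p <- parse_pdb_atom_lines(blk, first_model_only = FALSE)
    as.matrix(p$atoms[, c("x", "y", "z")])
  })
  n <- vapply(frames, nrow, 1L)
  if (length(unique(n)) != 1L)
    stop("MODEL blocks have differing atom counts")
  array(unlist(frames, use.names = FALSE), dim = c(n[1L], 3L, length(frames)))
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL block per frame; coordinate precision is the PDB format's
#' 0.001 Angstrom.
#'
#' @param traj a `pg_trajectory`.
#' @param path output path.
#' @param frames optional 0-based frame indices (default all).
#' @export
write_multimodel_pdb <- function(traj, path, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(traj$n_frames) - 1L
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_frame_lines(traj$topology, frame_coords(traj, frames[i])),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- XTC via python/MDAnalysis bridge ----

read_xtc_coords <- function(path) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "")
    stop("XTC support requires a system python with MDAnalysis on PATH")
  tmp <- tempfile(fileext = ".dcd")
  script <- paste(
    "import sys",
    "import MDAnalysis as mda",
    "xtc, dcd = sys.argv[1], sys.argv[2]",
    "r = mda.coordinates.XTC.XTCReader(xtc)",
    "u = mda.Universe.empty(r.n_atoms, trajectory=True)",
    "u.load_new(xtc)",
    "with mda.Writer(dcd, u.atoms.n_atoms) as w:",
    "    for ts in u.trajectory:",
    "        w.write(u.atoms)",
    sep = "\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2(py, c(sf, shQuote(path), shQuote(tmp)),
                    stdout = FALSE, stderr = FALSE)
  unlink(sf)
  if (status != 0L || !file.exists(tmp))
    stop("XTC -> DCD conversion via MDAnalysis failed for: ", path)
  on.exit(unlink(tmp), add = TRUE)
  read_dcd_coords(tmp)  # MDAnalysis writes DCD in Angstrom
}
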