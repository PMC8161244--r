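# Trajectory reading/writing.
#
# Two coordinate formats are supported: CHARMM/NAMD-style binary DCD and
# multi-model PDB.  XTC is not supported (its XDR 3dfcoord compression has no
# reader in this R stack); use DCD.

#' Write a DCD coordinate trajectory
#'
#' Writes a CHARMM-format DCD (no unit cell, single-precision coordinates in
#' Angstrom).  Mainly used by the synthetic-trajectory generator and for
#' round-trip tests.
#'
#' @param coords numeric array of shape (n_atoms, 3, n_frames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  natom <- dim(coords)[1L]
  nframe <- dim(coords)[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header record: "CORD" + 20 control ints (delta stored as a float)
  wi(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wi(c(nframe, 0L, 1L, nframe, 0L, 0L, 0L, 0L, 0L))       # icntrl 1..9
  writeBin(1, con, size = 4L, endian = "little")          # icntrl 10: delta
  wi(c(0L, rep(0L, 8L), 24L))                             # icntrl 11..20
  wi(84L)
  title <- formatC("Synthetic trajectory written by rednmf", width = -80L)
  wi(4L + 80L)
  wi(1L)
  writeChar(substr(title, 1L, 80L), con, nchars = 80L, eos = NULL)
  wi(4L + 80L)
  wi(4L); wi(natom); wi(4L)
  for (f in seq_len(nframe)) {
    for (d in 1:3) {
      wi(4L * natom)
      writeBin(as.numeric(coords[, d, f]), con, size = 4L, endian = "little")
      wi(4L * natom)
    }
  }
  invisible(path)
}

read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = endian)
  m <- ri(1L)
  if (m != 84L) {
    endian <- "big"
    seek(con, 0L)
    m <- ri(1L)
    if (m != 84L) stop("not a DCD file: ", path, call. = FALSE)
  }
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD: ", path, call. = FALSE)
  icntrl_1_9 <- ri(9L)
  readBin(con, "numeric", n = 1L, size = 4L, endian = endian)  # delta
  icntrl_11_20 <- ri(10L)
  ri(1L)                                   # closing marker
  has_cell <- icntrl_11_20[1L] == 1L
  tl <- ri(1L)
  ri(1L)                                   # ntitle
  readChar(con, tl - 4L, useBytes = TRUE)
  ri(1L)
  ri(1L); natom <- ri(1L); ri(1L)
  frames <- list()
  repeat {
    if (has_cell) {
      mk <- ri(1L)
      if (length(mk) == 0L) break
      readBin(con, "numeric", n = 6L, size = 8L, endian = endian)
      ri(1L)
    }
    mk <- ri(1L)
    if (length(mk) == 0L) break
    xyz <- matrix(0, natom, 3L)
    for (d in 1:3) {
      if (d > 1L) ri(1L)
      xyz[, d] <- readBin(con, "numeric", n = natom, size = 4L, endian = endian)
      ri(1L)
    }
    frames[[length(frames) + 1L]] <- xyz
  }
  array(unlist(frames), dim = c(natom, 3L, length(frames)))
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1L, 6L))
  is_atom <- rec %in% c("ATOM", "HETATM")
  model_id <- cumsum(rec == "MODEL")
  if (max(model_id) == 0L) model_id <- model_id + 1L
  model_id <- model_id[is_atom]
  lines <- lines[is_atom]
  parse_xyz <- function(l) cbind(
    as.numeric(substr(l, 31L, 38L)),
    as.numeric(substr(l, 39L, 46L)),
    as.numeric(substr(l, 47L, 54L)))
  models <- split(lines, model_id)
  natom <- length(models[[1L]])
  arr <- array(0, dim = c(natom, 3L, length(models)))
  for (i in seq_along(models)) {
    if (length(models[[i]]) != natom)
      stop("inconsistent atom counts across models in ", path, call. = FALSE)
    arr[, , i] <- parse_xyz(models[[i]])
  }
  arr
}

#' Read trajectory frames
#'
#' Reads a DCD or multi-model PDB coordinate file against a topology, keeping
#' every `stride`-th frame.  Returned frames are re-indexed 0, 1, 2, ... and
#' time stamps are `frame_index * frame_interval_ns`.
#'
#' @param topology a `red_topology` from [load_topology()].
#' @param traj_path path to a `.dcd` or (multi-model) `.pdb` file.
#' @param stride keep every `stride`-th frame (default 1).
#' @param frame_interval_ns time between stored frames in ns, used only to
#'   stamp `time_ns`; default `NA` leaves times unset.
#' @return an object of class `red_traj`: list with `coords`
#'   (n_atoms x 3 x n_frames array), `frame_index` (0-based), `time_ns`,
#'   `n_frames`.
#' @export
read_frames <- function(topology, traj_path, stride = 1L, frame_interval_ns = NA) {
  stopifnot(inherits(topology, "red_topology"), stride >= 1L)
  ext <- tolower(tools::file_ext(traj_path))
  coords <- switch(ext,
    dcd = read_dcd(traj_path),
    pdb = read_pdb_models(traj_path),
    xtc = stop("XTC trajectories are not supported; convert to DCD", call. = FALSE),
    stop("unknown trajectory format: .", ext, call. = FALSE))
  if (dim(coords)[1L] != nrow(topology$atoms))
    stop("topology mismatch: trajectory has ", dim(coords)[1L],
         " atoms, topology has ", nrow(topology$atoms), call. = FALSE)
  sel <- seq(1L, dim(coords)[3L], by = stride)
  coords <- coords[, , sel, drop = FALSE]
  idx <- seq_along(sel) - 1L
  structure(list(
    coords = coords,
    frame_index = idx,
    time_ns = if (is.na(frame_interval_ns)) rep(NA_real_, length(idx))
              else frames_to_time(idx, frame_interval_ns),
    n_frames = length(idx)),
    class = "red_traj")
}

#' @export
print.red_traj <- function(x, ...) {
  cat("MD trajectory:", x$n_frames, "frames,", dim(x$coords)[1L], "atoms\n")
  invisible(x)
}

#' Extract one frame's coordinate matrix
#'
#' @param traj a `red_traj`.
#' @param frame_index 0-based frame index.
#' @return an n_atoms x 3 numeric matrix.
#' @export
get_frame <- function(traj, frame_index) {
  stopifnot(inherits(traj, "red_traj"))
  i <- frame_index + 1L
  if (i < 1L || i > traj$n_frames)
    stop("frame_index out of range: ", frame_index, call. = FALSE)
  traj$coords[, , i]
}
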