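# Residue-contact construction: per-frame binary maps, the (R, R, n) tensor,
# flattening to the feature-by-time NMF input, sliding-window smoothing, and
# the ligand-protein contact variant.

#' Per-frame residue contact map
#'
#' Two residues are in contact when any atom of one lies within `cutoff_A`
#' (inclusive) of any atom of the other.  The map is symmetric with a unit
#' diagonal.  Distances are plain Euclidean: no periodic-boundary
#' minimum-image convention is applied, so trajectories should be wrapped
#' with the protein whole.
#'
#' @param topology a `red_topology`.
#' @param coords n_atoms x 3 coordinate matrix for one frame (same atom order
#'   as the topology), or a `red_traj` plus `frame_index`.
#' @param cutoff_A contact distance cutoff in Angstrom (default 3.5).
#' @param atom_scope `"all"` uses every atom including hydrogens (matching
#'   the usual VMD `within` selection); `"heavy"` drops hydrogens, for
#'   models built without them.
#' @param frame_index 0-based frame to use when `coords` is a `red_traj`.
#' @return an R x R binary integer matrix (R = number of protein residues).
#' @export
frame_contact_map <- function(topology, coords, cutoff_A = 3.5,
                              atom_scope = c("all", "heavy"),
                              frame_index = 0L) {
  atom_scope <- match.arg(atom_scope)
  stopifnot(cutoff_A > 0)
  if (inherits(coords, "red_traj")) coords <- get_frame(coords, frame_index)
  a <- topology$atoms
  sel <- a$component_class == "protein"
  if (atom_scope == "heavy") sel <- sel & toupper(a$element) != "H"
  R <- topology$n_residues
  xyz <- coords[sel, , drop = FALSE]
  res <- a$residue_index[sel] + 1L
  d <- as.matrix(stats::dist(xyz)) <= cutoff_A
  # membership matrix: atoms x residues
  memb <- matrix(0L, nrow(xyz), R)
  memb[cbind(seq_len(nrow(xyz)), res)] <- 1L
  cm <- (t(memb) %*% d %*% memb) > 0
  diag(cm) <- TRUE
  storage.mode(cm) <- "integer"
  cm
}

#' Build the binary residue-contact tensor of a trajectory
#'
#' Stacks [frame_contact_map()] over all frames into an (R, R, n) array.
#'
#' @inheritParams frame_contact_map
#' @param traj a `red_traj`.
#' @return a `red_contact_tensor`: the (R, R, n) 0/1 array with attributes
#'   `cutoff_A` and `atom_scope`.
#' @export
build_contact_tensor <- function(topology, traj, cutoff_A = 3.5,
                                 atom_scope = c("all", "heavy")) {
  atom_scope <- match.arg(atom_scope)
  stopifnot(inherits(traj, "red_traj"), traj$n_frames >= 1L)
  R <- topology$n_residues
  out <- array(0L, dim = c(R, R, traj$n_frames))
  for (t in seq_len(traj$n_frames))
    out[, , t] <- frame_contact_map(topology, traj$coords[, , t],
                                    cutoff_A, atom_scope)
  contact_tensor(out, cutoff_A = cutoff_A, atom_scope = atom_scope)
}

#' @rdname build_contact_tensor
#' @param values an (R, R, n) binary array, e.g. from the synthetic generator.
#' @export
contact_tensor <- function(values, cutoff_A = 3.5, atom_scope = "all") {
  stopifnot(length(dim(values)) == 3L, dim(values)[1L] == dim(values)[2L])
  structure(values, cutoff_A = cutoff_A, atom_scope = atom_scope,
            class = "red_contact_tensor")
}

#' Flatten a contact tensor to the feature-by-time matrix
#'
#' Rearranges the (R, R, n) tensor into the (F, n) matrix consumed by the
#' factorization.  `"full"` keeps all R^2 ordered pairs (the historical
#' convention, and the default); `"upper_triangle"` keeps each unordered pair
#' once (F = R(R+1)/2), halving memory with no loss for symmetric tensors.
#'
#' @param tensor a `red_contact_tensor`.
#' @param dedupe `"full"` or `"upper_triangle"`.
#' @return a `red_features` object: list with `values` (F x n matrix),
#'   `labels` (data frame of 0-based residue pairs `i`, `j`), `kind`
#'   (`"pair"`) and the tensor's `cutoff_A`.
#' @export
flatten_tensor <- function(tensor, dedupe = c("full", "upper_triangle")) {
  dedupe <- match.arg(dedupe)
  R <- dim(tensor)[1L]
  n <- dim(tensor)[3L]
  i <- rep(seq_len(R) - 1L, times = R)       # column-major: i varies fastest
  j <- rep(seq_len(R) - 1L, each = R)
  vals <- matrix(as.numeric(tensor), R * R, n)
  if (dedupe == "upper_triangle") {
    keep <- i <= j
    vals <- vals[keep, , drop = FALSE]
    i <- i[keep]
    j <- j[keep]
  }
  structure(list(values = vals,
                 labels = data.frame(i = i, j = j),
                 kind = "pair",
                 cutoff_A = attr(tensor, "cutoff_A") %||% NA_real_,
                 window_frames = NA_integer_),
            class = "red_features")
}

#' @export
print.red_features <- function(x, ...) {
  cat("Contact features:", nrow(x$values), "features x", ncol(x$values),
      "frames (", x$kind, ")\n", sep = " ")
  if (!is.na(x$window_frames))
    cat("  smoothed, window =", x$window_frames, "frames\n")
  invisible(x)
}

#' Sliding-window temporal smoothing of contact features
#'
#' Replaces each feature's 0/1 trace by its centered moving average.  Fast
#' contact flicker averages towards an intermediate occupancy (~0.5 for a
#' balanced flicker) while rare persistent transitions keep their full 0-to-1
#' swing, which is what makes them stand out to the factorization.  Windows
#' are truncated at both trajectory ends, so no frames are dropped.
#'
#' @param x a `red_features` object or a plain numeric matrix (features x
#'   frames).
#' @param window_frames width of the centered window, in frames.  The
#'   conventional choice is the frame count spanning ~30 ns of simulation
#'   (125 frames at a 0.24 ns parse interval).
#' @return same type as `x`, with values in `[0, 1]` and unchanged shape.
#' @export
smooth_contacts <- function(x, window_frames = 125L) {
  if (inherits(x, "red_features")) {
    x$values <- row_moving_average(x$values, window_frames)
    x$window_frames <- as.integer(window_frames)
    return(x)
  }
  row_moving_average(x, window_frames)
}

#' Ligand-protein contact features
#'
#' One feature per protein residue: 1 when any ligand atom is within
#' `cutoff_A` of any atom of that residue.  This is the reduced contact
#' representation used to follow the ligand's binding mode (R features
#' instead of R^2).
#'
#' @inheritParams build_contact_tensor
#' @param window_frames optional smoothing window applied to the result
#'   (`NULL` = leave binary).
#' @return a `red_features` with `kind = "residue"` and labels `i` (0-based
#'   residue index).
#' @export
ligand_contact_matrix <- function(topology, traj, cutoff_A = 3.5,
                                  atom_scope = c("all", "heavy"),
                                  window_frames = NULL) {
  atom_scope <- match.arg(atom_scope)
  a <- topology$atoms
  lig <- a$component_class == "ligand"
  if (atom_scope == "heavy") lig <- lig & toupper(a$element) != "H"
  if (!any(lig)) stop("no ligand atoms in topology; set `ligand_resnames` ",
                      "in load_topology()", call. = FALSE)
  prot <- a$component_class == "protein"
  if (atom_scope == "heavy") prot <- prot & toupper(a$element) != "H"
  R <- topology$n_residues
  res <- a$residue_index[prot] + 1L
  out <- matrix(0, R, traj$n_frames)
  for (t in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , t]
    pl <- xyz[prot, , drop = FALSE]
    ll <- xyz[lig, , drop = FALSE]
    # distance of each protein atom to its nearest ligand atom
    d2 <- outer(rowSums(pl^2), rowSums(ll^2), "+") - 2 * pl %*% t(ll)
    near <- sqrt(pmax(apply(d2, 1L, min), 0)) <= cutoff_A
    out[, t] <- as.numeric(tapply(near, res, any)[as.character(seq_len(R))])
  }
  out[is.na(out)] <- 0
  feats <- structure(list(values = out,
                          labels = data.frame(i = seq_len(R) - 1L),
                          kind = "residue",
                          cutoff_A = cutoff_A,
                          window_frames = NA_integer_),
                     class = "red_features")
  if (!is.null(window_frames)) feats <- smooth_contacts(feats, window_frames)
  feats
}

#' Save / load contact features
#'
#' Features are stored as a plain-text matrix (one feature per line) with a
#' JSON sidecar holding shape, labels, cutoff and smoothing window, so a
#' factorization can be rerun without recomputing contacts.
#'
#' @param x a `red_features`.
#' @param path base path; `.tsv.gz` and `.json` files are written.
#' @return `path` (for `write_features`) or the restored `red_features`.
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "red_features"))
  con <- gzfile(paste0(path, ".tsv.gz"), "w")
  utils::write.table(x$values, con, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  close(con)
  jsonlite::write_json(
    list(kind = x$kind, labels = x$labels, cutoff_A = x$cutoff_A,
         window_frames = x$window_frames,
         dim = dim(x$values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(gzfile(paste0(path, ".tsv.gz")),
                                      sep = "\t"))
  dimnames(vals) <- NULL
  structure(list(values = vals, labels = as.data.frame(meta$labels),
                 kind = meta$kind, cutoff_A = meta$cutoff_A,
                 window_frames = meta$window_frames %||% NA_integer_),
            class = "red_features")
}
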