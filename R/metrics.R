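# Companion structural metrics: intracellular-cavity water counting, helix
# axes and bend/wobble angles, residue-pair distances, TM selections, and
# optimal-superposition RMSD.

#' Intracellular-cavity criteria
#'
#' The cavity is defined by set membership on water oxygen positions: a
#' water is in the cavity if its oxygen is within `radius_1` of the Calpha
#' of `include_1` OR within `radius_2` of the Calpha of `include_2`, AND not
#' within `lipid_radius` of any lipid atom, AND not within `exclude_radius`
#' of the Calpha of `exclude_center`.  The defaults are the standard
#' Class-A-GPCR choice: L2.43 (15 A), A6.33 (8 A), lipids at 5 A, S3.39
#' (12 A).
#'
#' @param include_1,include_2,exclude_center BW labels of the anchor
#'   residues.
#' @param radius_1,radius_2,lipid_radius,exclude_radius radii in Angstrom.
#' @return a `red_cavity_criteria` list.
#' @export
cavity_criteria <- function(include_1 = "2.43", radius_1 = 15,
                            include_2 = "6.33", radius_2 = 8,
                            lipid_radius = 5,
                            exclude_center = "3.39", exclude_radius = 12) {
  r <- c(radius_1, radius_2, lipid_radius, exclude_radius)
  if (any(r <= 0)) stop("all cavity radii must be positive", call. = FALSE)
  structure(list(include_1 = include_1, radius_1 = radius_1,
                 include_2 = include_2, radius_2 = radius_2,
                 lipid_radius = lipid_radius,
                 exclude_center = exclude_center,
                 exclude_radius = exclude_radius),
            class = "red_cavity_criteria")
}

.ca_coord <- function(topology, coords, residue_index) {
  a <- topology$atoms
  row <- which(a$residue_index == residue_index & a$atom_name == "CA")
  if (length(row) == 0L)
    stop("no CA atom for residue index ", residue_index, call. = FALSE)
  coords[row[1L], ]
}

#' Count water molecules in the intracellular cavity
#'
#' Applies the literal membership rule of [cavity_criteria()] to each water
#' oxygen of one frame.  When the system contains no lipid atoms the lipid
#' exclusion passes vacuously (a message notes this once per call).
#'
#' @param topology a `red_topology`.
#' @param coords n_atoms x 3 coordinate matrix for the frame (or a
#'   `red_traj` plus `frame_index`).
#' @param bw_map a `red_bwmap` resolving the criteria's anchor labels.
#' @param criteria a `red_cavity_criteria` (defaults apply).
#' @param frame_index 0-based frame when `coords` is a trajectory.
#' @param quiet suppress the no-lipid message.
#' @return integer count of cavity waters.
#' @export
cavity_water_count <- function(topology, coords, bw_map,
                               criteria = cavity_criteria(),
                               frame_index = 0L, quiet = FALSE) {
  if (inherits(coords, "red_traj")) coords <- get_frame(coords, frame_index)
  a <- topology$atoms
  c1 <- .ca_coord(topology, coords, resolve_bw(bw_map, criteria$include_1))
  c2 <- .ca_coord(topology, coords, resolve_bw(bw_map, criteria$include_2))
  c3 <- .ca_coord(topology, coords, resolve_bw(bw_map, criteria$exclude_center))
  wat <- a$component_class == "water" & toupper(a$element) == "O"
  if (!any(wat)) return(0L)
  wxyz <- coords[wat, , drop = FALSE]
  d_to <- function(p) sqrt(colSums((t(wxyz) - p)^2))
  inside <- (d_to(c1) <= criteria$radius_1) | (d_to(c2) <= criteria$radius_2)
  inside <- inside & (d_to(c3) > criteria$exclude_radius)
  lip <- a$component_class == "lipid"
  if (any(lip)) {
    lxyz <- coords[lip, , drop = FALSE]
    # nearest lipid atom per water oxygen
    d2 <- outer(rowSums(wxyz^2), rowSums(lxyz^2), "+") - 2 * wxyz %*% t(lxyz)
    near_lipid <- sqrt(pmax(apply(d2, 1L, min), 0)) <= criteria$lipid_radius
    inside <- inside & !near_lipid
  } else if (!quiet) {
    message("no lipid atoms present; lipid exclusion passes vacuously")
  }
  sum(inside)
}

#' Axis of a helical segment
#'
#' Estimates the helix axis from ordered Calpha positions using second
#' differences (Kahn's construction): the second difference of consecutive
#' Calpha positions points radially toward the axis, so cross products of
#' consecutive second differences all point along it.  Unlike a plain
#' principal-component fit, this is exact for an ideal helix of any length
#' (PCA is biased by the fractional helical turn of a finite segment, by
#' several degrees for typical 10-15-residue segments).  For (nearly)
#' collinear input the principal direction is used instead.  The axis is
#' oriented N-to-C (positive projection on the last-minus-first vector).
#'
#' @param ca_coords m x 3 matrix of ordered Calpha coordinates, m >= 4.
#' @return list with unit `axis` (length-3) and `centroid`.
#' @export
helix_axis <- function(ca_coords) {
  ca_coords <- as.matrix(ca_coords)
  m <- nrow(ca_coords)
  if (m < 4L)
    stop("helix_axis needs at least 4 Calpha points", call. = FALSE)
  ctr <- colMeans(ca_coords)
  V <- diff(ca_coords)            # bond vectors
  A <- diff(V)                    # second differences: radial, in-plane
  acc <- c(0, 0, 0)
  scale_ref <- mean(sqrt(rowSums(A^2)))
  if (scale_ref > 1e-9 && nrow(A) >= 2L) {
    for (i in seq_len(nrow(A) - 1L)) {
      cr <- pracma_cross(A[i, ], A[i + 1L, ])
      ncr <- vnorm(cr)
      if (ncr > 1e-9 * scale_ref^2) acc <- acc + cr / ncr
    }
  }
  if (vnorm(acc) < 1e-6) {
    # straight/degenerate segment: fall back to the principal direction
    x <- sweep(ca_coords, 2L, ctr)
    acc <- svd(x, nu = 0L, nv = 1L)$v[, 1L]
  }
  nc <- ca_coords[m, ] - ca_coords[1L, ]
  if (sum(acc * nc) < 0) acc <- -acc
  list(axis = unit(acc), centroid = ctr)
}

# Core bend/wobble computation on raw coordinates.
# Convention: bend = angle between the pre- and post-segment axes.  Wobble =
# signed angle, about the pre-segment axis, from the reference direction
# (the component perpendicular to the pre-axis of pivot_ca - pre centroid)
# to the perpendicular component of the post axis; right-handed about the
# pre-axis.
helix_wobble_core <- function(ca_pre, ca_post, pivot_ca,
                              degenerate_tol = 1e-3) {
  pre <- helix_axis(ca_pre)
  post <- helix_axis(ca_post)
  a <- pre$axis
  b <- post$axis
  bend <- acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
  perp <- b - sum(a * b) * a
  if (bend < degenerate_tol || vnorm(perp) < 1e-12) {
    return(list(bend_angle_deg = bend, wobble_angle_deg = 0,
                degenerate = TRUE))
  }
  ref <- pivot_ca - pre$centroid
  ref <- ref - sum(a * ref) * a
  if (vnorm(ref) < 1e-12)
    return(list(bend_angle_deg = bend, wobble_angle_deg = 0,
                degenerate = TRUE))
  ref <- unit(ref)
  perp <- unit(perp)
  cosw <- sum(ref * perp)
  sinw <- sum(a * pracma_cross(ref, perp))
  wob <- atan2(sinw, cosw) * 180 / pi
  list(bend_angle_deg = bend, wobble_angle_deg = wob, degenerate = FALSE)
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' Helix bend and wobble angle at a pivot
#'
#' Quantifies the reorientation of a helix across a kink or hinge residue
#' (e.g. the proline kink of TM6 at 6.50, or Helix 8 pivoting at 7.57).  The
#' bend angle is the polar angle between the axes of the two flanking
#' segments; the wobble angle is the azimuthal direction of that
#' reorientation about the pre-segment axis, measured right-handed from a
#' fixed reference (the pivot Calpha direction seen from the pre-segment
#' centroid, projected perpendicular to the pre-axis).  Absolute wobble
#' values are convention-dependent; differences over time are the physically
#' meaningful quantity.
#'
#' @param topology a `red_topology`.
#' @param coords frame coordinates (or a `red_traj` plus `frame_index`).
#' @param pivot BW label of the pivot residue.
#' @param pre_range,post_range length-2 character vectors of BW labels
#'   bounding the two helical segments (each >= 4 residues).
#' @param bw_map a `red_bwmap`.
#' @param frame_index 0-based frame when `coords` is a trajectory.
#' @return a list: `bend_angle_deg` in `[0, 180]`, `wobble_angle_deg` in
#'   `(-180, 180]` (0 with `degenerate = TRUE` when the helix is straight),
#'   `pivot`, `pre_segment`, `post_segment` residue indices.
#' @export
wobble_angle <- function(topology, coords, pivot = "7.57",
                         pre_range = c("7.46", "7.56"),
                         post_range = c("7.58", "7.68"),
                         bw_map, frame_index = 0L) {
  if (inherits(coords, "red_traj")) coords <- get_frame(coords, frame_index)
  pre_idx <- bw_range(bw_map, pre_range[1L], pre_range[2L])
  post_idx <- bw_range(bw_map, post_range[1L], post_range[2L])
  if (length(pre_idx) < 4L || length(post_idx) < 4L)
    stop("helical segments must contain at least 4 residues", call. = FALSE)
  piv_idx <- resolve_bw(bw_map, pivot)
  ca <- function(idx) t(vapply(idx, function(r) .ca_coord(topology, coords, r),
                               numeric(3L)))
  res <- helix_wobble_core(ca(pre_idx), ca(post_idx),
                           .ca_coord(topology, coords, piv_idx))
  c(res, list(pivot = piv_idx, pre_segment = pre_idx, post_segment = post_idx))
}

#' Residue-pair distance time series
#'
#' @param topology a `red_topology`.
#' @param traj a `red_traj`.
#' @param residue_a,residue_b BW labels of the two residues.
#' @param atom `"CA"` for Calpha-Calpha distance, `"min_heavy"` for the
#'   minimum heavy-atom distance.
#' @param bw_map a `red_bwmap`.
#' @return numeric vector of per-frame distances in Angstrom.
#' @export
pair_distance_series <- function(topology, traj, residue_a, residue_b,
                                 atom = c("CA", "min_heavy"), bw_map) {
  atom <- match.arg(atom)
  ia <- resolve_bw(bw_map, residue_a)
  ib <- resolve_bw(bw_map, residue_b)
  a <- topology$atoms
  rows_for <- function(ri) {
    if (atom == "CA") {
      r <- which(a$residue_index == ri & a$atom_name == "CA")
      if (!length(r)) stop("no CA atom for residue index ", ri, call. = FALSE)
      r[1L]
    } else {
      r <- which(a$residue_index == ri & toupper(a$element) != "H")
      if (!length(r)) stop("no heavy atoms for residue index ", ri, call. = FALSE)
      r
    }
  }
  ra <- rows_for(ia)
  rb <- rows_for(ib)
  vapply(seq_len(traj$n_frames), function(t) {
    xa <- matrix(traj$coords[ra, , t], ncol = 3L)
    xb <- matrix(traj$coords[rb, , t], ncol = 3L)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    sqrt(max(min(d2), 0))
  }, numeric(1L))
}

#' Transmembrane-domain residue selection
#'
#' Resolves a list of BW label ranges (one per TM helix) to the union of
#' their residue indices.
#'
#' @param bw_map a `red_bwmap`.
#' @param tm_definitions list of length-2 character vectors
#'   `c(start_label, end_label)`.
#' @return sorted integer vector of unique 0-based residue indices.
#' @export
#' @examples
#' m <- bw_map(sprintf("5.%d", 37:63), 100:126)
#' length(tm_selection(m, list(c("5.37", "5.63"))))  # 27
tm_selection <- function(bw_map, tm_definitions) {
  if (length(tm_definitions) == 0L) return(integer())
  idx <- unlist(lapply(tm_definitions, function(d)
    bw_range(bw_map, d[[1L]], d[[2L]])))
  sort(unique(as.integer(idx)))
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of two ordered point sets followed by
#' RMSD over the same points.  The mobile set is fit onto the reference;
#' the fitted and scored atom sets are identical.
#'
#' @param coords_ref,coords_mobile m x 3 matrices, m >= 3, corresponding
#'   rows.
#' @return RMSD in Angstrom after superposition.
#' @export
superpose_rmsd <- function(coords_ref, coords_mobile) {
  P <- as.matrix(coords_ref)
  Q <- as.matrix(coords_mobile)
  if (!all(dim(P) == dim(Q)))
    stop("point sets must have identical dimensions", call. = FALSE)
  if (nrow(P) < 3L) stop("need at least 3 points", call. = FALSE)
  pc <- colMeans(P)
  qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc)
  Q0 <- sweep(Q, 2L, qc)
  C <- crossprod(Q0, P0)                # 3x3 covariance
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  Rm <- s$u %*% D %*% t(s$v)            # rotation applied to mobile
  Qr <- Q0 %*% Rm
  sqrt(mean(rowSums((Qr - P0)^2)))
}

#' Compare two structures over their TM domains
#'
#' Convenience wrapper: reads two PDB files and their BW maps, selects the
#' TM Calpha atoms by shared generic labels, and returns the Kabsch RMSD.
#' The two maps may cover different label sets; only ranges resolvable in
#' both structures are compared.
#'
#' @param pdb_ref,pdb_mobile paths to PDB files.
#' @param map_ref,map_mobile `red_bwmap`s (or map file paths) for each.
#' @param tm_definitions list of BW ranges, as in [tm_selection()].
#' @return list with `rmsd` (Angstrom) and `n_atoms` compared.
#' @export
tm_rmsd <- function(pdb_ref, pdb_mobile, map_ref, map_mobile, tm_definitions) {
  top_r <- load_topology(pdb_ref)
  top_m <- load_topology(pdb_mobile)
  if (is.character(map_ref)) map_ref <- read_bw_map(map_ref, top_r)
  if (is.character(map_mobile)) map_mobile <- read_bw_map(map_mobile, top_m)
  # per-label CA coordinates, intersected on labels present in both maps
  labels <- unlist(lapply(tm_definitions, function(d) {
    helix <- sub("\\..*$", "", d[[1L]])
    from <- as.integer(sub("^.*\\.", "", d[[1L]]))
    to <- as.integer(sub("^.*\\.", "", d[[2L]]))
    sprintf("%s.%d", helix, from:to)
  }))
  labels <- labels[labels %in% names(map_ref) & labels %in% names(map_mobile)]
  if (length(labels) < 3L)
    stop("fewer than 3 shared TM labels between the two maps", call. = FALSE)
  ca_of <- function(top, map) t(vapply(labels, function(l)
    .ca_coord(top, top$first_frame, resolve_bw(map, l)), numeric(3L)))
  list(rmsd = superpose_rmsd(ca_of(top_r, map_ref), ca_of(top_m, map_mobile)),
       n_atoms = length(labels))
}
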