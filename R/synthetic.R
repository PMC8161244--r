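# Synthetic fixtures with known ground truth: contact series with planted
# archetype transitions, geometric toy trajectories realizing a planted
# tensor, cavity scenes with a known water count, and kinked helices with
# planted bend/wobble angles.  Every generator is a pure function of its
# parameters and seed.

#' Generate a contact series with planted transitions
#'
#' Emulates what the contact tensor of a long trajectory looks like: a
#' stationary backbone of contacts (diagonal plus near-neighbor band and a
#' shared core), state-specific contact sets that switch at planted
#' transition frames, fast i.i.d. contact flicker at rate
#' `flip_noise_rate`, and linear cross-fades of the contact probabilities
#' over `ramp_frames` around each transition so that transitions are rare
#' but not instantaneous.  An optional two-state Markov flicker
#' (`noise_autocorr` in `[0, 1)`) makes the noise temporally correlated, a
#' harder, more MD-like regime.
#'
#' @param R number of residues.
#' @param n number of frames.
#' @param n_states number of archetypes (ignored when `archetypes` given).
#' @param transition_frames strictly increasing frames in `(0, n)` at which
#'   the state switches; default: evenly spaced for `n_states` states.
#' @param flip_noise_rate per-entry, per-frame flip probability in
#'   `[0, 0.5)`.
#' @param ramp_frames width of the linear cross-fade at each transition.
#' @param archetypes optional list of R x R binary symmetric matrices to use
#'   as the states.
#' @param pairs_per_state number of state-specific contact pairs; the
#'   default scales with R (~0.75 R), capped so the requested number of
#'   states stays feasible.
#' @param noise_autocorr persistence of the flicker noise (0 = i.i.d.).
#' @param seed integer seed; same seed, same output.
#' @return list with `tensor` (a `red_contact_tensor`) and `truth`: list
#'   with `archetypes`, `transition_frames`, `states` (per-frame state),
#'   `flip_noise_rate`, `ramp_frames`, `seed`.
#' @export
generate_contact_series <- function(R, n, n_states = 2L,
                                    transition_frames = NULL,
                                    flip_noise_rate = 0.05,
                                    ramp_frames = 50L,
                                    archetypes = NULL,
                                    pairs_per_state = NULL,
                                    noise_autocorr = 0,
                                    seed = 1L) {
  stopifnot(flip_noise_rate >= 0, flip_noise_rate < 0.5,
            noise_autocorr >= 0, noise_autocorr < 1)
  with_seed(seed, {
    if (is.null(archetypes)) {
      n_states <- as.integer(n_states)
      # shared scaffold: diagonal + |i-j|<=2 band + a random stable core
      base <- diag(1L, R)
      for (d in 1:2) {
        idx <- cbind(seq_len(R - d), seq_len(R - d) + d)
        base[idx] <- 1L
        base[idx[, 2:1, drop = FALSE]] <- 1L
      }
      all_pairs <- which(upper.tri(matrix(0, R, R)) &
                           base == 0L, arr.ind = TRUE)
      core_n <- min(nrow(all_pairs) %/% 2L, round(R))
      perm <- sample.int(nrow(all_pairs))
      core <- all_pairs[perm[seq_len(core_n)], , drop = FALSE]
      base[core] <- 1L
      base[core[, 2:1, drop = FALSE]] <- 1L
      pool <- perm[-seq_len(core_n)]
      if (is.null(pairs_per_state))
        pairs_per_state <- min(max(4L, round(R * 0.75)),
                               length(pool) %/% n_states)
      need <- pairs_per_state * n_states
      if (pairs_per_state < 2L || length(pool) < need)
        stop("R too small for the requested number of state-specific pairs",
             call. = FALSE)
      archetypes <- vector("list", n_states)
      for (s in seq_len(n_states)) {
        A <- base
        own <- all_pairs[pool[((s - 1L) * pairs_per_state + 1L):
                                (s * pairs_per_state)], , drop = FALSE]
        A[own] <- 1L
        A[own[, 2:1, drop = FALSE]] <- 1L
        archetypes[[s]] <- A
      }
    } else {
      n_states <- length(archetypes)
      dims <- vapply(archetypes, function(a) all(dim(a) == c(R, R)), TRUE)
      if (!all(dims)) stop("archetype shapes inconsistent with R", call. = FALSE)
    }
    if (is.null(transition_frames) && n_states > 1L)
      transition_frames <- round(seq_len(n_states - 1L) * n / n_states)
    transition_frames <- as.integer(transition_frames %||% integer())
    if (length(transition_frames)) {
      if (any(diff(transition_frames) <= 0) ||
          any(transition_frames <= 0L | transition_frames >= n))
        stop("transition frames must be strictly increasing inside (0, n)",
             call. = FALSE)
      if (length(transition_frames) != n_states - 1L)
        stop("need one transition frame per consecutive state pair",
             call. = FALSE)
    }

    # per-frame state and cross-faded mixing weight
    state <- findInterval(seq_len(n) - 1L, transition_frames) + 1L
    ut <- upper.tri(matrix(0, R, R))
    arch_u <- vapply(archetypes, function(a) as.numeric(a[ut]),
                     numeric(sum(ut)))           # pairs x states
    np <- nrow(arch_u)
    q <- flip_noise_rate
    tensor <- array(0L, dim = c(R, R, n))
    prev_flip <- NULL
    for (t in seq_len(n)) {
      s <- state[t]
      p <- arch_u[, s]
      # linear cross-fade over [tf - ramp/2, tf + ramp/2)
      if (ramp_frames > 0) for (ti in seq_along(transition_frames)) {
        tf <- transition_frames[ti]
        alpha <- ((t - 1L) - (tf - ramp_frames / 2)) / ramp_frames
        if (alpha > 0 && alpha < 1)
          p <- (1 - alpha) * arch_u[, ti] + alpha * arch_u[, ti + 1L]
      }
      if (q > 0) {
        if (noise_autocorr > 0) {
          # two-state Markov flicker: flip indicator persists
          if (is.null(prev_flip)) {
            flip <- stats::runif(np) < q
          } else {
            stay <- stats::runif(np) < noise_autocorr
            flip <- ifelse(stay, prev_flip, stats::runif(np) < q)
          }
          prev_flip <- flip
          val <- as.integer(stats::runif(np) < p)
          val[flip] <- 1L - val[flip]
        } else {
          pq <- p * (1 - q) + (1 - p) * q
          val <- as.integer(stats::runif(np) < pq)
        }
      } else {
        val <- as.integer(stats::runif(np) < p)
      }
      m <- matrix(0L, R, R)
      m[ut] <- val
      m <- m + t(m)
      diag(m) <- 1L
      tensor[, , t] <- m
    }
    list(tensor = contact_tensor(tensor),
         truth = list(archetypes = archetypes,
                      transition_frames = transition_frames,
                      states = state,
                      flip_noise_rate = flip_noise_rate,
                      ramp_frames = ramp_frames,
                      noise_autocorr = noise_autocorr,
                      seed = seed))
  })
}

#' Realize a planted contact tensor as a toy trajectory
#'
#' Writes a PDB + DCD pair (plus a JSON truth sidecar) in which each residue
#' is a single pseudo-atom: residues in contact sit 3.0 A apart, all others
#' at least 6 A apart, so [build_contact_tensor()] at the 3.5 A cutoff
#' recovers the planted tensor exactly.  Geometric realization requires each
#' residue to take part in at most one off-diagonal contact per frame (a
#' matching); denser contact sets raise a feasibility error.
#'
#' @param tensor an (R, R, n) binary array or `red_contact_tensor` whose
#'   every frame is a matching.
#' @param dir output directory (created if needed).
#' @param basename file base name.
#' @return list of written paths: `pdb`, `dcd`, `truth`.
#' @export
generate_toy_trajectory <- function(tensor, dir = tempdir(),
                                    basename = "toy") {
  R <- dim(tensor)[1L]
  n <- dim(tensor)[3L]
  if (R > 60L) stop("toy trajectories are desk-scale: R <= 60", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # base grid, spacing 10 A
  gx <- ceiling(sqrt(R))
  base <- cbind(((seq_len(R) - 1L) %% gx) * 10,
                ((seq_len(R) - 1L) %/% gx) * 10,
                0)
  coords <- array(0, dim = c(R, 3L, n))
  for (t in seq_len(n)) {
    m <- tensor[, , t]
    diag(m) <- 0L
    deg <- rowSums(m)
    if (any(deg > 1L))
      stop("infeasible geometry at frame ", t - 1L, ": residue(s) ",
           paste(which(deg > 1L) - 1L, collapse = ", "),
           " have >1 simultaneous contact; plant fewer simultaneous contacts",
           call. = FALSE)
    pos <- base
    pr <- which(upper.tri(m) & m == 1L, arr.ind = TRUE)
    if (nrow(pr)) for (e in seq_len(nrow(pr))) {
      i <- pr[e, 1L]
      j <- pr[e, 2L]
      pos[j, ] <- pos[i, ] + c(3, 0, 0)
    }
    coords[, , t] <- pos
  }
  atoms <- data.frame(
    atom_id = seq_len(R) - 1L,
    atom_name = "CA",
    element = "C",
    residue_index = seq_len(R) - 1L,
    residue_name = "GLY",
    resseq = seq_len(R),
    chain = "A",
    component_class = "protein",
    stringsAsFactors = FALSE)
  top <- structure(list(atoms = atoms, n_residues = R,
                        first_frame = coords[, , 1L]),
                   class = "red_topology")
  pdb <- file.path(dir, paste0(basename, ".pdb"))
  dcd <- file.path(dir, paste0(basename, ".dcd"))
  truth_path <- file.path(dir, paste0(basename, "_truth.json"))
  write_pdb(top, coords[, , 1L], pdb)
  write_dcd(coords, dcd)
  jsonlite::write_json(list(R = R, n = n, kind = "toy_trajectory"),
                       truth_path, auto_unbox = TRUE, digits = NA)
  list(pdb = pdb, dcd = dcd, truth = truth_path)
}

#' Generate a cavity-counting scene with a known answer
#'
#' Builds an in-memory topology (10-residue pseudo-protein, a lipid wall,
#' and water oxygens) in which exactly `n_in` waters satisfy the cavity
#' criteria, `n_out` violate the inclusion spheres, and `n_lipid_blocked`
#' satisfy inclusion but sit within the lipid exclusion radius.  Anchors:
#' label 2.43 is residue 0 at the origin (15 A sphere), 6.33 is residue 1 at
#' (40,0,0), 3.39 is residue 2 at (0,80,0).  A lipid atom sits at (0,0,12).
#'
#' @param n_in,n_out,n_lipid_blocked water counts by construction.
#' @param seed integer seed.
#' @return list with `topology`, `coords`, `bw_map`, `expected`
#'   (`= n_in`).
#' @export
generate_cavity_scene <- function(n_in, n_out, n_lipid_blocked, seed = 1L) {
  stopifnot(n_in >= 0, n_out >= 0, n_lipid_blocked >= 0)
  with_seed(seed, {
    ca <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 80, 0))
    extra <- cbind(0, -60, seq_len(7L) * 10)
    prot_xyz <- rbind(ca, extra)
    lipid_xyz <- rbind(c(0, 0, 12), c(5, 0, 12), c(-5, 0, 12))

    rand_dir <- function(k) {
      v <- matrix(stats::rnorm(3 * k), k, 3L)
      v / sqrt(rowSums(v^2))
    }
    sample_in <- function(k) {
      out <- matrix(0, 0, 3L)
      while (nrow(out) < k) {
        m <- rand_dir(2L * k + 4L) * stats::runif(2L * k + 4L, 6, 14)
        ok <- m[, 3L] <= 5        # keeps every lipid atom > 5 A away
        out <- rbind(out, m[ok, , drop = FALSE])
      }
      out[seq_len(k), , drop = FALSE]
    }
    sample_out <- function(k) {
      if (k == 0L) return(matrix(0, 0, 3L))
      m <- rand_dir(k) * stats::runif(k, 20, 30)
      m[, 1L] <- -abs(m[, 1L]) - 1    # x < 0: far from the 6.33 sphere too
      m
    }
    sample_blocked <- function(k) {
      if (k == 0L) return(matrix(0, 0, 3L))
      out <- matrix(0, 0, 3L)
      while (nrow(out) < k) {
        m <- sweep(rand_dir(2L * k + 4L) * stats::runif(2L * k + 4L, 0.5, 4),
                   2L, c(0, 0, 12), "+")
        ok <- sqrt(rowSums(m^2)) <= 14.5
        out <- rbind(out, m[ok, , drop = FALSE])
      }
      out[seq_len(k), , drop = FALSE]
    }
    wat <- rbind(sample_in(n_in), sample_out(n_out),
                 sample_blocked(n_lipid_blocked))

    n_prot <- nrow(prot_xyz)
    n_lip <- nrow(lipid_xyz)
    n_wat <- nrow(wat)
    atoms <- data.frame(
      atom_id = seq_len(n_prot + n_lip + n_wat) - 1L,
      atom_name = c(rep("CA", n_prot), rep("C2", n_lip), rep("OH2", n_wat)),
      element = c(rep("C", n_prot + n_lip), rep("O", n_wat)),
      residue_index = c(seq_len(n_prot) - 1L,
                        n_prot + rep(0L, n_lip),
                        n_prot + 1L + seq_len(max(n_wat, 1L))[seq_len(n_wat)] - 1L),
      residue_name = c(rep("GLY", n_prot), rep("POPC", n_lip),
                       rep("TIP3", n_wat)),
      resseq = c(seq_len(n_prot), rep(n_prot + 1L, n_lip),
                 n_prot + 1L + seq_len(max(n_wat, 1L))[seq_len(n_wat)]),
      chain = "A",
      component_class = c(rep("protein", n_prot), rep("lipid", n_lip),
                          rep("water", n_wat)),
      stringsAsFactors = FALSE)
    coords <- rbind(prot_xyz, lipid_xyz, wat)
    top <- structure(list(atoms = atoms, n_residues = n_prot,
                          first_frame = coords),
                     class = "red_topology")
    list(topology = top, coords = coords,
         bw_map = bw_map(c("2.43", "6.33", "3.39"), c(0L, 1L, 2L)),
         expected = as.integer(n_in))
  })
}

.rotation_about <- function(axis, theta) {
  a <- unit(axis)
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a kinked ideal helix with planted bend and wobble
#'
#' Builds an ideal alpha-helix (1.5 A rise, 100 degrees twist per residue,
#' 2.3 A radius) of `pre_len + 1 + post_len` residues and rotates the
#' post-pivot segment rigidly about the pivot Calpha so that the bend/wobble
#' convention of [wobble_angle()] reads back exactly the planted angles.
#'
#' @param bend_deg planted bend angle in `[0, 180)`.
#' @param wobble_deg planted wobble angle in `(-180, 180]`; must be 0 when
#'   `bend_deg` is 0 (a straight helix has no defined wobble).
#' @param pre_len,post_len residues in the two segments (>= 4 each).
#' @param jitter_A optional isotropic Gaussian positional noise.
#' @param seed integer seed (used only for jitter).
#' @return list with `ca_coords` (m x 3), `pivot` (1-based row of the pivot
#'   Calpha), `pre_rows`, `post_rows`, `topology`, `bw_map` (labels
#'   7.46-7.68 when the default 11+1+11 layout is used, 7.x otherwise), and
#'   `truth = list(bend_deg, wobble_deg)`.
#' @export
generate_kinked_helix <- function(bend_deg, wobble_deg, pre_len = 11L,
                                  post_len = 11L, jitter_A = 0, seed = 1L) {
  stopifnot(bend_deg >= 0, bend_deg < 180,
            wobble_deg > -180, wobble_deg <= 180,
            pre_len >= 4L, post_len >= 4L)
  if (bend_deg == 0 && wobble_deg != 0)
    stop("a straight helix (bend 0) cannot carry a nonzero wobble",
         call. = FALSE)
  m <- pre_len + 1L + post_len
  idx <- seq_len(m) - 1L
  twist <- 100 * pi / 180
  ca <- cbind(2.3 * cos(idx * twist), 2.3 * sin(idx * twist), 1.5 * idx)
  pivot <- pre_len + 1L
  pre_rows <- seq_len(pre_len)
  post_rows <- (pivot + 1L):m
  if (bend_deg > 0) {
    # the exact axis of the as-built ideal helix is +z by construction;
    # using the analytic truth here keeps the generator independent of the
    # package's axis estimator, which it is meant to cross-check
    a <- c(0, 0, 1)
    centroid_pre <- colMeans(ca[pre_rows, , drop = FALSE])
    ref <- ca[pivot, ] - centroid_pre
    ref <- unit(ref - sum(a * ref) * a)
    e2 <- pracma_cross(a, ref)
    th <- bend_deg * pi / 180
    ph <- wobble_deg * pi / 180
    d <- cos(th) * a + sin(th) * (cos(ph) * ref + sin(ph) * e2)
    b0 <- c(0, 0, 1)
    rot_ax <- pracma_cross(b0, d)
    if (vnorm(rot_ax) < 1e-12) rot_ax <- ref   # b0 parallel to d
    Rm <- .rotation_about(rot_ax, acos(pmin(pmax(sum(b0 * d), -1), 1)))
    piv <- ca[pivot, ]
    ca[post_rows, ] <- sweep(sweep(ca[post_rows, , drop = FALSE], 2L, piv) %*%
                               t(Rm), 2L, piv, "+")
  }
  if (jitter_A > 0)
    ca <- ca + with_seed(seed, matrix(stats::rnorm(3L * m, sd = jitter_A), m, 3L))
  labels <- sprintf("7.%d", (57L - pre_len):(57L + post_len))
  atoms <- data.frame(
    atom_id = seq_len(m) - 1L, atom_name = "CA", element = "C",
    residue_index = seq_len(m) - 1L, residue_name = "ALA",
    resseq = seq_len(m), chain = "A", component_class = "protein",
    stringsAsFactors = FALSE)
  top <- structure(list(atoms = atoms, n_residues = m, first_frame = ca),
                   class = "red_topology")
  list(ca_coords = ca, pivot = pivot, pre_rows = pre_rows,
       post_rows = post_rows, topology = top,
       bw_map = bw_map(labels, seq_len(m) - 1L),
       truth = list(bend_deg = bend_deg, wobble_deg = wobble_deg))
}
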