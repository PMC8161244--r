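# Independent oracles, coded from the definitions and kept separate from the
# package's implementation paths.

# brute-force centered truncated moving average, one window at a time
oracle_moving_average <- function(m, w) {
  n <- ncol(m)
  left <- floor((w - 1) / 2)
  right <- w - 1 - left
  out <- m
  for (t in seq_len(n)) {
    lo <- max(1, t - left)
    hi <- min(n, t + right)
    out[, t] <- rowMeans(m[, lo:hi, drop = FALSE])
  }
  out
}

# NNDSVD written directly from the published construction
oracle_nndsvd <- function(A, k) {
  s <- svd(A)
  W <- matrix(0, nrow(A), k)
  H <- matrix(0, k, ncol(A))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k >= 2) for (j in 2:k) {
    x <- s$u[, j]; y <- s$v[, j]
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    yp <- pmax(y, 0); yn <- pmax(-y, 0)
    nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
    nyp <- sqrt(sum(yp^2)); nyn <- sqrt(sum(yn^2))
    if (nxp * nyp >= nxn * nyn) {
      sig <- nxp * nyp
      u <- if (nxp > 0) xp / nxp else xp
      v <- if (nyp > 0) yp / nyp else yp
    } else {
      sig <- nxn * nyn
      u <- if (nxn > 0) xn / nxn else xn
      v <- if (nyn > 0) yn / nyn else yn
    }
    W[, j] <- sqrt(s$d[j] * sig) * u
    H[j, ] <- sqrt(s$d[j] * sig) * v
  }
  list(W = W, H = H)
}

# literal per-water membership test for the cavity definition
oracle_cavity_count <- function(topology, coords, bw_map, criteria) {
  a <- topology$atoms
  ca_of <- function(label) {
    ri <- unname(bw_map[[label]])
    row <- which(a$residue_index == ri & a$atom_name == "CA")[1]
    coords[row, ]
  }
  c1 <- ca_of(criteria$include_1)
  c2 <- ca_of(criteria$include_2)
  c3 <- ca_of(criteria$exclude_center)
  lip_rows <- which(a$component_class == "lipid")
  wat_rows <- which(a$component_class == "water" & toupper(a$element) == "O")
  count <- 0L
  for (w in wat_rows) {
    p <- coords[w, ]
    d <- function(q) sqrt(sum((p - q)^2))
    inc <- d(c1) <= criteria$radius_1 || d(c2) <= criteria$radius_2
    if (!inc) next
    if (d(c3) <= criteria$exclude_radius) next
    blocked <- FALSE
    for (l in lip_rows)
      if (sqrt(sum((p - coords[l, ])^2)) <= criteria$lipid_radius) {
        blocked <- TRUE
        break
      }
    if (!blocked) count <- count + 1L
  }
  count
}

# quaternion (Horn) optimal superposition RMSD, independent of Kabsch
oracle_quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Q0, P0)  # mobile^T reference
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# direct elementwise Frobenius residual
oracle_frobenius <- function(I, W, H) {
  r <- I - W %*% H
  sqrt(sum(r * r))
}
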