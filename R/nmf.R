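# Non-negative matrix factorization of smoothed contact features.
#
# The input I (features x frames, entries in [0,1]) is factorized as
# I ~ W H with W >= 0 (features x k, the structural archetypes) and H >= 0
# (k x frames, the temporal weights).  Initialization is deterministic
# NNDSVD; the solver is HALS coordinate descent on the Frobenius objective,
# optionally with an L1 sparsity penalty on W and a squared-first-difference
# temporal-smoothness penalty on H (used for the ligand contact mode).

#' NNDSVD initialization
#'
#' Non-negative Double Singular Value Decomposition: deterministic starting
#' factors built from the leading `k` singular triplets of `I`, with each
#' singular vector split into its positive and negative parts and the
#' dominant part kept.  The `"plain"` variant leaves structural zeros at
#' zero (well suited to sparse contact data); `"mean"` fills them with the
#' matrix mean, which avoids zero-locking under multiplicative updates.
#'
#' @param I non-negative numeric matrix (features x frames) or a
#'   `red_features`.
#' @param k number of components; must not exceed `min(dim(I))`.
#' @param variant `"plain"` or `"mean"`.
#' @return list with non-negative matrices `W0` (F x k) and `H0` (k x n).
#' @references Boutsidis & Gallopoulos (2008) "SVD based initialization: a
#'   head start for nonnegative matrix factorization", Pattern Recognition.
#' @export
nndsvd_init <- function(I, k, variant = c("plain", "mean")) {
  variant <- match.arg(variant)
  if (inherits(I, "red_features")) I <- I$values
  if (any(I < 0)) stop("NNDSVD input must be non-negative", call. = FALSE)
  if (k > min(dim(I)))
    stop("rank k = ", k, " exceeds min(dim(I)) = ", min(dim(I)), call. = FALSE)
  s <- svd(I, nu = k, nv = k)
  W0 <- matrix(0, nrow(I), k)
  H0 <- matrix(0, k, ncol(I))
  # leading triplet: already sign-indeterminate only up to a joint flip
  u1 <- abs(s$u[, 1L])
  v1 <- abs(s$v[, 1L])
  W0[, 1L] <- sqrt(s$d[1L]) * u1
  H0[1L, ] <- sqrt(s$d[1L]) * v1
  if (k >= 2L) for (j in 2:k) {
    x <- s$u[, j]
    y <- s$v[, j]
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    yp <- pmax(y, 0); yn <- pmax(-y, 0)
    xpn <- vnorm(xp); xnn <- vnorm(xn)
    ypn <- vnorm(yp); ynn <- vnorm(yn)
    mp <- xpn * ypn
    mn <- xnn * ynn
    if (mp >= mn) {
      u <- if (xpn > 0) xp / xpn else xp
      v <- if (ypn > 0) yp / ypn else yp
      sig <- mp
    } else {
      u <- if (xnn > 0) xn / xnn else xn
      v <- if (ynn > 0) yn / ynn else yn
      sig <- mn
    }
    W0[, j] <- sqrt(s$d[j] * sig) * u
    H0[j, ] <- sqrt(s$d[j] * sig) * v
  }
  if (variant == "mean") {
    mu <- mean(I)
    W0[W0 == 0] <- mu
    H0[H0 == 0] <- mu
  }
  list(W0 = W0, H0 = H0)
}

# Thomas algorithm for a symmetric tridiagonal system with diagonal `d`
# (vector) and constant off-diagonal `e`.
.tridiag_solve <- function(d, e, b) {
  n <- length(b)
  if (n == 1L) return(b / d)
  cp <- numeric(n)
  bp <- numeric(n)
  cp[1L] <- e / d[1L]
  bp[1L] <- b[1L] / d[1L]
  for (i in 2:n) {
    m <- d[i] - e * cp[i - 1L]
    cp[i] <- e / m
    bp[i] <- (b[i] - e * bp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1L):1L) x[i] <- bp[i] - cp[i] * x[i + 1L]
  x
}

# Full objective: 0.5||I - WH||_F^2 + l1 * sum(W) + smooth * sum(dH^2),
# computed from the Gram pieces already needed by the updates.
.nmf_objective <- function(normI2, WtI, WtW, H, l1, smooth, sumW) {
  HHt <- H %*% t(H)
  fit <- 0.5 * (normI2 - 2 * sum(WtI * H) + sum(WtW * HHt))
  pen <- l1 * sumW
  if (smooth > 0) {
    dH <- H[, -1L, drop = FALSE] - H[, -ncol(H), drop = FALSE]
    pen <- pen + smooth * sum(dH * dH)
  }
  max(fit, 0) + pen
}

#' Factorize contact features into archetypes and temporal weights
#'
#' Fits `I ~ W H` by non-negative matrix factorization from a deterministic
#' NNDSVD start, minimizing `0.5 * ||I - W H||_F^2` (plus optional penalties,
#' see [factorize_ligand()]) with multiplicative updates.  The fit is fully
#' deterministic: identical inputs and settings give bit-identical factors.
#'
#' After convergence each W column is rescaled to unit maximum and the
#' inverse factor applied to its H row, so temporal weights are comparable
#' across components; the product `W H` is unchanged.
#'
#' @param I a `red_features` (typically from [smooth_contacts()]) or a
#'   non-negative matrix, features x frames.
#' @param k number of components.  Six is a practical default for a
#'   single-protein trajectory expected to hold a handful of rare
#'   transitions plus one stationary component; three for ligand mode.
#'   Re-running with k +/- 2-3 and comparing events is cheap and
#'   recommended.
#' @param max_iter,tol iteration cap and relative-objective convergence
#'   tolerance.
#' @param sparsity_weight L1 penalty weight on W entries (>= 0).
#' @param smoothness_weight penalty weight on squared first differences of H
#'   rows (>= 0).
#' @param init_variant NNDSVD variant, see [nndsvd_init()].
#' @param keep_input store `I` in the fit (needed by `residuals()` and
#'   `summary()`; default `TRUE`).
#' @return an object of class `red_nmf` with elements `W`, `H`, `k`,
#'   `objective_value` (the Frobenius reconstruction error `||I - WH||_F`),
#'   `objective_trace` (penalized objective per iteration), `n_iterations`,
#'   `converged`, `feature_labels`, `settings`.
#' @seealso [detect_events()], [top_features()], [reconstruction_error()]
#' @export
red_nmf <- function(I, k = 6L, max_iter = 2000L, tol = 1e-6,
                    sparsity_weight = 0, smoothness_weight = 0,
                    init_variant = c("plain", "mean"), keep_input = TRUE) {
  init_variant <- match.arg(init_variant)
  labels <- NULL
  meta <- list()
  if (inherits(I, "red_features")) {
    labels <- I$labels
    meta <- list(kind = I$kind, cutoff_A = I$cutoff_A,
                 window_frames = I$window_frames)
    I <- I$values
  }
  if (any(I < 0)) stop("NMF input must be non-negative", call. = FALSE)
  if (sparsity_weight < 0 || smoothness_weight < 0)
    stop("penalty weights must be non-negative", call. = FALSE)
  n <- ncol(I)
  init <- nndsvd_init(I, k, init_variant)
  W <- init$W0
  H <- init$H0
  eps <- 1e-12
  normI2 <- sum(I * I)
  l1 <- sparsity_weight
  sm <- smoothness_weight
  # degree vector for the smoothness penalty's separable (diagonal) part
  deg <- if (n > 1L) c(1, rep(2, n - 2L), 1) else 0

  trace <- numeric(0)
  obj_prev <- Inf
  it <- 0L
  converged <- FALSE
  # HALS (hierarchical alternating least squares): exact projected
  # coordinate minimization over one W column / H row at a time.  Unlike
  # multiplicative updates it can revive entries zeroed by the plain NNDSVD
  # start, which matters for sparse contact data.  The expensive products
  # against I are reused across the objective and the next H update; the
  # cheap row/column sweeps are repeated `inner` times per outer iteration.
  inner <- 3L
  WtI <- crossprod(W, I)
  WtW <- crossprod(W)
  obj_ref <- .nmf_objective(normI2, WtI, WtW, H, l1, sm, sum(W))
  while (it < max_iter) {
    it <- it + 1L
    for (sweep_i in seq_len(inner)) for (j in seq_len(k)) {
      denom <- WtW[j, j]
      if (denom <= eps) next
      g <- WtI[j, ] - WtW[j, ] %*% H + denom * H[j, ]
      if (sm > 0 && n > 1L) {
        # minimize 0.5*denom*||h||^2 - g.h + sm*||diff(h)||^2 :
        # (denom*Id + 2*sm*DtD) h = g, tridiagonal (Thomas), then clip
        H[j, ] <- pmax(.tridiag_solve(denom + 2 * sm * deg, -2 * sm,
                                      as.numeric(g)), 0)
      } else {
        H[j, ] <- pmax(g / denom, 0)
      }
    }
    IHt <- I %*% t(H)
    HHt <- tcrossprod(H)
    for (sweep_i in seq_len(inner)) for (j in seq_len(k)) {
      denom <- HHt[j, j]
      if (denom <= eps) next
      w <- (IHt[, j] - W %*% HHt[, j] + denom * W[, j] - l1) / denom
      W[, j] <- pmax(w, 0)
    }
    # renormalize every iteration: unit-max W columns, inverse factor on H.
    # Leaves W %*% H (and the fit term) unchanged but pins the scale, which
    # the L1 penalty needs: without it W shrinks and H grows without bound.
    scl <- apply(W, 2L, max)
    scl[scl <= 0] <- 1
    W <- sweep(W, 2L, scl, "/")
    H <- sweep(H, 1L, scl, "*")

    WtI <- crossprod(W, I)
    WtW <- crossprod(W)
    obj <- .nmf_objective(normI2, WtI, WtW, H, l1, sm, sum(W))
    trace <- c(trace, obj)
    # decrease measured against the objective at initialization (the
    # scikit-learn NMF convention), so tol has a data-independent meaning
    if (is.finite(obj_prev) &&
        (obj_ref <= 0 || (obj_prev - obj) / obj_ref < tol)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  # normalize: unit-max W columns, inverse on H rows (WH unchanged)
  scl <- apply(W, 2L, max)
  scl[scl <= 0] <- 1
  W <- sweep(W, 2L, scl, "/")
  H <- sweep(H, 1L, scl, "*")

  err <- sqrt(sum((I - W %*% H)^2))
  structure(list(
    W = W, H = H, k = as.integer(k),
    objective_value = err,
    objective_trace = trace,
    n_iterations = it,
    converged = converged,
    feature_labels = labels,
    input = if (keep_input) I else NULL,
    settings = c(list(k = as.integer(k), max_iter = max_iter, tol = tol,
                      sparsity_weight = sparsity_weight,
                      smoothness_weight = smoothness_weight,
                      init_variant = init_variant), meta)),
    class = "red_nmf")
}

#' @rdname red_nmf
#' @param ... passed on to [red_nmf()].
#' @export
factorize <- function(I, k = 6L, ...) red_nmf(I, k = k, ...)

#' Regularized factorization for ligand-protein contacts
#'
#' The ligand contact matrix is small (R features), so fewer components
#' suffice and extra structure helps interpretation: an L1 penalty keeps the
#' archetypes sparse (few residues per binding mode) and a first-difference
#' penalty keeps the temporal weights smooth.  With both weights zero this
#' is exactly [red_nmf()].
#'
#' @inheritParams red_nmf
#' @export
factorize_ligand <- function(I, k = 3L, sparsity_weight = 0.1,
                             smoothness_weight = 1.0, ...) {
  red_nmf(I, k = k, sparsity_weight = sparsity_weight,
          smoothness_weight = smoothness_weight, ...)
}

#' Frobenius reconstruction error
#'
#' @param I the input matrix or `red_features` used for the fit.
#' @param fit a `red_nmf`.
#' @return `||I - W H||_F`.
#' @export
reconstruction_error <- function(I, fit) {
  if (inherits(I, "red_features")) I <- I$values
  stopifnot(inherits(fit, "red_nmf"))
  if (!all(dim(I) == c(nrow(fit$W), ncol(fit$H))))
    stop("shape mismatch between I and the decomposition", call. = FALSE)
  sqrt(sum((I - fit$W %*% fit$H)^2))
}
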