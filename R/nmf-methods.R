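# S3 methods for fitted factorizations.

#' @export
print.red_nmf <- function(x, ...) {
  cat("Non-negative matrix factorization of contact dynamics\n")
  cat(sprintf("  %d features x %d frames, k = %d components\n",
              nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  reconstruction error ||I - WH||_F = %.6g after %d iterations%s\n",
              x$objective_value, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.red_nmf <- function(object, cv_threshold = 0.15, ...) {
  H <- object$H
  mu <- rowMeans(H)
  cv <- apply(H, 1L, stats::sd) / ifelse(mu > 0, mu, NA)
  stat <- tryCatch(classify_stationary(H, cv_threshold), error = function(e) integer())
  rel_err <- if (!is.null(object$input)) {
    object$objective_value / sqrt(sum(object$input^2))
  } else NA_real_
  out <- list(
    k = object$k,
    n_iterations = object$n_iterations,
    converged = object$converged,
    objective_value = object$objective_value,
    relative_error = rel_err,
    component_mean = mu,
    component_cv = cv,
    stationary = stat)
  class(out) <- "summary.red_nmf"
  out
}

#' @export
print.summary.red_nmf <- function(x, ...) {
  cat(sprintf("NMF fit: k = %d, %d iterations%s\n", x$k, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  ||I - WH||_F = %.6g", x$objective_value))
  if (is.finite(x$relative_error))
    cat(sprintf("  (relative %.4f)", x$relative_error))
  cat("\n  component temporal weights:\n")
  tab <- data.frame(component = seq_along(x$component_mean),
                    mean = signif(x$component_mean, 4),
                    cv = signif(x$component_cv, 3),
                    stationary = seq_along(x$component_mean) %in% x$stationary)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.red_nmf <- function(object, ...) object$W

#' Temporal weights of a fit
#'
#' @param object a `red_nmf`.
#' @param ... unused.
#' @return the k x n matrix H.
#' @export
weights.red_nmf <- function(object, ...) object$H

#' @export
fitted.red_nmf <- function(object, ...) object$W %*% object$H

#' @export
residuals.red_nmf <- function(object, ...) {
  if (is.null(object$input))
    stop("fit was made with keep_input = FALSE; residuals unavailable",
         call. = FALSE)
  object$input - fitted(object)
}

#' Project new frames onto fitted archetypes
#'
#' With `newdata = NULL` returns the reconstruction `W H`.  Otherwise solves
#' for non-negative weights `h` of each new column of `newdata` against the
#' fitted `W` by multiplicative updates (W held fixed).
#'
#' @param object a `red_nmf`.
#' @param newdata optional features x m non-negative matrix with the same
#'   feature rows as the fit.
#' @param max_iter,tol solver controls for the projection.
#' @param ... unused.
#' @return the reconstruction, or a k x m weight matrix for `newdata`.
#' @export
predict.red_nmf <- function(object, newdata = NULL, max_iter = 500L,
                            tol = 1e-8, ...) {
  if (is.null(newdata)) return(fitted(object))
  if (inherits(newdata, "red_features")) newdata <- newdata$values
  W <- object$W
  if (nrow(newdata) != nrow(W))
    stop("newdata must have ", nrow(W), " feature rows", call. = FALSE)
  WtX <- crossprod(W, newdata)
  WtW <- crossprod(W)
  H <- matrix(mean(newdata) + 1e-6, object$k, ncol(newdata))
  eps <- 1e-12
  for (i in seq_len(max_iter)) {
    Hn <- H * WtX / (WtW %*% H + eps)
    if (max(abs(Hn - H)) < tol) { H <- Hn; break }
    H <- Hn
  }
  H
}

#' Plot temporal component weights
#'
#' Draws every H row against the frame index, the standard diagnostic for
#' spotting the stationary component and the interlocking rise/fall humps
#' that mark conformational events.
#'
#' @param x a `red_nmf`.
#' @param frame_interval_ns optional; when given, the x axis is time in ns.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.red_nmf <- function(x, frame_interval_ns = NULL, ...) {
  n <- ncol(x$H)
  xs <- seq_len(n) - 1L
  xlab <- "frame"
  if (!is.null(frame_interval_ns)) {
    xs <- frames_to_time(xs, frame_interval_ns)
    xlab <- "time (ns)"
  }
  graphics::matplot(xs, t(x$H), type = "l", lty = 1L,
                    xlab = xlab, ylab = "component weight", ...)
  graphics::legend("topright", legend = paste("component", seq_len(x$k)),
                   col = seq_len(x$k), lty = 1L, cex = 0.7, bty = "n")
  invisible(x)
}
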