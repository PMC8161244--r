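# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All generators route their randomness
# through this so the package never leaks global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average of each row of `m` with window `w` frames.
# Windows are truncated at both edges, so ncol is preserved.  For even w the
# window covers [t - w/2, t + w/2 - 1].
row_moving_average <- function(m, w) {
  if (w < 1L) stop("window must be >= 1 frame", call. = FALSE)
  n <- ncol(m)
  if (w > n) stop("smoothing window (", w, ") exceeds frame count (", n, ")",
                  call. = FALSE)
  left <- floor((w - 1L) / 2L)   # frames before t
  right <- w - 1L - left         # frames after t
  cs <- cbind(0, t(apply(m, 1L, cumsum)))  # cs[, t + 1] = sum of first t cols
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
  dimnames(out) <- dimnames(m)
  out
}

# argmax down columns with ties going to the lowest row index
col_argmax <- function(m) max.col(t(m), ties.method = "first")

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert trajectory frames to simulation time
#'
#' Frame indices are 0-based, so `frames_to_time(0, dt)` is 0 ns.  The frame
#' interval is always an explicit argument: trajectories carry no reliable
#' internal time stamp, and the parse interval (e.g. 0.24 ns) and the interval
#' implied by event bookkeeping (e.g. 2.4 ns) can legitimately differ, so the
#' package never guesses it.
#'
#' @param frames integer vector of 0-based frame indices.
#' @param frame_interval_ns time between consecutive stored frames, in ns.
#' @return numeric vector of times in ns.
#' @seealso [time_to_frames()]
#' @export
#' @examples
#' frames_to_time(620, 2.4)   # 1488 ns
#' frames_to_time(125, 0.24)  # 30 ns
frames_to_time <- function(frames, frame_interval_ns) {
  stopifnot(is.numeric(frame_interval_ns), frame_interval_ns > 0)
  frames * frame_interval_ns
}

#' @rdname frames_to_time
#' @param time_ns numeric vector of times in ns.
#' @export
time_to_frames <- function(time_ns, frame_interval_ns) {
  stopifnot(is.numeric(frame_interval_ns), frame_interval_ns > 0)
  time_ns / frame_interval_ns
}
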