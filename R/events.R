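# Event detection on the temporal weight matrix H.
#
# Components are numbered 1..k (R convention).  Frames are 0-based and all
# event intervals are half-open [start_frame, end_frame).

#' Identify stationary components
#'
#' A stationary component carries the contacts that never change (backbone
#' neighbors, stable cores); its weight trace is flat and substantial.  A
#' component is flagged when the coefficient of variation of its H row is
#' below `cv_threshold` and its mean weight is above 10% of the global mean
#' row weight.  If nothing qualifies, the single lowest-CV component is
#' returned, so downstream dominance analysis always has a baseline to
#' exclude.
#'
#' @param H a k x n non-negative weight matrix, or a `red_nmf`.
#' @param cv_threshold coefficient-of-variation cutoff (default 0.15).
#' @return integer vector of stationary component indices (1-based).
#' @export
classify_stationary <- function(H, cv_threshold = 0.15) {
  if (inherits(H, "red_nmf")) H <- H$H
  stopifnot(is.matrix(H), nrow(H) >= 1L)
  if (any(H < 0)) stop("H must be non-negative", call. = FALSE)
  if (all(H == 0)) stop("degenerate input: H is all zero", call. = FALSE)
  mu <- rowMeans(H)
  sdv <- apply(H, 1L, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, Inf)
  flagged <- which(cv < cv_threshold & mu > 0.1 * mean(mu))
  if (length(flagged) == 0L) flagged <- which.min(cv)
  as.integer(flagged)
}

#' Per-frame dominant component
#'
#' For each frame, the non-stationary component with the largest (lightly
#' re-smoothed) weight; ties go to the lower component index.
#'
#' @inheritParams classify_stationary
#' @param stationary component indices excluded from the argmax (from
#'   [classify_stationary()]).
#' @param window re-smoothing window in frames (default 11) applied before
#'   the argmax to stop single-frame flicker in the trace.
#' @return integer vector of length n: dominant component index per frame.
#' @export
dominance_trace <- function(H, stationary = integer(), window = 11L) {
  if (inherits(H, "red_nmf")) H <- H$H
  active <- setdiff(seq_len(nrow(H)), stationary)
  if (length(active) == 0L)
    stop("no non-stationary components left", call. = FALSE)
  Hs <- row_moving_average(H[active, , drop = FALSE], min(window, ncol(H)))
  active[col_argmax(Hs)]
}

#' Detect rare conformational events
#'
#' An event is a handoff of dominance between two components: the outgoing
#' archetype's weight falls while the incoming one rises through the same
#' frames (the "interlocking humps" signature).  For each switch A -> B in
#' the dominance trace, with crossover frame `t*` (first frame of B's run):
#'
#' * `start_frame` — the last frame before `t*` at which B's smoothed weight
#'   was still below `rise_fraction` of its local hump range
#'   (`min + rise_fraction * (max - min)`, extrema taken over the two
#'   dominance runs extended by one smoothing window);
#' * `end_frame` — the first frame after `t*` at which A's weight has fallen
#'   below the same fractional level of A's hump.
#'
#' Switches whose flanking dominance runs are shorter than
#' `min_duration_frames`, or whose resulting interval is shorter than that,
#' are discarded as flicker.
#'
#' @inheritParams dominance_trace
#' @param rise_fraction fractional level of the local hump range defining
#'   event boundaries (default 0.5).
#' @param min_duration_frames minimum dominance-run and event length
#'   (default 25, about one fifth of the usual 125-frame smoothing window).
#' @param window re-smoothing window for the dominance trace.
#' @return a `red_events` object: data frame with columns `outgoing`,
#'   `incoming` (component indices), `start_frame`, `crossover_frame`,
#'   `end_frame` (0-based, `[start, end)`), plus attributes `stationary`
#'   and `n_frames`.
#' @export
detect_events <- function(H, stationary = NULL, rise_fraction = 0.5,
                          min_duration_frames = 25L, window = 11L) {
  if (inherits(H, "red_nmf")) H <- H$H
  stopifnot(rise_fraction > 0, rise_fraction < 1)
  if (is.null(stationary)) stationary <- classify_stationary(H)
  n <- ncol(H)
  trace <- dominance_trace(H, stationary, window)
  Hs <- row_moving_average(H, min(window, n))

  runs <- rle(trace)
  ends <- cumsum(runs$lengths)            # 1-based inclusive run ends
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ev <- list()
  if (length(runs$values) >= 2L) for (s in 2:length(runs$values)) {
    A <- runs$values[s - 1L]
    B <- runs$values[s]
    if (runs$lengths[s - 1L] < min_duration_frames ||
        runs$lengths[s] < min_duration_frames) next
    tstar <- starts[s]                    # 1-based crossover frame
    lo <- max(1L, starts[s - 1L] - window)
    hi <- min(n, ends[s] + window)
    # B's hump is scored on its rising flank (up to the crossover), A's on
    # its falling flank (from the crossover on); taking extrema over the
    # whole joint window instead would put both half-levels exactly at the
    # crossover and collapse every event to zero width
    vB <- Hs[B, lo:tstar]
    thrB <- min(vB) + rise_fraction * (max(vB) - min(vB))
    vA <- Hs[A, tstar:hi]
    thrA <- min(vA) + rise_fraction * (max(vA) - min(vA))
    below_B <- (lo - 1L) + which(Hs[B, lo:(tstar - 1L)] < thrB)
    start <- if (length(below_B)) max(below_B) else lo
    after <- tstar + which(Hs[A, (tstar + 1L):hi] < thrA)
    end <- if (length(after)) min(after) else hi
    if (end - start < min_duration_frames) next
    ev[[length(ev) + 1L]] <- data.frame(
      outgoing = A, incoming = B,
      start_frame = start - 1L,
      crossover_frame = tstar - 1L,
      end_frame = end - 1L)
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(outgoing = integer(), incoming = integer(),
               start_frame = integer(), crossover_frame = integer(),
               end_frame = integer())
  out <- out[order(out$start_frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, stationary = stationary, n_frames = n,
            rise_fraction = rise_fraction,
            min_duration_frames = min_duration_frames,
            class = c("red_events", "data.frame"))
}

#' @export
print.red_events <- function(x, ...) {
  cat("Rare conformational events:", nrow(x), "detected",
      sprintf("(stationary component%s: %s)\n",
              if (length(attr(x, "stationary")) == 1L) "" else "s",
              paste(attr(x, "stationary"), collapse = ", ")))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Top contributing features of a component
#'
#' Ranks the W column of one component by weight.  For residue-pair
#' features, the symmetric duplicates (i,j)/(j,i) produced by full R^2
#' flattening are collapsed to one unordered pair keeping the larger weight.
#' Ties are broken by lexicographic pair order.
#'
#' @param fit a `red_nmf`.
#' @param component component index (1-based).
#' @param k number of features to keep (default 10).
#' @param collapse_symmetric collapse (i,j)/(j,i) duplicates (default TRUE).
#' @return a `red_ranking` data frame with columns `i`, `j` (0-based residue
#'   indices; `j` absent for residue-kind features), `weight`, `label`.
#' @export
top_features <- function(fit, component, k = 10L, collapse_symmetric = TRUE) {
  stopifnot(inherits(fit, "red_nmf"))
  if (component < 1L || component > fit$k)
    stop("component index out of range: ", component, call. = FALSE)
  w <- fit$W[, component]
  lab <- fit$feature_labels
  if (is.null(lab))
    lab <- data.frame(i = seq_along(w) - 1L)
  df <- cbind(lab, weight = w)
  if (collapse_symmetric && "j" %in% names(df)) {
    lo <- pmin(df$i, df$j)
    hi <- pmax(df$i, df$j)
    key <- paste(lo, hi)
    agg <- tapply(df$weight, key, max)
    parts <- do.call(rbind, strsplit(names(agg), " "))
    df <- data.frame(i = as.integer(parts[, 1L]), j = as.integer(parts[, 2L]),
                     weight = as.numeric(agg))
  }
  if ("j" %in% names(df)) {
    df <- df[order(-df$weight, df$i, df$j), , drop = FALSE]
    df$label <- paste0("(", df$i, ",", df$j, ")")
  } else {
    df <- df[order(-df$weight, df$i), , drop = FALSE]
    df$label <- as.character(df$i)
  }
  df <- utils::head(df, k)
  rownames(df) <- NULL
  structure(df, component = component, class = c("red_ranking", "data.frame"))
}

#' Render an event report
#'
#' Joins events with per-component feature rankings and converts frames to
#' trajectory times.  Residue indices are rendered 1-based (and with BW
#' generic labels when a map is provided).
#'
#' @param events a `red_events`.
#' @param rankings optional named list of `red_ranking` objects, indexed by
#'   component ("1", "2", ...).
#' @param frame_interval_ns time per frame in ns.
#' @param bw_map optional `red_bwmap` used to attach generic labels to
#'   residue indices.
#' @return a data frame with one row per event: components, frame interval,
#'   times in ns, and (when rankings are given) the top features of the
#'   incoming component as a single text column.
#' @export
event_report <- function(events, rankings = NULL, frame_interval_ns, bw_map = NULL) {
  stopifnot(frame_interval_ns > 0)
  rev_bw <- NULL
  if (!is.null(bw_map))
    rev_bw <- stats::setNames(names(bw_map), as.character(unname(bw_map)))
  res_label <- function(idx) {
    out <- as.character(idx + 1L)              # 1-based in reports
    if (!is.null(rev_bw)) {
      hit <- rev_bw[as.character(idx)]
      out[!is.na(hit)] <- hit[!is.na(hit)]
    }
    out
  }
  df <- as.data.frame(events)
  df$start_ns <- frames_to_time(df$start_frame, frame_interval_ns)
  df$crossover_ns <- frames_to_time(df$crossover_frame, frame_interval_ns)
  df$end_ns <- frames_to_time(df$end_frame, frame_interval_ns)
  if (!is.null(rankings) && nrow(df)) {
    df$top_features <- vapply(seq_len(nrow(df)), function(r) {
      rk <- rankings[[as.character(df$incoming[r])]]
      if (is.null(rk)) return(NA_character_)
      if ("j" %in% names(rk))
        paste(sprintf("%s-%s", res_label(rk$i), res_label(rk$j)),
              collapse = "; ")
      else paste(res_label(rk$i), collapse = "; ")
    }, "")
  }
  df
}
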