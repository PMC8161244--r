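# Benchmark: planted-transition recovery on synthetic contact series.

#' Planted-transition recovery study
#'
#' Runs the full detection chain — synthetic contact series with planted
#' transitions, flattening, sliding-window smoothing, NNDSVD-initialized
#' factorization, event detection — over several seeds and scores it
#' against the generator's ground truth.  A planted transition counts as
#' recovered when some detected event's `[start, end)` interval contains
#' the planted transition frame; detected events matching no planted
#' transition count as spurious.
#'
#' The default world is the standard benchmark: 40 residues, 1500 frames,
#' 5 archetypes and 4 transitions, 5% flip noise, 125-frame smoothing,
#' k = 6 (one component absorbs the stationary scaffold).
#'
#' @param n_seeds number of independent replicates.
#' @param R,n,n_states,flip_noise_rate,ramp_frames generator world, see
#'   [generate_contact_series()].
#' @param window_frames smoothing window.
#' @param k factorization rank.
#' @param base_seed replicate i uses seed `base_seed + i - 1`.
#' @param ... further arguments to [detect_events()].
#' @return a data frame with one row per seed: `seed`, `n_planted`,
#'   `n_recovered`, `n_spurious`, `n_events`.
#' @export
event_recovery_study <- function(n_seeds = 20L, R = 40L, n = 1500L,
                                 n_states = 5L, flip_noise_rate = 0.05,
                                 ramp_frames = 50L, window_frames = 125L,
                                 k = 6L, base_seed = 1L, ...) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    g <- generate_contact_series(R = R, n = n, n_states = n_states,
                                 flip_noise_rate = flip_noise_rate,
                                 ramp_frames = ramp_frames,
                                 seed = base_seed + i - 1L)
    I <- smooth_contacts(flatten_tensor(g$tensor), window_frames)
    fit <- red_nmf(I, k = k, keep_input = FALSE)
    ev <- detect_events(fit, ...)
    planted <- g$truth$transition_frames          # 0-based by construction
    hit <- logical(length(planted))
    used <- logical(nrow(ev))
    if (nrow(ev)) for (p in seq_along(planted)) {
      ok <- which(ev$start_frame <= planted[p] & planted[p] < ev$end_frame &
                    !used)
      if (length(ok)) {
        hit[p] <- TRUE
        used[ok[1L]] <- TRUE
      }
    }
    data.frame(seed = base_seed + i - 1L,
               n_planted = length(planted),
               n_recovered = sum(hit),
               n_spurious = sum(!used),
               n_events = nrow(ev))
  })
  do.call(rbind, rows)
}
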