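# One small fitted world reused across event tests
event_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_contact_series(R = 20, n = 800, n_states = 3,
                                   transition_frames = c(270, 530),
                                   flip_noise_rate = 0.05, seed = 21)
      I <- smooth_contacts(flatten_tensor(g$tensor), 75)
      cache <<- list(g = g, fit = red_nmf(I, k = 4, keep_input = FALSE))
    }
    cache
  }
})

test_that("classify_stationary flags flat substantial rows", {
  set.seed(30)
  n <- 500
  H <- rbind(rep(0.8, n),                       # flat
             0.5 + 0.5 * sin(seq_len(n) / 20),  # fluctuating
             abs(rnorm(n, 1, 0.6)))             # noisy
  expect_identical(classify_stationary(H), 1L)
  # all rows identical constants -> all flagged
  Hc <- matrix(0.7, 3, n)
  expect_identical(classify_stationary(Hc), 1:3)
  # none qualifying -> single lowest-CV row
  Hf <- rbind(abs(rnorm(n, 1, 0.9)), abs(rnorm(n, 1, 0.4)))
  expect_identical(classify_stationary(Hf), 2L)
  expect_error(classify_stationary(matrix(0, 2, 10)), "degenerate")
})

test_that("stationary detection singles out the planted flat component", {
  w <- event_world()
  st <- classify_stationary(w$fit$H)
  expect_length(st, 1L)
  cv <- apply(w$fit$H, 1, sd) / rowMeans(w$fit$H)
  expect_identical(st, which.min(cv))
  expect_lt(cv[st], 0.15)
  expect_gt(min(cv[-st]), 0.5)
})

test_that("dominance_trace follows the argmax with lower-index ties", {
  H <- rbind(c(1, 1, 3, 3), c(2, 2, 2, 3))
  expect_identical(dominance_trace(H, integer(), window = 1),
                   c(2L, 2L, 1L, 1L))  # exact tie at frame 4 -> lower index
  H2 <- rbind(rep(1, 10), rep(2, 10))
  expect_identical(dominance_trace(H2, integer(), window = 3), rep(2L, 10))
  expect_error(dominance_trace(H2, 1:2), "non-stationary")
})

test_that("detected events bracket the planted transitions", {
  w <- event_world()
  ev <- detect_events(w$fit)
  expect_s3_class(ev, "red_events")
  expect_identical(nrow(ev), 2L)
  planted <- w$g$truth$transition_frames
  for (p in seq_along(planted)) {
    expect_lte(ev$start_frame[p], planted[p])
    expect_lt(planted[p], ev$end_frame[p])
  }
  # ordering and interval invariants
  expect_true(all(ev$start_frame < ev$crossover_frame))
  expect_true(all(ev$crossover_frame < ev$end_frame))
  expect_true(!is.unsorted(ev$start_frame))
  # stationary component never participates
  st <- attr(ev, "stationary")
  expect_false(any(c(ev$outgoing, ev$incoming) %in% st))
})

test_that("a single non-stationary component yields no events", {
  set.seed(31)
  H <- rbind(rep(1, 300), abs(rnorm(300, 1, 0.5)))
  ev <- detect_events(H, stationary = 1L)
  expect_identical(nrow(ev), 0L)
})

test_that("component permutation relabels but keeps event intervals", {
  w <- event_world()
  ev <- detect_events(w$fit$H, stationary = classify_stationary(w$fit$H))
  perm <- c(3L, 1L, 4L, 2L)
  Hp <- w$fit$H[perm, ]
  evp <- detect_events(Hp, stationary = match(classify_stationary(w$fit$H),
                                              perm))
  expect_identical(nrow(ev), nrow(evp))
  expect_identical(ev$start_frame, evp$start_frame)
  expect_identical(ev$end_frame, evp$end_frame)
  expect_identical(match(ev$incoming, perm), evp$incoming)
})

test_that("event count never exceeds the number of dominance switches", {
  w <- event_world()
  st <- classify_stationary(w$fit$H)
  tr <- dominance_trace(w$fit$H, st)
  n_switch <- sum(diff(tr) != 0)
  ev <- detect_events(w$fit$H, st)
  expect_lte(nrow(ev), n_switch)
})

test_that("top_features ranks, collapses symmetric pairs, breaks ties", {
  W <- matrix(0, 9, 2)
  lab <- expand.grid(i = 0:2, j = 0:2)[, c("i", "j")]
  # (0,2) appears as rows i=0,j=2 and i=2,j=0 with different weights
  W[lab$i == 0 & lab$j == 2, 1] <- 0.4
  W[lab$i == 2 & lab$j == 0, 1] <- 0.9
  W[lab$i == 1 & lab$j == 1, 1] <- 0.9
  W[lab$i == 0 & lab$j == 1, 1] <- 0.2
  fit <- structure(list(W = W, H = matrix(1, 2, 3), k = 2L,
                        feature_labels = lab), class = "red_nmf")
  rk <- top_features(fit, 1, k = 3)
  expect_identical(rk$weight, c(0.9, 0.9, 0.2))
  # tie at 0.9 between pairs (0,2) and (1,1): lexicographic order
  expect_identical(rk$i[1:2], c(0L, 1L))
  expect_identical(rk$j[1:2], c(2L, 1L))
  expect_error(top_features(fit, 5), "out of range")

  # single nonzero entry
  W2 <- matrix(0, 9, 1)
  W2[lab$i == 1 & lab$j == 2, 1] <- 0.7
  fit2 <- structure(list(W = W2, H = matrix(1, 1, 3), k = 1L,
                         feature_labels = lab), class = "red_nmf")
  rk2 <- top_features(fit2, 1, k = 10)
  expect_identical(rk2$weight[1], 0.7)
  expect_identical(c(rk2$i[1], rk2$j[1]), c(1L, 2L))
})

test_that("top 10 of a dense component gives 10 unique unordered pairs", {
  w <- event_world()
  ev <- detect_events(w$fit)
  rk <- top_features(w$fit, ev$incoming[1], k = 10)
  expect_identical(nrow(rk), 10L)
  key <- paste(pmin(rk$i, rk$j), pmax(rk$i, rk$j))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(diff(rk$weight) <= 0))
})

test_that("event reports convert frames to times at the configured interval", {
  ev <- structure(data.frame(outgoing = 2L, incoming = 4L,
                             start_frame = 149L, crossover_frame = 250L,
                             end_frame = 337L),
                  class = c("red_events", "data.frame"))
  rep24 <- event_report(ev, frame_interval_ns = 2.4)
  expect_equal(rep24$start_ns, 149 * 2.4)
  expect_equal(frames_to_time(620, 2.4), 1488)
  expect_equal(frames_to_time(0, 2.4), 0)
  expect_equal(frames_to_time(125, 0.24), 30)
  # BW labels attached to top features when a map is given
  rk <- structure(data.frame(i = 0L, j = 1L, weight = 1,
                             label = "(0,1)"),
                  component = 4L, class = c("red_ranking", "data.frame"))
  out <- event_report(ev, rankings = list(`4` = rk), frame_interval_ns = 2.4,
                      bw_map = bw_map(c("2.43", "6.33"), 0:1))
  expect_identical(out$top_features, "2.43-6.33")
})

test_that("transitions are recovered across counts and noise levels", {
  # desk-scale sweep of the planted world: 1-3 transitions, flip noise
  # 0.02-0.10; every planted transition must be bracketed by an event and
  # spurious events stay <= 1 per run
  cases <- expand.grid(n_states = c(2, 4), noise = c(0.02, 0.10))
  for (r in seq_len(nrow(cases))) {
    ns <- cases$n_states[r]
    g <- generate_contact_series(R = 24, n = 700, n_states = ns,
                                 flip_noise_rate = cases$noise[r],
                                 seed = 40 + r)
    I <- smooth_contacts(flatten_tensor(g$tensor), 75)
    fit <- red_nmf(I, k = ns + 1, keep_input = FALSE)
    ev <- detect_events(fit)
    planted <- g$truth$transition_frames
    hits <- vapply(planted, function(p)
      any(ev$start_frame <= p & p < ev$end_frame), logical(1))
    expect_true(all(hits), info = sprintf("case %d", r))
    expect_lte(nrow(ev) - sum(hits), 1L)
  }
})
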