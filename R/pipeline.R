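# End-to-end pipeline: contacts -> smoothing -> factorization -> events ->
# report, with provenance stamped into every artifact.

.config_defaults <- function() list(
  topology = NULL, trajectory = NULL, bw_map = NULL, output_dir = NULL,
  ligand_resnames = character(), lipid_resnames = .default_lipid,
  water_resnames = .default_water,
  cutoff_A = 3.5, atom_scope = "all", window_frames = 125L,
  frame_interval_ns = NULL, stride = 1L,
  mode = "protein", k = NULL, max_iter = 2000L, tol = 1e-6,
  sparsity_weight = 0.1, smoothness_weight = 1.0,
  init_variant = "plain", dedupe = "full",
  rise_fraction = 0.5, min_duration_frames = 25L, cv_threshold = 0.15,
  dominance_window = 11L, top_k = 10L, seed = 1L)

#' Build and validate a run configuration
#'
#' Unknown keys are rejected; `frame_interval_ns` is required (the tool
#' never infers the frame spacing, see [frames_to_time()]).  `k` defaults
#' to 6 in protein mode and 3 in ligand mode.
#'
#' @param ... configuration values overriding the defaults; see
#'   [run_pipeline()] for their meaning.
#' @return a validated `red_config` list.
#' @export
red_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1L]]) && is.null(names(user)))
    user <- user[[1L]]
  unknown <- setdiff(names(user), names(.config_defaults()))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.config_defaults(), user, keep.null = TRUE)
  if (is.null(cfg$frame_interval_ns))
    stop("configuration error: `frame_interval_ns` is required",
         call. = FALSE)
  if (!cfg$mode %in% c("protein", "ligand"))
    stop("mode must be 'protein' or 'ligand'", call. = FALSE)
  if (is.null(cfg$k)) cfg$k <- if (cfg$mode == "ligand") 3L else 6L
  structure(cfg, class = "red_config")
}

#' Read a key = value configuration file
#'
#' Plain text, one `key = value` pair per line, `#` comments.  Values are
#' parsed as numbers when possible, comma-separated lists become vectors.
#'
#' @param path configuration file path.
#' @param ... overrides applied on top of the file.
#' @return a `red_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[[2L]], "\\s*,\\s*")[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1L)
  do.call(red_config, utils::modifyList(vals, list(...)))
}

.config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(utils::capture.output(utils::str(unclass(cfg))),
                   collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

.provenance <- function(cfg) {
  list(tool = "rednmf",
       version = as.character(utils::packageVersion("rednmf")),
       config = unclass(cfg),
       config_hash = .config_hash(cfg))
}

#' Run the full rare-event-detection pipeline
#'
#' Reads topology + trajectory, builds and smooths contact features
#' (protein residue pairs, or ligand-residue contacts in ligand mode),
#' factorizes them, detects events, ranks the contributing features of
#' every component involved in an event, and writes the artifact bundle to
#' `output_dir`: `weights.csv` (H), `events.csv`/`events.json`,
#' `rankings.csv`, `selections.txt` (per-component residue lists for
#' molecular-viewer highlighting) and `provenance.json`.  Re-running with
#' identical inputs overwrites with identical content.
#'
#' @param config a `red_config` (or arguments for one, via `...`).
#' @param ... passed to [red_config()] when `config` is missing.
#' @return invisibly, a list with `fit`, `events`, `rankings`, `report`
#'   and the output paths.
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- if (inherits(config, "red_config")) config else red_config(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  top <- stage("topology", load_topology(
    cfg$topology, ligand_resnames = cfg$ligand_resnames,
    lipid_resnames = cfg$lipid_resnames, water_resnames = cfg$water_resnames))
  traj <- stage("trajectory", read_frames(
    top, cfg$trajectory, stride = cfg$stride,
    frame_interval_ns = cfg$frame_interval_ns))

  feats <- stage("contacts", {
    if (cfg$mode == "ligand") {
      ligand_contact_matrix(top, traj, cfg$cutoff_A, cfg$atom_scope,
                            window_frames = cfg$window_frames)
    } else {
      tensor <- build_contact_tensor(top, traj, cfg$cutoff_A, cfg$atom_scope)
      smooth_contacts(flatten_tensor(tensor, cfg$dedupe), cfg$window_frames)
    }
  })
  fit <- stage("factorize", {
    if (cfg$mode == "ligand")
      factorize_ligand(feats, k = cfg$k,
                       sparsity_weight = cfg$sparsity_weight,
                       smoothness_weight = cfg$smoothness_weight,
                       max_iter = cfg$max_iter, tol = cfg$tol,
                       init_variant = cfg$init_variant)
    else
      red_nmf(feats, k = cfg$k, max_iter = cfg$max_iter, tol = cfg$tol,
              init_variant = cfg$init_variant)
  })
  stationary <- stage("events", classify_stationary(fit$H, cfg$cv_threshold))
  events <- stage("events", detect_events(
    fit$H, stationary, rise_fraction = cfg$rise_fraction,
    min_duration_frames = cfg$min_duration_frames,
    window = cfg$dominance_window))
  comps <- sort(unique(c(events$outgoing, events$incoming)))
  rankings <- stats::setNames(
    lapply(comps, function(cc) top_features(fit, cc, k = cfg$top_k)),
    as.character(comps))
  bw <- if (!is.null(cfg$bw_map)) read_bw_map(cfg$bw_map, top) else NULL
  report <- event_report(events, rankings, cfg$frame_interval_ns, bw)

  paths <- list()
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(cfg$output_dir, f)
    utils::write.csv(data.frame(component = seq_len(fit$k), fit$H),
                     out("weights.csv"), row.names = FALSE)
    utils::write.csv(report, out("events.csv"), row.names = FALSE)
    jsonlite::write_json(list(events = report,
                              stationary = attr(events, "stationary"),
                              provenance = .provenance(cfg)),
                         out("events.json"), auto_unbox = TRUE, digits = NA)
    rank_df <- do.call(rbind, lapply(names(rankings), function(cc)
      cbind(component = as.integer(cc), as.data.frame(rankings[[cc]]))))
    utils::write.csv(rank_df %||% data.frame(), out("rankings.csv"),
                     row.names = FALSE)
    sel <- vapply(names(rankings), function(cc) {
      rk <- rankings[[cc]]
      res <- sort(unique(c(rk$i, if ("j" %in% names(rk)) rk$j)))
      sprintf("component %s: resid %s", cc, paste(res + 1L, collapse = " "))
    }, "")
    writeLines(sel, out("selections.txt"))
    jsonlite::write_json(.provenance(cfg), out("provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- list(weights = out("weights.csv"), events = out("events.csv"),
                  events_json = out("events.json"),
                  rankings = out("rankings.csv"),
                  selections = out("selections.txt"),
                  provenance = out("provenance.json"))
  }
  invisible(list(fit = fit, events = events, rankings = rankings,
                 report = report, paths = paths, config = cfg))
}

#' Compute per-frame structural metrics
#'
#' Metric specs are lists: `list(type = "cavity_waters")`,
#' `list(type = "wobble", pivot = "7.57", pre = c("7.46","7.56"),
#' post = c("7.58","7.68"))`, or `list(type = "distance", a = "1.52",
#' b = "7.67", atom = "CA")`.  All BW-addressed metrics need `bw_map` in
#' the config.
#'
#' @param config a `red_config` (needs `topology`, `trajectory`,
#'   `bw_map`).
#' @param metrics list of metric specs.
#' @param output_csv optional path; when given the table is also written.
#' @return a data frame: `frame`, `time_ns`, one column per metric.
#' @export
run_metrics <- function(config, metrics, output_csv = NULL) {
  cfg <- if (inherits(config, "red_config")) config else red_config(config)
  top <- load_topology(cfg$topology, ligand_resnames = cfg$ligand_resnames,
                       lipid_resnames = cfg$lipid_resnames,
                       water_resnames = cfg$water_resnames)
  traj <- read_frames(top, cfg$trajectory, stride = cfg$stride,
                      frame_interval_ns = cfg$frame_interval_ns)
  bw <- if (!is.null(cfg$bw_map)) read_bw_map(cfg$bw_map, top) else NULL
  out <- data.frame(frame = traj$frame_index, time_ns = traj$time_ns)
  for (ms in metrics) {
    name <- ms$name %||% ms$type
    col <- switch(ms$type,
      cavity_waters = vapply(seq_len(traj$n_frames) - 1L, function(t)
        as.numeric(cavity_water_count(top, traj, bw,
                                      ms$criteria %||% cavity_criteria(),
                                      frame_index = t, quiet = TRUE)),
        numeric(1L)),
      wobble = vapply(seq_len(traj$n_frames) - 1L, function(t)
        wobble_angle(top, traj, ms$pivot, ms$pre, ms$post, bw,
                     frame_index = t)$wobble_angle_deg, numeric(1L)),
      bend = vapply(seq_len(traj$n_frames) - 1L, function(t)
        wobble_angle(top, traj, ms$pivot, ms$pre, ms$post, bw,
                     frame_index = t)$bend_angle_deg, numeric(1L)),
      distance = pair_distance_series(top, traj, ms$a, ms$b,
                                      ms$atom %||% "CA", bw),
      stop("validation error: unknown metric type '", ms$type, "'",
           call. = FALSE))
    out[[name]] <- col
  }
  if (!is.null(output_csv)) utils::write.csv(out, output_csv, row.names = FALSE)
  out
}
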