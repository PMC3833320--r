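#' Pipeline configuration
#'
#' Nested list of every stage's parameters, merged from the package defaults,
#' an optional YAML file and programmatic overrides; all values are validated
#' at load time by constructing the stage parameter objects.
#'
#' The default LIAC profile here is the *tracking* profile (large discharge,
#' small recharge): charge memories fade within about two frames, so the
#' person box follows the current silhouette closely, which is what the fall
#' indicators need. [liac_params()] alone defaults to the balanced
#' trail-preserving profile (discharge = recharge = 32) that keeps full
#' motion-history trails alive while motion continues.
#'
#' Sections and keys: `liac` (`n_bands, discharge, recharge, hom_min`),
#' `post` (`threshold, min_height, max_height, min_width, max_width,
#' min_compactness, max_compactness`), `window` (`fall_time_ms, sliding`),
#' `fuzzy` (`rules_path, crossover, step`), `monitor`
#' (`inactivity_limit_ms`), `meta` (`interval_ms, channels`).
#'
#' @param path optional YAML config file; its keys override the defaults.
#' @param overrides optional nested list applied on top of the file.
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    liac = list(n_bands = 8, discharge = 128, recharge = 16, hom_min = 1),
    post = list(threshold = 128, min_height = 20, max_height = NA,
                min_width = 10, max_width = NA,
                min_compactness = 0.2, max_compactness = 1.0),
    window = list(fall_time_ms = 1200, sliding = FALSE),
    fuzzy = list(rules_path = NULL, crossover = 40, step = 0.05),
    monitor = list(inactivity_limit_ms = 30000),
    meta = list(interval_ms = 200, channels = 1)
  )
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' @rdname default_config
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_fw("config file not found: %s", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  # constructing the stage objects enforces every invariant; fail fast
  config_liac_params(cfg)
  config_blob_limits(cfg)
  window_length(cfg$window$fall_time_ms, cfg$meta$interval_ms)
  monitor_init(cfg$monitor$inactivity_limit_ms)
  sequence_meta(cfg$meta$interval_ms, cfg$meta$channels)
  invisible(cfg)
}

config_liac_params <- function(cfg) {
  liac_params(n_bands = cfg$liac$n_bands, discharge = cfg$liac$discharge,
              recharge = cfg$liac$recharge, hom_min = cfg$liac$hom_min,
              threshold = cfg$post$threshold)
}

config_blob_limits <- function(cfg) {
  blob_limits(min_height = cfg$post$min_height,
              max_height = cfg$post$max_height,
              min_width = cfg$post$min_width,
              max_width = cfg$post$max_width,
              min_compactness = cfg$post$min_compactness,
              max_compactness = cfg$post$max_compactness)
}

#' Run the full fall-recognition pipeline
#'
#' Segments the frames (LIAC, binarise, open, blob filter), windows the box
#' stream over the fall time, scores every window with the fuzzy system and
#' feeds the decisions through the inactivity monitor. When `out_dir` is
#' given, writes `blobs.csv`, `indicators.csv`, `decisions.csv` (columns
#' `window,score,is_fall,pattern,event`) and, optionally, the cleaned masks
#' as `mask_NNNN.pgm`.
#'
#' @param frames list of [video_frame()] objects, or a directory/glob
#'   accepted by [load_sequence()].
#' @param config configuration list from [load_config()].
#' @param out_dir output directory (`NULL` for no files).
#' @param write_masks also write per-frame masks (needs `out_dir`).
#' @return (invisibly) list with `rois`, `indicators`, `decisions` and
#'   `events` (data frame `window, time_ms, event`).
#' @examples
#' scene <- gen_fall_sequence(scenario_spec("walk_then_fall", seed = 3))
#' res <- run_pipeline(scene$frames)
#' res$decisions
#' @export
run_pipeline <- function(frames, config = load_config(), out_dir = NULL,
                         write_masks = FALSE) {
  if (is.character(frames)) {
    meta <- sequence_meta(config$meta$interval_ms, config$meta$channels)
    frames <- load_sequence(frames, meta)
  }
  params <- config_liac_params(config)
  limits <- config_blob_limits(config)
  seg <- segment_frames(frames, params = params, limits = limits,
                        keep_masks = write_masks || !is.null(out_dir))

  n <- window_length(config$window$fall_time_ms, config$meta$interval_ms)
  indicators <- stream_windows(seg$rois, n, sliding = config$window$sliding)

  fis <- fall_system(rules = config$fuzzy$rules_path,
                     crossover = config$fuzzy$crossover,
                     step = config$fuzzy$step)
  decisions <- predict(fis, indicators)

  mon <- monitor_init(config$monitor$inactivity_limit_ms)
  events <- data.frame(window = integer(0), time_ms = numeric(0),
                       event = character(0))
  ev_col <- character(nrow(decisions))
  for (i in seq_len(nrow(decisions))) {
    now_ms <- (decisions$last_frame[i] + 1) * config$meta$interval_ms
    step_out <- monitor_step(mon, fis, decisions[i, ], decisions[i, ], now_ms)
    mon <- step_out$state
    if (length(step_out$events)) {
      events <- rbind(events, data.frame(window = decisions$window[i],
                                         time_ms = now_ms,
                                         event = step_out$events))
      ev_col[i] <- paste(step_out$events, collapse = ";")
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    blob_rows <- do.call(rbind, lapply(seq_along(seg$rois), function(i) {
      r <- seg$rois[[i]]
      if (is.null(r)) NULL else cbind(data.frame(frame = i - 1L), r)
    }))
    if (is.null(blob_rows))
      blob_rows <- data.frame(frame = integer(0), x = integer(0),
                              y = integer(0), w = integer(0), h = integer(0),
                              area = integer(0), compactness = numeric(0))
    write_blob_csv(blob_rows, file.path(out_dir, "blobs.csv"))
    write_indicator_csv(indicators, file.path(out_dir, "indicators.csv"))
    dec_lines <- c("window,score,is_fall,pattern,event",
                   if (nrow(decisions) > 0)
                     sprintf("%d,%.2f,%s,%d,%s", decisions$window,
                             decisions$score,
                             tolower(as.character(decisions$is_fall)),
                             decisions$pattern, ev_col))
    writeLines(dec_lines, file.path(out_dir, "decisions.csv"))
    if (write_masks) {
      for (i in seq_along(seg$masks))
        write_pgm(seg$masks[[i]],
                  file.path(out_dir, sprintf("mask_%04d.pgm", i - 1L)))
    }
  }
  invisible(list(rois = seg$rois, indicators = indicators,
                 decisions = decisions, events = events))
}
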