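#' Post-fall inactivity monitor
#'
#' A small state machine layered over the per-window fall decisions. In
#' `detection` mode a positive fall decision switches to `inactivity`
#' monitoring (event `FALL_DETECTED`). While monitoring, a window whose box
#' looks upright again (`mu_LOW(whr) > 0.5`) returns to `detection`
#' (event `RECOVERED`); if instead the inactivity limit elapses with no
#' stand-up, the terminal `alarm` mode is entered (event `ALARM`).
#'
#' @param inactivity_limit_ms how long the person may stay down before the
#'   alarm, in milliseconds (default 30000, i.e. 30 s).
#' @return an object of class `monitor_state` (mode `detection`).
#' @export
monitor_init <- function(inactivity_limit_ms = 30000) {
  if (inactivity_limit_ms <= 0) stop_fw("inactivity_limit_ms must be > 0")
  structure(list(mode = "detection", fall_detected_at_ms = NULL,
                 inactivity_limit_ms = inactivity_limit_ms,
                 last_ms = -Inf),
            class = "monitor_state")
}

#' @export
print.monitor_state <- function(x, ...) {
  cat(sprintf("<monitor_state: mode %s%s, limit %g ms>\n", x$mode,
              if (!is.null(x$fall_detected_at_ms))
                sprintf(", fall at %g ms", x$fall_detected_at_ms) else "",
              x$inactivity_limit_ms))
  invisible(x)
}

#' Advance the inactivity monitor by one window
#'
#' @param state a [monitor_init()] state.
#' @param fis the [fall_system()] (used to judge stand-up posture).
#' @param decision one-row data frame with at least `is_fall` (e.g. a row of
#'   [predict.fall_fis()] output).
#' @param iv the window's indicator row (used for the stand-up test).
#' @param now_ms current timestamp in milliseconds; must not decrease across
#'   calls.
#' @return `list(state = updated state, events = character vector)` where
#'   events is any of `"FALL_DETECTED"`, `"RECOVERED"`, `"ALARM"`.
#' @export
monitor_step <- function(state, fis, decision, iv, now_ms) {
  if (now_ms < state$last_ms)
    stop_fw("now_ms must be non-decreasing (got %g after %g)",
            now_ms, state$last_ms)
  state$last_ms <- now_ms
  events <- character(0)
  if (state$mode == "detection") {
    if (isTRUE(decision$is_fall)) {
      state$mode <- "inactivity"
      state$fall_detected_at_ms <- now_ms
      events <- "FALL_DETECTED"
    }
  } else if (state$mode == "inactivity") {
    upright <- fuzzify(fis, iv)$WidthToHeightRatio[["LOW"]] > 0.5
    if (upright) {
      state$mode <- "detection"
      state$fall_detected_at_ms <- NULL
      events <- "RECOVERED"
    } else if (now_ms - state$fall_detected_at_ms >=
               state$inactivity_limit_ms) {
      state$mode <- "alarm"
      events <- "ALARM"
    }
  }
  # alarm mode is terminal until reset via monitor_init()
  list(state = state, events = events)
}
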