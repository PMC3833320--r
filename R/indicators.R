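#' Frames per fall-time window
#'
#' The indicator stage analyses non-overlapping windows of
#' `round(fall_time_ms / interval_ms)` frames; the fall indicators compare
#' the first and last person box of each window.
#'
#' @param fall_time_ms analysis window length in milliseconds (typically
#'   1200, i.e. 1.2 s; sensible values span 1-3 s).
#' @param interval_ms capture interval in milliseconds.
#' @return integer number of frames per window (>= 2).
#' @examples
#' window_length(1200, 200)  # 6 frames
#' @export
window_length <- function(fall_time_ms = 1200, interval_ms = 200) {
  if (fall_time_ms <= 0 || interval_ms <= 0)
    stop_fw("fall_time_ms and interval_ms must be positive")
  if (fall_time_ms < 2 * interval_ms)
    stop_fw("window too short: fall_time_ms must be at least 2 * interval_ms")
  as.integer(round(fall_time_ms / interval_ms))
}

#' Fall indicators from the first and last box of a window
#'
#' Computes the six crisp inputs of the fuzzy fall detector from the person
#' bounding box at the start (`first`) and end (`last`) of a fall-time
#' window:
#' * `whr` — width-to-height ratio of the final box (low standing, high lying);
#' * `height_change` — initial height over final height (> 1 when the person
#'   gets lower);
#' * `h_vel` — horizontal velocity ratio: absolute height change over the
#'   initial height (the height change realised within one fall time,
#'   normalised by its maximum);
#' * `v_vel` — vertical velocity ratio: absolute width change over the
#'   initial width;
#' * `direction` — 1 when the top-left corner moved right (`last$x > first$x`),
#'   else 0;
#' * `position_change` — 1 when the top-left corner rose (`last$y < first$y`),
#'   else 0; flags falls from a lying position (e.g. out of bed).
#'
#' @param first,last one-row blob data frames (columns `x, y, w, h`).
#' @return one-row data frame with the six indicator columns.
#' @examples
#' compute_indicators(data.frame(x = 10, y = 5, w = 30, h = 60),
#'                    data.frame(x = 12, y = 40, w = 55, h = 25))
#' @export
compute_indicators <- function(first, last) {
  if (is.null(first) || is.null(last))
    stop_fw("both the first and last box of the window must be present")
  if (first$w < 1 || first$h < 1 || last$w < 1 || last$h < 1)
    stop_fw("boxes must have positive width and height")
  data.frame(
    whr = last$w / last$h,
    height_change = first$h / last$h,
    h_vel = abs(first$h - last$h) / first$h,
    v_vel = abs(first$w - last$w) / first$w,
    direction = as.integer(last$x > first$x),
    position_change = as.integer(last$y < first$y)
  )
}

#' Indicator vectors for consecutive windows of a box stream
#'
#' Splits the per-frame ROI stream into non-overlapping windows of `n` frames
#' and computes one indicator row per window from its first and last box.
#' Windows whose first or last frame has no box are skipped with a warning.
#'
#' @param rois list with one element per frame: a one-row blob data frame or
#'   `NULL` when no person was found.
#' @param n frames per window, from [window_length()].
#' @param sliding if `TRUE`, windows advance one frame at a time instead of
#'   `n` frames.
#' @return data frame with columns `window` (1-based index of the window),
#'   `first_frame`, `last_frame` (0-based frame indices) and the six
#'   indicator columns.
#' @export
stream_windows <- function(rois, n, sliding = FALSE) {
  n <- as.integer(n)
  if (n < 2) stop_fw("window length must be >= 2 frames")
  starts <- if (sliding) seq_len(max(length(rois) - n + 1, 0)) else
    seq(1L, by = n, length.out = length(rois) %/% n)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- i0 + n - 1L
    first <- rois[[i0]]; last <- rois[[i1]]
    if (is.null(first) || is.null(last)) {
      warning(sprintf("window %d (frames %d-%d) skipped: missing person box",
                      k, i0 - 1L, i1 - 1L), call. = FALSE)
      next
    }
    iv <- compute_indicators(first, last)
    out[[k]] <- cbind(data.frame(window = k, first_frame = i0 - 1L,
                                 last_frame = i1 - 1L), iv)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(window = integer(0), first_frame = integer(0),
                      last_frame = integer(0), whr = numeric(0),
                      height_change = numeric(0), h_vel = numeric(0),
                      v_vel = numeric(0), direction = integer(0),
                      position_change = integer(0)))
  do.call(rbind, out)
}

#' Write indicator rows as CSV
#'
#' Dialect: header `window,whr,height_change,h_vel,v_vel,direction,
#' position_change`, continuous fields at 3 decimals.
#'
#' @param indicators data frame from [stream_windows()].
#' @param path file to write.
#' @return the path, invisibly.
#' @export
write_indicator_csv <- function(indicators, path) {
  header <- "window,whr,height_change,h_vel,v_vel,direction,position_change"
  lines <- if (nrow(indicators) == 0) character(0) else
    sprintf("%d,%.3f,%.3f,%.3f,%.3f,%d,%d",
            as.integer(indicators$window), indicators$whr,
            indicators$height_change, indicators$h_vel, indicators$v_vel,
            as.integer(indicators$direction),
            as.integer(indicators$position_change))
  writeLines(c(header, lines), path)
  invisible(path)
}
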