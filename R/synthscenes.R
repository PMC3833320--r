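#' Synthetic fall-scene specification
#'
#' Describes a deterministic synthetic scene: a single bright (infrared) or
#' coloured rectangle person on a noisy uniform background, animated from its
#' start posture to its end posture over one fall time. The scenarios mirror
#' the situations the detector is built for: static falls from standing
#' (frontal/backward and lateral-right), falls from sitting, a fall from a
#' lying position (the risen-corner case), a kneeling false fall, a dynamic
#' fall while walking, and a fully static scene.
#'
#' @param scenario one of `"stand_fall_frontal"`, `"stand_fall_right"`,
#'   `"sit_fall_frontal"`, `"sit_fall_right"`, `"lying_fall"`,
#'   `"kneel_false"`, `"walk_then_fall"`, `"static_scene"`.
#' @param width,height image size in pixels.
#' @param person_w,person_h upright person box size in pixels.
#' @param person_intensity,background_intensity 0..255; scalars for infrared
#'   (1 channel) or length-3 vectors for colour. The background is uniform;
#'   the person carries a per-pixel texture in body coordinates (seeded,
#'   uniform in `person_intensity +/- texture_amp`), so any body motion
#'   re-maps the texture and the whole silhouette changes intensity band —
#'   a flat rectangle would expose only its edges to a motion segmenter.
#' @param texture_amp half-range of the person texture; 0 gives a flat
#'   silhouette.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param interval_ms capture interval; `fall_time_ms` the fall duration.
#' @param channels 1 (infrared) or 3 (colour).
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = "stand_fall_frontal",
                          width = 96, height = 72,
                          person_w = 18, person_h = 54,
                          person_intensity = if (channels == 1) 210 else
                            c(220, 180, 80),
                          background_intensity = if (channels == 1) 16 else
                            c(16, 112, 144),
                          texture_amp = 45,
                          noise_sd = 2, interval_ms = 200,
                          fall_time_ms = 1200, channels = 1, seed = 1) {
  scenarios <- c("stand_fall_frontal", "stand_fall_right",
                 "sit_fall_frontal", "sit_fall_right", "lying_fall",
                 "kneel_false", "walk_then_fall", "static_scene")
  if (!scenario %in% scenarios)
    stop_fw("unknown scenario '%s'", scenario)
  if (!channels %in% c(1, 3)) stop_fw("channels must be 1 or 3")
  if (length(person_intensity) != channels ||
      length(background_intensity) != channels)
    stop_fw("intensities must have one value per channel")
  if (any(person_intensity < 0 | person_intensity > 255) ||
      any(background_intensity < 0 | background_intensity > 255))
    stop_fw("intensities must lie in [0, 255]")
  if (noise_sd < 0) stop_fw("noise_sd must be >= 0")
  if (texture_amp < 0) stop_fw("texture_amp must be >= 0")
  structure(list(scenario = scenario, width = width, height = height,
                 person_w = person_w, person_h = person_h,
                 person_intensity = person_intensity,
                 background_intensity = background_intensity,
                 texture_amp = texture_amp,
                 noise_sd = noise_sd, interval_ms = interval_ms,
                 fall_time_ms = fall_time_ms, channels = as.integer(channels),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# Start box, end box, true pattern and timing for a scenario. Boxes are
# (x, y, w, h), 0-based; the "ground" keeps boxes bottom-aligned. A standing
# fall swaps the box to (0.9 h, 0.9 w); frontal falls widen symmetrically
# about the body centre, lateral-right falls displace the corner rightward.
scenario_plan <- function(spec) {
  g <- spec$height - 4                       # ground line (box bottoms)
  pw <- spec$person_w; ph <- spec$person_h
  up <- c(x = 30, y = g - ph, w = pw, h = ph)
  lw <- round(0.9 * ph); lh <- round(0.9 * pw)   # lying box from standing
  centre <- function(b) b[["x"]] + b[["w"]] / 2
  lying_from <- function(b, wl, hl, dx = NULL) {
    x <- if (is.null(dx)) round(centre(b) - wl / 2) else b[["x"]] + dx
    c(x = x, y = g - hl, w = wl, h = hl)
  }
  n_fall <- window_length(spec$fall_time_ms, spec$interval_ms)
  plan <- switch(spec$scenario,
    stand_fall_frontal = list(start = up, end = lying_from(up, lw, lh),
                              pattern = 1L),
    stand_fall_right = list(start = up, end = lying_from(up, lw, lh, dx = 6),
                            pattern = 2L),
    sit_fall_frontal = {
      sit <- c(x = 30, y = g - round(0.6 * ph), w = pw, h = round(0.6 * ph))
      list(start = sit, end = lying_from(sit, 60, 26), pattern = 4L)
    },
    sit_fall_right = {
      sit <- c(x = 30, y = g - round(0.6 * ph), w = pw, h = round(0.6 * ph))
      list(start = sit, end = lying_from(sit, 60, 26, dx = 6), pattern = 5L)
    },
    lying_fall = list(start = c(x = 20, y = g - 16, w = 49, h = 16),
                      end = c(x = 24, y = g - 16 - 10, w = 52, h = 14),
                      pattern = 7L),
    kneel_false = list(start = up,
                       end = c(x = 30, y = g - round(0.75 * ph), w = pw,
                               h = round(0.75 * ph)),
                       pattern = 0L, fall_frames = 2L * n_fall),
    walk_then_fall = {
      start <- c(x = 12, y = g - ph, w = pw, h = ph)
      list(start = start, end = NULL, pattern = 1L, walk_frames = 2L * n_fall,
           walk_step = 2L)
    },
    static_scene = list(start = up, end = up, pattern = 0L)
  )
  plan$n_fall <- n_fall
  plan$g <- g
  plan
}

# Per-frame true boxes for a scenario: pre-fall hold, linear interpolation
# over the fall frames, post-fall hold.
truth_boxes <- function(spec) {
  plan <- scenario_plan(spec)
  n <- plan$n_fall
  if (spec$scenario == "static_scene") {
    onset <- NA_integer_
    boxes <- matrix(rep(plan$start, 3L * n), ncol = 4, byrow = TRUE)
  } else if (spec$scenario == "walk_then_fall") {
    wf <- plan$walk_frames
    walk <- t(vapply(seq_len(wf) - 1L, function(i) {
      b <- plan$start; b[["x"]] <- b[["x"]] + plan$walk_step * i; b
    }, numeric(4)))
    start <- plan$start
    start[["x"]] <- start[["x"]] + plan$walk_step * (wf - 1L)
    lw <- round(0.9 * spec$person_h); lh <- round(0.9 * spec$person_w)
    end <- c(x = round(start[["x"]] + start[["w"]] / 2 - lw / 2),
             y = plan$g - lh, w = lw, h = lh)
    onset <- wf
    # the box moves on every fall frame: frame onset is already 1/n into the
    # fall, frame onset + n - 1 is the end posture
    fall <- t(vapply(seq_len(n), function(i) {
      f <- i / n
      round(start + f * (end - start))
    }, numeric(4)))
    post <- matrix(rep(round(end), n), ncol = 4, byrow = TRUE)
    boxes <- rbind(walk, fall, post)
  } else {
    nf <- if (is.null(plan$fall_frames)) n else plan$fall_frames
    onset <- n
    pre <- matrix(rep(plan$start, n), ncol = 4, byrow = TRUE)
    fall <- t(vapply(seq_len(nf), function(i) {
      f <- i / nf
      round(plan$start + f * (plan$end - plan$start))
    }, numeric(4)))
    post <- matrix(rep(round(plan$end), n), ncol = 4, byrow = TRUE)
    boxes <- rbind(pre, fall, post)
  }
  colnames(boxes) <- c("x", "y", "w", "h")
  df <- as.data.frame(boxes)
  df <- cbind(data.frame(frame = seq_len(nrow(df)) - 1L), df)
  bad <- df$x < 0 | df$y < 0 | df$x + df$w > spec$width |
    df$y + df$h > spec$height
  if (any(bad))
    stop_fw("scenario box escapes the image at frame %d",
            df$frame[which(bad)[1]])
  list(boxes = df, pattern = plan$pattern, onset = onset)
}

# Per-pixel body texture in upright person coordinates, one layer per channel.
sample_texture <- function(spec) {
  lapply(seq_len(spec$channels), function(ch) {
    base <- spec$person_intensity[ch]
    matrix(clamp(round(runif(spec$person_h * spec$person_w,
                             base - spec$texture_amp,
                             base + spec$texture_amp)), 0, 255),
           spec$person_h, spec$person_w)
  })
}

render_frame <- function(spec, box, texture) {
  rows <- (box$y + 1):(box$y + box$h)
  cols <- (box$x + 1):(box$x + box$w)
  # nearest-neighbour mapping of the body texture onto the current box
  tr <- ceiling(seq_len(box$h) * spec$person_h / box$h)
  tc <- ceiling(seq_len(box$w) * spec$person_w / box$w)
  render_channel <- function(bg, tex) {
    m <- matrix(bg, spec$height, spec$width)
    m[rows, cols] <- tex[tr, tc, drop = FALSE]
    if (spec$noise_sd > 0)
      m <- m + rnorm(length(m), sd = spec$noise_sd)
    m <- round(clamp(m, 0, 255))
    storage.mode(m) <- "integer"
    m
  }
  if (spec$channels == 1)
    return(render_channel(spec$background_intensity, texture[[1]]))
  px <- array(0L, dim = c(spec$height, spec$width, 3))
  for (ch in 1:3)
    px[, , ch] <- render_channel(spec$background_intensity[ch], texture[[ch]])
  px
}

#' Generate a synthetic falling-person frame sequence
#'
#' Renders the scenario's animated rectangle with additive Gaussian noise
#' (clamped to \[0, 255\]); the same spec and seed always reproduce the same
#' frames bit for bit.
#'
#' @param spec a [scenario_spec()].
#' @return list with `frames` (list of [video_frame()]), `truth` (data frame
#'   `frame, x, y, w, h` of true boxes), `pattern` (true label, 0 for the
#'   false-fall and static scenarios) and `onset` (0-based fall onset frame,
#'   `NA` for the static scene).
#' @examples
#' scene <- gen_fall_sequence(scenario_spec("stand_fall_frontal", seed = 7))
#' length(scene$frames); scene$pattern
#' @export
gen_fall_sequence <- function(spec) {
  tr <- truth_boxes(spec)
  frames <- with_seed(spec$seed, {
    texture <- sample_texture(spec)
    lapply(seq_len(nrow(tr$boxes)), function(i) {
      video_frame(render_frame(spec, tr$boxes[i, ], texture), index = i - 1L,
                  timestamp_ms = (i - 1) * spec$interval_ms)
    })
  })
  list(frames = frames, truth = tr$boxes, pattern = tr$pattern,
       onset = tr$onset)
}

#' Generate an indicator-row stream with known ground truth
#'
#' Computes the per-window indicator rows directly from the scenario's true
#' boxes (bypassing the vision stages) and adds Gaussian jitter to the
#' continuous fields; crisp fields are left untouched. Useful for testing
#' the classifier in isolation.
#'
#' @param spec a [scenario_spec()] (its `noise_sd` is ignored here).
#' @param jitter_sd standard deviation of the jitter on `whr`,
#'   `height_change`, `h_vel` and `v_vel`.
#' @param seed jitter seed; defaults to the spec's.
#' @return list with `indicators` (data frame as from [stream_windows()])
#'   and `pattern` (the true label).
#' @export
gen_indicator_stream <- function(spec, jitter_sd = 0, seed = spec$seed) {
  if (jitter_sd < 0) stop_fw("jitter_sd must be >= 0")
  tr <- truth_boxes(spec)
  n <- window_length(spec$fall_time_ms, spec$interval_ms)
  rois <- lapply(seq_len(nrow(tr$boxes)), function(i)
    tr$boxes[i, c("x", "y", "w", "h")])
  ind <- stream_windows(rois, n)
  if (jitter_sd > 0 && nrow(ind) > 0) {
    ind <- with_seed(seed, {
      for (col in c("whr", "height_change", "h_vel", "v_vel")) {
        ind[[col]] <- ind[[col]] + rnorm(nrow(ind), sd = jitter_sd)
      }
      ind$whr <- pmax(ind$whr, 0.01)
      ind$height_change <- pmax(ind$height_change, 0.01)
      ind$h_vel <- pmax(ind$h_vel, 0)
      ind$v_vel <- pmax(ind$v_vel, 0)
      ind
    })
  }
  list(indicators = ind, pattern = tr$pattern)
}
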