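#' LIAC engine parameters
#'
#' Tunables of the accumulative-computation segmentation engine. Charges live
#' in `[q_min, q_max]`; a pixel entering a band saturates to `q_max`, a pixel
#' staying in its band is decremented by `discharge` per step, and lateral
#' inhibition adds `recharge` (at most once per step) to partially charged
#' pixels 4-connected to a saturated pixel through charged paths.
#'
#' @param n_bands number of intensity bands N (>= 2) per channel.
#' @param q_min,q_max charge bounds (defaults 0 and 255).
#' @param discharge charge lost per step by a pixel that stays in its band.
#' @param recharge lateral-inhibition increment per step.
#' @param hom_min minimum charge for a pixel to join a homogenisation
#'   component (must exceed `q_min`).
#' @param threshold binarisation level used downstream ([binarise()]).
#' @return an object of class `liac_params`.
#' @export
liac_params <- function(n_bands = 8, q_min = 0, q_max = 255, discharge = 32,
                        recharge = 32, hom_min = 1, threshold = 128) {
  if (n_bands < 2) stop_fw("n_bands must be >= 2")
  if (q_min >= q_max) stop_fw("q_min must be < q_max")
  span <- q_max - q_min
  if (discharge <= 0 || discharge > span)
    stop_fw("discharge must lie in (0, q_max - q_min]")
  if (recharge <= 0 || recharge > span)
    stop_fw("recharge must lie in (0, q_max - q_min]")
  if (hom_min <= q_min || hom_min > q_max)
    stop_fw("hom_min must lie in (q_min, q_max]")
  if (threshold <= q_min || threshold > q_max)
    stop_fw("threshold must lie in (q_min, q_max]")
  structure(list(n_bands = as.integer(n_bands), q_min = q_min, q_max = q_max,
                 discharge = discharge, recharge = recharge,
                 hom_min = hom_min, threshold = threshold),
            class = "liac_params")
}

#' Initialise LIAC working memory
#'
#' All charges start at `q_min`; the previous band map is absent, so the first
#' [liac_update_charge()] only records its band map without charging.
#'
#' @param height,width frame dimensions in pixels.
#' @param channels 1 or 3.
#' @param params a [liac_params()].
#' @return an object of class `liac_state`.
#' @export
liac_init <- function(height, width, channels = 1, params = liac_params()) {
  if (!channels %in% c(1, 3)) stop_fw("channels must be 1 or 3")
  q <- lapply(seq_len(channels), function(ch)
    array(params$q_min, dim = c(height, width, params$n_bands)))
  structure(list(q = q, prev = NULL, height = as.integer(height),
                 width = as.integer(width), channels = as.integer(channels),
                 params = params),
            class = "liac_state")
}

#' @export
print.liac_state <- function(x, ...) {
  cat(sprintf("<liac_state %dx%d, %d channel(s), %d bands, %s>\n",
              x$width, x$height, x$channels, x$params$n_bands,
              if (is.null(x$prev)) "uninitialised" else "running"))
  invisible(x)
}

# Extract channel ch of a band map stored as h x w (1 ch) or h x w x 3.
bandmap_channel <- function(bandmap, ch) {
  if (length(dim(bandmap)) == 3) band_slice(bandmap, ch) else bandmap
}

# Slice band b of an h x w x N array as an h x w matrix (dims preserved).
band_slice <- function(arr, b) {
  m <- arr[, , b, drop = FALSE]
  dim(m) <- dim(arr)[1:2]
  m
}

#' Quantize a frame into intensity bands
#'
#' Uniform scalar quantization: intensity `v` maps to band
#' `floor(v * n_bands / 256)`, each channel independently.
#'
#' @param frame a [video_frame()] or a raw pixel matrix/array.
#' @param n_bands number of bands.
#' @return integer band map with the same dimensions as the pixels
#'   (values in `0..n_bands - 1`).
#' @export
liac_quantize <- function(frame, n_bands = 8) {
  px <- if (inherits(frame, "video_frame")) frame$pixels else frame
  bm <- (px * n_bands) %/% 256
  storage.mode(bm) <- "integer"
  bm
}

#' Charge / discharge step
#'
#' Per channel, band and pixel: a pixel not in the band discharges to `q_min`;
#' a pixel that just entered the band saturates to `q_max`; a pixel in the
#' band at both instants is decremented by `discharge`, floored at `q_min`.
#' On the first call (no previous band map) charges are left at `q_min` and
#' the band map is recorded.
#'
#' @param state a [liac_state][liac_init()].
#' @param bandmap band map from [liac_quantize()].
#' @return the updated state.
#' @export
liac_update_charge <- function(state, bandmap) {
  d <- dim(bandmap)
  if (!identical(as.integer(d[1:2]), c(state$height, state$width)))
    stop_fw("band map dimensions do not match state")
  p <- state$params
  if (is.null(state$prev)) {
    state$prev <- bandmap
    return(state)
  }
  for (ch in seq_len(state$channels)) {
    bm <- bandmap_channel(bandmap, ch)
    pbm <- bandmap_channel(state$prev, ch)
    for (b in seq_len(p$n_bands) - 1L) {
      q <- band_slice(state$q[[ch]], b + 1L)
      inb <- bm == b
      q[!inb] <- p$q_min
      entered <- inb & pbm != b
      q[entered] <- p$q_max
      staying <- inb & pbm == b
      q[staying] <- pmax(q[staying] - p$discharge, p$q_min)
      state$q[[ch]][, , b + 1L] <- q
    }
  }
  state$prev <- bandmap
  state
}

# Pixels reachable from `src` through 4-connected paths of `transparent`
# pixels, computed by vectorised wavefront growth.
propagate4 <- function(src, transparent) {
  reach <- src
  repeat {
    grown <- reach | (neighbour4_any(reach) & transparent)
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

#' Lateral-inhibition recharge
#'
#' Saturated pixels (`q == q_max`) emit charge; partially charged pixels pass
#' it on; fully discharged pixels (`q == q_min`) are opaque. Every partially
#' charged pixel reachable from a saturated one through 4-connected charged
#' paths receives exactly one increment of `recharge`, capped at `q_max`.
#' Sources and transparency are evaluated on a frozen snapshot, so the result
#' does not depend on traversal order.
#'
#' @inheritParams liac_update_charge
#' @return the updated state.
#' @export
liac_recharge <- function(state) {
  p <- state$params
  for (ch in seq_len(state$channels)) {
    for (b in seq_len(p$n_bands)) {
      q <- band_slice(state$q[[ch]], b)
      src <- q == p$q_max
      if (!any(src)) next
      partial <- q > p$q_min & q < p$q_max
      if (!any(partial)) next
      reach <- propagate4(src, q > p$q_min)
      sel <- reach & partial
      if (any(sel)) {
        q[sel] <- pmin(q[sel] + p$recharge, p$q_max)
        state$q[[ch]][, , b] <- q
      }
    }
  }
  state
}

#' Charge homogenisation
#'
#' Within each channel and band, every 4-connected component of pixels whose
#' charge is at least `hom_min` is replaced by the floor of the component's
#' mean charge. Dilutes spurious background charge and gives each object part
#' a common charge value.
#'
#' @inheritParams liac_update_charge
#' @return the updated state.
#' @export
liac_homogenize <- function(state) {
  p <- state$params
  for (ch in seq_len(state$channels)) {
    for (b in seq_len(p$n_bands)) {
      q <- band_slice(state$q[[ch]], b)
      member <- q >= p$hom_min
      if (!any(member)) next
      lab <- EBImage::bwlabel(member + 0)  # 4-connected components
      means <- floor(tapply(q[member], lab[member], mean))
      q[member] <- as.numeric(means[as.character(lab[member])])
      state$q[[ch]][, , b] <- q
    }
  }
  state
}

#' Fuse bands and channels
#'
#' `liac_fuse_bands()` takes the pixelwise maximum over the band charges of
#' each channel. `liac_fuse_channels()` conjoins channels: a single channel
#' passes through; three channels are combined by pixelwise minimum, the
#' greyscale counterpart of a logical AND of the per-channel binarisations.
#'
#' @inheritParams liac_update_charge
#' @return `liac_fuse_bands()`: a list of per-channel charge matrices;
#'   `liac_fuse_channels()`: a single charge matrix.
#' @export
liac_fuse_bands <- function(state) {
  lapply(seq_len(state$channels), function(ch) {
    q <- state$q[[ch]]
    Reduce(pmax, lapply(seq_len(dim(q)[3]), function(b) band_slice(q, b)))
  })
}

#' @rdname liac_fuse_bands
#' @param images list of per-channel charge matrices (length 1 or 3).
#' @export
liac_fuse_channels <- function(images) {
  if (length(images) == 1) return(images[[1]])
  if (length(images) == 3) return(Reduce(pmin, images))
  stop_fw("channel fusion supports 1 or 3 channels, got %d", length(images))
}

#' One full LIAC step
#'
#' Composes quantization, charge update, lateral-inhibition recharge,
#' homogenisation, band fusion and channel fusion, in that order.
#'
#' @inheritParams liac_update_charge
#' @param frame a [video_frame()] (or raw pixel matrix/array).
#' @return `list(state = updated state, fused = fused charge matrix)`.
#' @examples
#' st <- liac_init(16, 16, params = liac_params())
#' f0 <- video_frame(matrix(30L, 16, 16))
#' f1 <- video_frame(matrix(30L, 16, 16), index = 1, timestamp_ms = 200)
#' f1$pixels[4:12, 6:10] <- 220L   # a bright blob appears
#' st <- liac_step(st, f0)$state
#' out <- liac_step(st, f1)
#' range(out$fused)
#' @export
liac_step <- function(state, frame) {
  px <- if (inherits(frame, "video_frame")) frame$pixels else frame
  ch <- if (length(dim(px)) == 3) dim(px)[3] else 1L
  if (ch != state$channels)
    stop_fw("frame has %d channel(s), state expects %d", ch, state$channels)
  bm <- liac_quantize(px, state$params$n_bands)
  state <- liac_update_charge(state, bm)
  state <- liac_recharge(state)
  state <- liac_homogenize(state)
  fused <- liac_fuse_channels(liac_fuse_bands(state))
  list(state = state, fused = fused)
}
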