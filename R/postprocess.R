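#' Blob size/shape limits
#'
#' Inclusive acceptance ranges for person-candidate blobs. `NA` for a maximum
#' means "no limit" (resolved against the image size by [segment_frames()]).
#'
#' @param min_height,max_height blob height range in pixels.
#' @param min_width,max_width blob width range in pixels.
#' @param min_compactness,max_compactness area / (w*h) range, in (0, 1].
#' @return an object of class `blob_limits`.
#' @export
blob_limits <- function(min_height = 20, max_height = NA,
                        min_width = 10, max_width = NA,
                        min_compactness = 0.2, max_compactness = 1.0) {
  chk <- function(lo, hi, what)
    if (!is.na(hi) && lo > hi) stop_fw("min %s exceeds max %s", what, what)
  chk(min_height, max_height, "height")
  chk(min_width, max_width, "width")
  chk(min_compactness, max_compactness, "compactness")
  structure(list(min_height = min_height, max_height = max_height,
                 min_width = min_width, max_width = max_width,
                 min_compactness = min_compactness,
                 max_compactness = max_compactness),
            class = "blob_limits")
}

#' Binarise a charge image
#'
#' Values at or above the threshold map to 255, the rest to 0 (the equality
#' case is inclusive-above by convention).
#'
#' @param image numeric charge matrix.
#' @param threshold binarisation level.
#' @return integer matrix with values in `{0, 255}`.
#' @export
binarise <- function(image, threshold = 128) {
  m <- (image >= threshold) * 255L
  storage.mode(m) <- "integer"
  m
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a 3x3 square structuring element;
#' pixels outside the image count as background. Removes isolated pixels and
#' spots thinner than 3 pixels while preserving larger blobs.
#'
#' @param mask matrix with values in `{0, 255}` (any non-zero is foreground).
#' @return mask of the same shape, values in `{0, 255}`.
#' @export
morph_open <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with one background pixel so the outside of the image erodes as
  # background (EBImage replicates the border otherwise)
  fg <- matrix(0, nr + 2, nc + 2)
  fg[2:(nr + 1), 2:(nc + 1)] <- (mask != 0) + 0
  kern <- EBImage::makeBrush(3, shape = "box")
  opened <- EBImage::dilate(EBImage::erode(fg, kern), kern)
  out <- (opened[2:(nr + 1), 2:(nc + 1), drop = FALSE] > 0) * 255L
  storage.mode(out) <- "integer"
  out
}

# 8-connected labelling by iterative minimum-label propagation.
label8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(as.numeric(seq_len(nr * nc)), nr, nc)
  lab[!fg] <- Inf
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    nbmin <- lab
    for (s in shifts) {
      sh <- matrix(Inf, nr, nc)
      rs <- seq_len(nr) - s[1]; cs <- seq_len(nc) - s[2]
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      sh[ok_r, ok_c] <- lab[rs[ok_r], cs[ok_c], drop = FALSE]
      nbmin <- pmin(nbmin, sh)
    }
    nxt <- lab
    nxt[fg] <- nbmin[fg]
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab[!fg] <- 0
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

#' Extract blobs from a binary mask
#'
#' Finds 8-connected foreground components and reports each with its tight
#' bounding box (0-based top-left `x`, `y`; y grows downward), pixel area and
#' compactness (`area / (w * h)`).
#'
#' @param mask matrix; non-zero pixels are foreground.
#' @return data frame with columns `x, y, w, h, area, compactness`, one row
#'   per blob, ordered by label discovery (row-major topmost-leftmost pixel).
#' @export
extract_blobs <- function(mask) {
  fg <- mask != 0
  empty <- data.frame(x = integer(0), y = integer(0), w = integer(0),
                      h = integer(0), area = integer(0),
                      compactness = numeric(0))
  if (!any(fg)) return(empty)
  lab <- label8(fg)
  ids <- seq_len(max(lab))
  rows <- lapply(ids, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    w <- c1 - c0 + 1L; h <- r1 - r0 + 1L
    data.frame(x = c0 - 1L, y = r0 - 1L, w = w, h = h,
               area = nrow(idx), compactness = nrow(idx) / (w * h))
  })
  do.call(rbind, rows)
}

#' Filter blobs by size and compactness
#'
#' Keeps blobs whose height, width and compactness fall inside the inclusive
#' limits; input order is preserved.
#'
#' @param blobs data frame from [extract_blobs()].
#' @param limits a [blob_limits()].
#' @return the filtered data frame.
#' @export
filter_blobs <- function(blobs, limits = blob_limits()) {
  if (nrow(blobs) == 0) return(blobs)
  hi <- function(v, m) if (is.na(m)) rep(TRUE, length(v)) else v <= m
  keep <- blobs$h >= limits$min_height & hi(blobs$h, limits$max_height) &
    blobs$w >= limits$min_width & hi(blobs$w, limits$max_width) &
    blobs$compactness >= limits$min_compactness &
    blobs$compactness <= limits$max_compactness
  blobs[keep, , drop = FALSE]
}

#' Select the person region of interest
#'
#' Single-person assumption: pick the blob of maximal area; ties go to the
#' smaller `y`, then smaller `x`.
#'
#' @param blobs data frame of blobs.
#' @return a one-row data frame, or `NULL` when no blob is available.
#' @export
select_roi <- function(blobs) {
  if (is.null(blobs) || nrow(blobs) == 0) return(NULL)
  ord <- order(-blobs$area, blobs$y, blobs$x)
  blobs[ord[1], , drop = FALSE]
}

#' Segment a frame sequence into per-frame person boxes
#'
#' Runs the LIAC engine over the frames, binarises and opens each fused
#' charge image, and extracts the filtered maximal blob per frame.
#'
#' @param frames list of [video_frame()] objects.
#' @param params a [liac_params()].
#' @param limits a [blob_limits()]; `NA` maxima resolve to the image size.
#' @param keep_masks if `TRUE`, the cleaned binary masks are returned too.
#' @return list with `rois` (per-frame one-row data frame or `NULL`) and,
#'   if requested, `masks` (list of 0/255 matrices).
#' @export
segment_frames <- function(frames, params = liac_params(),
                           limits = blob_limits(), keep_masks = FALSE) {
  if (length(frames) == 0) stop_fw("empty frame sequence")
  d <- dim(frames[[1]]$pixels)
  ch <- if (length(d) == 3) d[3] else 1L
  if (is.na(limits$max_height)) limits$max_height <- d[1]
  if (is.na(limits$max_width)) limits$max_width <- d[2]
  state <- liac_init(d[1], d[2], channels = ch, params = params)
  rois <- vector("list", length(frames))
  masks <- if (keep_masks) vector("list", length(frames)) else NULL
  for (i in seq_along(frames)) {
    out <- liac_step(state, frames[[i]])
    state <- out$state
    mask <- morph_open(binarise(out$fused, params$threshold))
    if (keep_masks) masks[[i]] <- mask
    rois[[i]] <- select_roi(filter_blobs(extract_blobs(mask), limits))
  }
  res <- list(rois = rois)
  if (keep_masks) res$masks <- masks
  res
}
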