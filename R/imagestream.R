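#' Sequence metadata
#'
#' Capture interval and channel count shared by all frames of a sequence.
#' Timestamps are derived from the interval: frame `i` (0-based) is stamped
#' `i * interval_ms`.
#'
#' @param interval_ms capture interval in milliseconds (> 0).
#' @param channels number of channels, 1 (infrared/greyscale) or 3 (colour).
#' @return an object of class `sequence_meta`.
#' @export
sequence_meta <- function(interval_ms = 200, channels = 1) {
  if (!is.numeric(interval_ms) || length(interval_ms) != 1 || interval_ms <= 0)
    stop_fw("interval_ms must be a single positive number, got %s",
            deparse(interval_ms))
  if (!channels %in% c(1, 3))
    stop_fw("channels must be 1 or 3, got %s", deparse(channels))
  structure(list(interval_ms = as.numeric(interval_ms),
                 channels = as.integer(channels)),
            class = "sequence_meta")
}

#' Construct a video frame
#'
#' A frame stores 8-bit pixel intensities as an integer matrix
#' (`height x width`, one channel) or array (`height x width x 3`), using the
#' image convention: 0-based coordinates elsewhere in the package refer to the
#' top-left origin with y growing downward (matrix row = y + 1, column = x + 1).
#'
#' @param pixels integer matrix or `h x w x 3` array with values in 0..255.
#' @param index frame ordinal, 0-based.
#' @param timestamp_ms milliseconds from sequence start.
#' @return an object of class `video_frame`.
#' @export
video_frame <- function(pixels, index = 0L, timestamp_ms = 0) {
  d <- dim(pixels)
  if (is.null(d) || !(length(d) == 2 || (length(d) == 3 && d[3] == 3)))
    stop_fw("pixels must be a matrix or an h x w x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_fw("pixel intensities must lie in [0, 255]")
  structure(list(pixels = pixels, index = as.integer(index),
                 timestamp_ms = as.numeric(timestamp_ms)),
            class = "video_frame")
}

#' @export
print.video_frame <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<video_frame %dx%d, %d channel%s, index %d, t = %g ms>\n",
              d[2], d[1], ch, if (ch > 1) "s" else "", x$index,
              x$timestamp_ms))
  invisible(x)
}

frame_channels <- function(frame) {
  d <- dim(frame$pixels)
  if (length(d) == 3) d[3] else 1L
}

# ---- PGM (P2/P5) ------------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_all <- readBin(con, "raw", n = file.size(path))
  if (length(raw_all) < 8) stop_fw("%s: truncated PGM header", path)
  magic <- rawToChar(raw_all[1:2])
  if (!magic %in% c("P2", "P5"))
    stop_fw("%s: not a PGM file (magic '%s')", path, magic)
  # Tokenise the header: magic, width, height, maxval; '#' starts a comment.
  toks <- character(0); i <- 1L; n <- length(raw_all)
  while (length(toks) < 4L && i <= n) {
    ch <- rawToChar(raw_all[i])
    if (ch == "#") {
      while (i <= n && rawToChar(raw_all[i]) != "\n") i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", rawToChar(raw_all[j])) &&
             rawToChar(raw_all[j]) != "#") j <- j + 1L
      toks <- c(toks, rawToChar(raw_all[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(toks) < 4L) stop_fw("%s: truncated PGM header", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxval <- as.integer(toks[4])
  if (is.na(w) || is.na(h) || w < 1 || h < 1)
    stop_fw("%s: bad PGM dimensions", path)
  if (is.na(maxval) || maxval != 255L)
    stop_fw("%s: only 8-bit PGM (maxval 255) is supported, got maxval %s",
            path, toks[4])
  if (magic == "P5") {
    i <- i + 1L  # single whitespace byte after maxval
    vals <- as.integer(raw_all[i:(i + w * h - 1L)])
  } else {
    body <- rawToChar(raw_all[i:n])
    body <- gsub("#[^\n]*", "", body)
    vals <- as.integer(strsplit(trimws(body), "[[:space:]]+")[[1]])[seq_len(w * h)]
  }
  if (anyNA(vals)) stop_fw("%s: truncated PGM pixel data", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(pixels, path) {
  if (!is.matrix(pixels)) stop_fw("PGM supports single-channel images only")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(pixels), nrow(pixels)), con,
            eos = NULL)
  writeBin(as.raw(as.integer(t(pixels))), con)
  invisible(path)
}

# ---- frame files ------------------------------------------------------------

read_frame_pixels <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    px <- round(a * 255)
    if (length(dim(px)) == 3) {
      if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]     # drop alpha
      if (dim(px)[3] == 1) px <- px[, , 1]
    }
    return(px)
  }
  stop_fw("%s: unsupported frame format (use .pgm or .png)", path)
}

#' Write one frame or mask image
#'
#' Dispatches on file extension: `.pgm` (single channel, binary P5) or `.png`.
#'
#' @param pixels matrix or `h x w x 3` array of intensities 0..255.
#' @param path output file name.
#' @return the path, invisibly.
#' @export
write_frame <- function(pixels, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(invisible(write_pgm(pixels, path)))
  if (ext == "png") {
    png::writePNG(pixels / 255, path)
    return(invisible(path))
  }
  stop_fw("%s: unsupported frame format (use .pgm or .png)", path)
}

#' Load a numbered frame sequence
#'
#' Reads all `.pgm`/`.png` files matched by `path` (a directory or a glob),
#' ordered by the last run of digits in each file name, and stamps frame `i`
#' with `i * meta$interval_ms`.
#'
#' @param path directory containing frames, or a glob such as `"dir/ir_*.pgm"`.
#' @param meta a [sequence_meta()].
#' @return list of [video_frame()] objects.
#' @export
load_sequence <- function(path, meta = sequence_meta()) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(pgm|png)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    Sys.glob(path)
  }
  if (length(files) == 0)
    stop_fw("no frames found under '%s'", path)
  ord <- regmatches(basename(files), regexpr("[0-9]+(?=[^0-9]*$)",
                                             basename(files), perl = TRUE))
  if (length(ord) == length(files)) files <- files[order(as.integer(ord))]
  frames <- vector("list", length(files))
  ref_dim <- NULL
  for (i in seq_along(files)) {
    px <- read_frame_pixels(files[i])
    ch <- if (length(dim(px)) == 3) dim(px)[3] else 1L
    if (ch != meta$channels)
      stop_fw("%s: has %d channel(s), sequence declares %d",
              files[i], ch, meta$channels)
    d <- dim(px)[1:2]
    if (is.null(ref_dim)) ref_dim <- d
    if (!identical(d, ref_dim))
      stop_fw("%s: dimensions %dx%d do not match first frame %dx%d",
              files[i], d[2], d[1], ref_dim[2], ref_dim[1])
    frames[[i]] <- video_frame(px, index = i - 1L,
                               timestamp_ms = (i - 1) * meta$interval_ms)
  }
  frames
}

# ---- blob CSV ---------------------------------------------------------------

#' Write / read blob bounding boxes as CSV
#'
#' The dialect is one row per blob with header
#' `frame,x,y,w,h,area,compactness`; integer fields round-trip losslessly and
#' compactness is written with 4 decimals.
#'
#' @param blobs data frame with columns `frame, x, y, w, h, area, compactness`.
#' @param path file to write / read.
#' @return `write_blob_csv()` returns the path invisibly; `read_blob_csv()`
#'   returns the blob data frame.
#' @export
write_blob_csv <- function(blobs, path) {
  header <- "frame,x,y,w,h,area,compactness"
  lines <- if (nrow(blobs) == 0) character(0) else
    sprintf("%d,%d,%d,%d,%d,%d,%.4f",
            as.integer(blobs$frame), as.integer(blobs$x), as.integer(blobs$y),
            as.integer(blobs$w), as.integer(blobs$h), as.integer(blobs$area),
            blobs$compactness)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_blob_csv
#' @export
read_blob_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "x", "y", "w", "h", "area", "compactness")
  if (!identical(names(df), need))
    stop_fw("%s: expected header '%s'", path, paste(need, collapse = ","))
  for (col in need[1:6]) df[[col]] <- as.integer(df[[col]])
  df
}
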