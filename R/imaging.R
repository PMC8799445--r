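#' Wrap pixel data as a strip image
#'
#' Coordinates are 0-based pixel indices, row-major; the region of interest
#' is half-open `[start, stop)` in each dimension. Intensities are expected
#' on the 0-255 scale (8-bit) or 0-65535 (16-bit); [read_strip_image()]
#' rescales file data accordingly.
#'
#' @param pixels Numeric matrix (grayscale, rows x cols) or 3-d array
#'   (rows x cols x channels) for color.
#' @param flow_axis `"rows"` if sample flows along image rows (profile
#'   positions are row indices), `"columns"` otherwise.
#' @param roi Integer vector `c(row_start, row_stop, col_start, col_stop)`,
#'   0-based half-open; `NULL` means the whole image.
#' @param expected_line_position Expected test-line pixel index along the
#'   flow axis (full-image coordinates, 0-based).
#' @param search_half_width Half-width of the search window around
#'   `expected_line_position`, pixels.
#' @param channel Color-to-signal conversion for color input:
#'   `"inverted_luminance"` (default; `255 - Rec.601 luminance`, so a dark
#'   blue latex line on white nitrocellulose reads as high signal) or
#'   `"red"`, `"green"`, `"blue"` for `255 -` that channel.
#' @param invert For grayscale input: if `TRUE`, use `max_scale - pixels`
#'   (dark line on light background); default uses values as-is.
#' @param max_scale Full-scale intensity (255 for 8-bit input).
#' @return An `lfa_strip_image`.
#' @export
strip_image <- function(pixels, flow_axis = c("rows", "columns"), roi = NULL,
                        expected_line_position, search_half_width = 20,
                        channel = c("inverted_luminance", "red", "green", "blue"),
                        invert = FALSE, max_scale = 255) {
  flow_axis <- match.arg(flow_axis)
  channel <- match.arg(channel)
  d <- dim(pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("pixels must be a 2-d matrix or 3-d array", call. = FALSE)
  if (is.null(roi)) roi <- c(0L, d[1], 0L, d[2])
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] < 0L || roi[3] < 0L ||
      roi[2] > d[1] || roi[4] > d[2] || roi[1] >= roi[2] || roi[3] >= roi[4])
    stop("roi out of image bounds", call. = FALSE)
  flow_lo <- if (flow_axis == "rows") roi[1] else roi[3]
  flow_hi <- if (flow_axis == "rows") roi[2] else roi[4]
  p <- as.integer(expected_line_position)
  if (p - search_half_width < flow_lo || p + search_half_width >= flow_hi)
    stop("search window [expected +/- half_width] must lie within the roi",
         call. = FALSE)
  structure(list(pixels = pixels, flow_axis = flow_axis, roi = roi,
                 expected_line_position = p,
                 search_half_width = as.integer(search_half_width),
                 channel = channel, invert = invert, max_scale = max_scale),
            class = "lfa_strip_image")
}

#' Read a strip image from PNG or TIFF
#'
#' 8- or 16-bit, color or grayscale; values are rescaled to 0-255
#' (fractional values preserved for 16-bit input).
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @param ... Passed to [strip_image()].
#' @export
read_strip_image <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = {
                 if (!requireNamespace("tiff", quietly = TRUE))
                   stop("reading TIFF needs the 'tiff' package", call. = FALSE)
                 tiff::readTIFF(path)
               },
               stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3, drop = FALSE]             # drop alpha
  strip_image(px * 255, ...)
}

# collapse color / apply inversion -> signal-scale matrix
signal_matrix <- function(img) {
  px <- img$pixels
  if (length(dim(px)) == 3L) {
    s <- switch(img$channel,
                inverted_luminance =
                  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3],
                red = px[, , 1], green = px[, , 2], blue = px[, , 3])
    img$max_scale - s
  } else if (img$invert) img$max_scale - px else px
}

#' Width-averaged intensity profile
#'
#' For each position along the flow axis within the roi, the mean converted
#' pixel value across the strip width. Positions are full-image 0-based
#' indices along the flow axis.
#'
#' @param img An [strip_image()].
#' @return Numeric vector with a `"positions"` attribute.
#' @export
width_averaged_profile <- function(img) {
  stopifnot(inherits(img, "lfa_strip_image"))
  m <- signal_matrix(img)
  r <- img$roi
  m <- m[(r[1] + 1L):r[2], (r[3] + 1L):r[4], drop = FALSE]
  if (img$flow_axis == "rows") {
    prof <- rowMeans(m)
    attr(prof, "positions") <- r[1]:(r[2] - 1L)
  } else {
    prof <- colMeans(m)
    attr(prof, "positions") <- r[3]:(r[4] - 1L)
  }
  prof
}

# moving average, partial windows at the edges
smooth_profile <- function(x, window = 3L) {
  if (window <= 1L) return(x)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the test line in a profile
#'
#' Argmax of a lightly smoothed profile (moving average, default 3 px)
#' restricted to `expected +/- half_width`; ties are broken toward
#' `expected`, so a flat window returns `expected` itself.
#'
#' @param profile Profile from [width_averaged_profile()] (its `"positions"`
#'   attribute maps indices to image coordinates; a bare vector is treated as
#'   starting at position 0).
#' @param expected Expected line position (image coordinates, 0-based).
#' @param half_width Search half-width, pixels.
#' @param smooth Moving-average window, px; 1 disables smoothing.
#' @return Peak position in image coordinates.
#' @export
locate_test_line <- function(profile, expected, half_width, smooth = 3L) {
  pos <- attr(profile, "positions")
  if (is.null(pos)) pos <- seq_along(profile) - 1L
  win <- which(pos >= expected - half_width & pos <= expected + half_width)
  if (!length(win) || win[1] == 0L)
    stop("search window outside profile", call. = FALSE)
  sm <- smooth_profile(as.numeric(profile), smooth)[win]
  best <- win[sm >= max(sm) - 1e-12]
  bp <- pos[best]
  d <- abs(bp - expected)
  nearest <- bp[d == min(d)]
  # symmetric tie (equal peaks equidistant from the expected position)
  # resolves to the expected position itself
  if (length(nearest) > 1L) as.integer(expected) else nearest[1]
}

#' Baseline estimation and subtraction around the test line
#'
#' The baseline is the straight line through the robust (median) levels of
#' two flanking windows, `[peak - line_halfwidth - flank_width,
#' peak - line_halfwidth)` and `[peak + line_halfwidth,
#' peak + line_halfwidth + flank_width)`, evaluated at every profile
#' position; the corrected profile is `profile - baseline`. A linear
#' background gradient is removed exactly.
#'
#' @param profile Profile vector (with optional `"positions"` attribute).
#' @param peak_position Line position from [locate_test_line()].
#' @param line_halfwidth Half-width of the region treated as line, px.
#' @param flank_width Width of each background flank, px.
#' @return List with `baseline`, `corrected` (both full-length) and the
#'   anchor levels.
#' @export
subtract_background <- function(profile, peak_position, line_halfwidth = 8L,
                                flank_width = 10L) {
  pos <- attr(profile, "positions")
  if (is.null(pos)) pos <- seq_along(profile) - 1L
  prof <- as.numeric(profile)
  lw <- pos >= peak_position - line_halfwidth - flank_width &
    pos < peak_position - line_halfwidth
  rw <- pos >= peak_position + line_halfwidth &
    pos < peak_position + line_halfwidth + flank_width
  if (sum(lw) < flank_width || sum(rw) < flank_width)
    stop("background flanks fall outside the profile; widen the roi",
         call. = FALSE)
  left_level <- stats::median(prof[lw])
  right_level <- stats::median(prof[rw])
  left_x <- mean(pos[lw])
  right_x <- mean(pos[rw])
  slope <- (right_level - left_level) / (right_x - left_x)
  baseline <- left_level + slope * (pos - left_x)
  list(baseline = baseline, corrected = prof - baseline,
       left_level = left_level, right_level = right_level)
}

#' Quantify the test-line signal of one strip
#'
#' Pipeline: width-averaged profile, peak location in the search window,
#' flank-median baseline subtraction, peak height readout. The reported
#' `signal` is the baseline-corrected profile value at the peak, clipped at
#' zero; the unclipped value is kept in `corrected_peak` for diagnostics.
#'
#' @param img An [strip_image()].
#' @param line_halfwidth,flank_width Passed to [subtract_background()].
#' @param smooth Peak-finding smoothing window, px.
#' @return An `lfa_line_signal`: `profile`, `peak_position`,
#'   `baseline_at_peak`, `raw_peak`, `corrected_peak`, `signal`.
#' @examples
#' tr <- strip_truth(line_amplitude = 30, line_center = 60, seed = 1)
#' img <- render_strip(tr, shape = c(120, 30))$image
#' line_signal(img)$signal
#' @export
line_signal <- function(img, line_halfwidth = 8L, flank_width = 10L,
                        smooth = 3L) {
  prof <- width_averaged_profile(img)
  peak <- locate_test_line(prof, img$expected_line_position,
                           img$search_half_width, smooth = smooth)
  bg <- subtract_background(prof, peak, line_halfwidth, flank_width)
  pos <- attr(prof, "positions")
  i <- match(peak, pos)
  corrected <- bg$corrected[i]
  structure(list(profile = prof, peak_position = peak,
                 baseline_at_peak = bg$baseline[i],
                 raw_peak = as.numeric(prof[i]),
                 corrected_peak = corrected,
                 signal = max(0, corrected)),
            class = "lfa_line_signal")
}

#' @export
print.lfa_line_signal <- function(x, ...) {
  cat(sprintf("test line at px %d: raw %.2f, baseline %.2f, signal %.2f\n",
              x$peak_position, x$raw_peak, x$baseline_at_peak, x$signal))
  invisible(x)
}

#' Quantify a set of strip image files into a screen table
#'
#' One-strip-per-file mode: each file is quantified with shared geometry
#' parameters and one result row is emitted per strip, in the schema shared
#' with the synthetic screen tables (`condition_id, peak_position, raw_peak,
#' baseline, signal`).
#'
#' @param paths Image files.
#' @param condition_ids Condition id per file (defaults to file stem).
#' @param ... Geometry arguments for [read_strip_image()] /
#'   [strip_image()] (`expected_line_position` is required).
#' @param line_halfwidth,flank_width,smooth Passed to [line_signal()].
#' @return data.frame, one row per strip.
#' @export
quantify_strips <- function(paths, condition_ids = NULL, ...,
                            line_halfwidth = 8L, flank_width = 10L,
                            smooth = 3L) {
  if (is.null(condition_ids))
    condition_ids <- tools::file_path_sans_ext(basename(paths))
  stopifnot(length(condition_ids) == length(paths))
  rows <- lapply(seq_along(paths), function(i) {
    sig <- line_signal(read_strip_image(paths[i], ...),
                       line_halfwidth = line_halfwidth,
                       flank_width = flank_width, smooth = smooth)
    data.frame(condition_id = condition_ids[i],
               peak_position = sig$peak_position, raw_peak = sig$raw_peak,
               baseline = sig$baseline_at_peak, signal = sig$signal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
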