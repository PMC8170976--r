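# Motility-map module: frame stacks or raw diameter traces -> baseline
# corrected, normalized, signed spatiotemporal amplitude maps and heatmaps.

#' Track gut edges in a frame stack
#'
#' For each of `n_loci` equally spaced column bands of each frame, the mean
#' intensity profile over rows is thresholded (Otsu on the whole stack) and
#' the outermost above-threshold rows define the upper and lower gut border;
#' the diameter is their vertical extent divided by `px_per_mm`. Frames where
#' an edge is undetectable at a locus are flagged and linearly interpolated
#' from neighbouring frames; more than `max_flagged` flagged locus-frames is
#' an error.
#'
#' @param frames numeric array `height x width x n_frames`, intensities >= 0.
#' @param n_loci number of analysis loci across the frame width.
#' @param px_per_mm pixel scale.
#' @param fps frames per second.
#' @param segment_length physical segment length, cm (for calibration).
#' @param max_flagged maximum tolerated fraction of flagged locus-frames.
#' @return a [diameter_trace()] with attribute `flagged` (logical matrix).
#' @export
track_edges <- function(frames, n_loci, px_per_mm, fps,
                        segment_length = 2, max_flagged = 0.1) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  n_frames <- dim(frames)[3]
  if (n_frames < 2) stop("frame stack must contain at least 2 frames")
  width <- dim(frames)[2]
  bands <- split(seq_len(width),
                 cut(seq_len(width), n_loci, labels = FALSE))
  rng <- range(frames)
  if (diff(rng) <= 0) stop("stack has no intensity contrast")
  norm <- (frames - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(norm, nrow = dim(frames)[1])))

  d <- matrix(NA_real_, n_loci, n_frames)
  for (f in seq_len(n_frames)) {
    frame <- norm[, , f]
    for (i in seq_len(n_loci)) {
      profile <- rowMeans(frame[, bands[[i]], drop = FALSE])
      on <- which(profile > thr)
      if (length(on) >= 1) d[i, f] <- (max(on) - min(on) + 1) / px_per_mm
    }
  }
  flagged <- is.na(d)
  if (mean(flagged) > max_flagged) {
    stop(sprintf("%.1f%% of locus-frames have undetectable edges (limit %.0f%%)",
                 100 * mean(flagged), 100 * max_flagged))
  }
  if (any(flagged)) {
    for (i in seq_len(n_loci)) {
      bad <- which(flagged[i, ])
      if (length(bad)) {
        ok <- which(!flagged[i, ])
        d[i, bad] <- stats::approx(ok, d[i, ok], xout = bad, rule = 2)$y
      }
    }
  }
  tr <- diameter_trace(d, fps = fps,
                       spacing = segment_length * 10 / n_loci,
                       segment_length = segment_length)
  attr(tr, "flagged") <- flagged
  tr
}

#' Baseline-correct a diameter trace into a spatiotemporal map
#'
#' Removes the slow component of gut movement independently per locus with a
#' moving median (robust against contraction troughs) of width `window_s`
#' seconds, which must exceed the longest expected cycle period. The signed
#' amplitude is `trace - baseline`: contractions negative, dilatations
#' positive. `baseline + amplitude` reconstructs the input exactly.
#'
#' @param trace a [diameter_trace()].
#' @param window_s moving-median window, s (> 2/fps).
#' @return an object of class `st_map` with fields `amplitude`, `baseline`,
#'   `normalized` (NULL until [normalize_map()]), plus calibration.
#' @export
baseline_correct <- function(trace, window_s = 20) {
  stopifnot(inherits(trace, "diameter_trace"))
  if (window_s <= 2 / trace$fps) stop("window_s must exceed 2/fps")
  n <- ncol(trace$values)
  # The baseline is low-frequency by construction, so for wide windows the
  # median is evaluated on a decimated grid and linearly interpolated back;
  # this changes nothing for narrow windows and is exact for slow baselines.
  dec <- max(1L, ceiling(window_s * trace$fps / 1001))
  idx <- unique(c(seq(1L, n, by = dec), n))
  k <- round(window_s * trace$fps / dec)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, length(idx) - (1 - length(idx) %% 2))
  baseline <- t(apply(trace$values, 1, function(x) {
    med <- stats::runmed(x[idx], k, endrule = "median")
    if (dec == 1L) med else stats::approx(idx, med, xout = seq_len(n))$y
  }))
  structure(list(
    amplitude = trace$values - baseline,
    baseline = baseline,
    normalized = NULL,
    fps = trace$fps, spacing = trace$spacing,
    segment_length = trace$segment_length, window_s = window_s
  ), class = "st_map")
}

#' Normalize a spatiotemporal map to the initial diameter
#'
#' Divides each locus's amplitude by that locus's initial diameter, taken as
#' the mean raw diameter over the first `initial_window_s` seconds (averaging
#' rather than using frame 0 damps noise). Sign convention is preserved.
#'
#' @param map an `st_map` from [baseline_correct()].
#' @param initial_window_s averaging window for the initial diameter, s.
#' @return the map with its `normalized` field filled (fraction of initial
#'   diameter) and attribute `initial_diameter` per locus.
#' @export
normalize_map <- function(map, initial_window_s = 1) {
  stopifnot(inherits(map, "st_map"))
  n0 <- max(1L, round(initial_window_s * map$fps))
  raw <- map$amplitude + map$baseline
  init <- rowMeans(raw[, seq_len(min(n0, ncol(raw))), drop = FALSE])
  if (any(init <= 0)) stop("initial diameter must be > 0 at every locus")
  map$normalized <- sweep(map$amplitude, 1, init, "/")
  attr(map, "initial_diameter") <- init
  map
}

# Diverging blue-white-red colour map on [-1, 1].
diverging_rgb <- function(z) {
  z <- pmin(pmax(z, -1), 1)   # first argument keeps the matrix dims
  r <- ifelse(z >= 0, 1, 1 + z)
  g <- 1 - abs(z)
  b <- ifelse(z <= 0, 1, 1 - z)
  array(c(r, g, b), dim = c(dim(z), 3))
}

#' Render a spatiotemporal heatmap PNG
#'
#' Writes a PNG with time on the x-axis (frames) and locus position on the
#' y-axis (oral end at the top), using a symmetric diverging colour scale
#' centred at zero amplitude (contractions blue, dilatations red). Colour
#' limits default to the maximum absolute amplitude. Rendering is pixel-exact
#' and bitwise reproducible for fixed limits.
#'
#' @param map an `st_map`.
#' @param path output PNG path.
#' @param limits colour limit (positive scalar); NULL = max |amplitude|.
#' @param use `"amplitude"` (mm) or `"normalized"`.
#' @param y_scale vertical pixels per locus.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, path, limits = NULL,
                           use = c("amplitude", "normalized"), y_scale = 8) {
  stopifnot(inherits(map, "st_map"))
  use <- match.arg(use)
  m <- map[[use]]
  if (is.null(m)) stop("normalized layer missing; run normalize_map() first")
  if (is.null(limits)) limits <- max(abs(m), 1e-12)
  z <- m / limits
  z <- z[rep(seq_len(nrow(z)), each = y_scale), , drop = FALSE]
  png::writePNG(diverging_rgb(z), target = path)
  invisible(path)
}

#' Write / read a diameter trace as TSV + sidecar JSON
#'
#' The TSV holds one row per locus: first column `locus` (0-based, oral to
#' aboral), remaining columns the per-frame diameters in mm. The sidecar JSON
#' (`<path>.json`) carries fps, spacing and segment length so units are
#' recoverable.
#'
#' @param trace a [diameter_trace()].
#' @param path TSV output path.
#' @return `path` invisibly (write) or a [diameter_trace()] (read).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "diameter_trace"))
  df <- data.frame(locus = seq_len(nrow(trace$values)) - 1L,
                   trace$values, check.names = FALSE)
  names(df) <- c("locus", sprintf("f%d", seq_len(ncol(trace$values)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fps = trace$fps, spacing_mm = trace$spacing,
                            segment_length_cm = trace$segment_length),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(df[order(df$locus), -1, drop = FALSE])
  dimnames(values) <- NULL
  diameter_trace(values, fps = meta$fps, spacing = meta$spacing_mm,
                 segment_length = meta$segment_length_cm)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' @param stack numeric array `height x width x n_frames` in [0, 1].
#' @param path TIFF path.
#' @return `path` invisibly (write) or the array (read).
#' @export
write_frames <- function(stack, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  pages <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}
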