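# Quantification module: binarized percent-positive area, masked marker area,
# connected-component cell counting, percent reductions and marker ratios.

resolve_threshold <- function(img, method, fixed_threshold) {
  if (method == "fixed") {
    check_scalar(fixed_threshold, "fixed_threshold")
    return(fixed_threshold)
  }
  rng <- range(img)
  if (diff(rng) <= 0) return(Inf)  # featureless image: nothing above threshold
  EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng))) * diff(rng) + rng[1]
}

#' Percent positive area of a fluorescence image
#'
#' Binarizes a single-channel image (Otsu threshold by default, or a fixed
#' threshold for reproducibility audits) and reports the percentage of
#' above-threshold pixels, either over the whole picture section or restricted
#' to a binary mask (e.g. marker area within a Tuj1-positive ganglionic mask).
#'
#' @param img numeric matrix (single channel).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold intensity when `method = "fixed"`.
#' @param mask optional logical/0-1 matrix of the same shape; the percentage
#'   is then computed over mask pixels only. An empty mask is an error.
#' @return list of class `area_quant`: positive_fraction (percent), threshold,
#'   method, n_pixels evaluated.
#' @export
binarize_and_area <- function(img, method = c("otsu", "fixed"),
                              fixed_threshold = NULL, mask = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), is.numeric(img))
  thr <- resolve_threshold(img, method, fixed_threshold)
  pos <- img > thr
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(img)))
    mask <- mask > 0
    if (!any(mask)) stop("mask is empty")
    pos <- pos[mask]
  }
  structure(list(positive_fraction = 100 * mean(pos),
                 threshold = thr, method = method,
                 n_pixels = length(pos)),
            class = "area_quant")
}

#' Count cell-like objects by connected components
#'
#' Binarizes the image and counts connected components with at least
#' `min_area_px` pixels. No object splitting is attempted: two blobs merged by
#' a bridge count as one.
#'
#' @param img numeric matrix (single channel).
#' @param min_area_px minimum component area, px.
#' @param method,fixed_threshold as in [binarize_and_area()].
#' @return integer object count.
#' @export
count_cells <- function(img, min_area_px = 1, method = c("otsu", "fixed"),
                        fixed_threshold = NULL) {
  method <- match.arg(method)
  thr <- resolve_threshold(img, method, fixed_threshold)
  bw <- EBImage::Image(img > thr)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(as.integer(lab))
  sum(sizes >= min_area_px)
}

#' Percent reduction of a treated mean relative to a control mean
#'
#' `100 * (1 - mean_treated / mean_control)`, reported to two decimals.
#'
#' @param mean_treated,mean_control group means; the control must be > 0.
#' @return percent reduction, rounded to two decimals.
#' @export
percent_reduction <- function(mean_treated, mean_control) {
  check_scalar(mean_treated, "mean_treated")
  check_scalar(mean_control, "mean_control", lower = 1e-12)
  round(100 * (1 - mean_treated / mean_control), 2)
}

#' Marker-to-reference cell-count ratio
#'
#' Divides the marker-positive count by the reference (e.g. PGP9.5-positive)
#' count, optionally normalizing by a control ratio.
#'
#' @param n_marker marker-positive cells.
#' @param n_reference reference-positive cells; a zero reference yields `NA`.
#' @param control_ratio optional control ratio to normalize by.
#' @return numeric ratio (or `NA`).
#' @export
marker_ratio <- function(n_marker, n_reference, control_ratio = NULL) {
  check_scalar(n_marker, "n_marker", lower = 0)
  check_scalar(n_reference, "n_reference", lower = 0)
  if (n_reference == 0) return(NA_real_)
  r <- n_marker / n_reference
  if (!is.null(control_ratio)) {
    check_scalar(control_ratio, "control_ratio", lower = 1e-12)
    r <- r / control_ratio
  }
  r
}

#' Live/dead counts from a two-channel assay image pair
#'
#' Counts calcein-positive (live) and propidium-iodide-positive (dead) objects
#' per picture section; double-positive objects are counted as dead
#' (conservative).
#'
#' @param live_img,dead_img single-channel matrices of the two stains.
#' @param min_area_px minimum object area.
#' @param method,fixed_threshold thresholding, as in [count_cells()].
#' @return list of class `cell_counts`: n_live, n_dead.
#' @export
live_dead_counts <- function(live_img, dead_img, min_area_px = 1,
                             method = "otsu", fixed_threshold = NULL) {
  thr_l <- resolve_threshold(live_img, method, fixed_threshold)
  thr_d <- resolve_threshold(dead_img, method, fixed_threshold)
  dead_bw <- dead_img > thr_d
  live_bw <- (live_img > thr_l) & !dead_bw   # double-positive counted as dead
  count_bw <- function(bw) {
    sizes <- tabulate(as.integer(EBImage::bwlabel(EBImage::Image(bw))))
    sum(sizes >= min_area_px)
  }
  structure(list(n_live = count_bw(live_bw), n_dead = count_bw(dead_bw)),
            class = "cell_counts")
}
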