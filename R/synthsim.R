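# Synthetic-data module: seeded generators with known ground truth for every
# downstream stage (diameter traces, rendered frame stacks, count matrices,
# fluorescence images, two-group cohorts).

#' Wave parameters for the contraction-trace generator
#'
#' Bundles the acquisition and signal constants used by [simulate_trace()].
#' Defaults emulate a small-intestine-like ex vivo recording: a 2 cm segment
#' observed at 25 frames/s through 30 equally spaced loci, carrying propagating
#' contraction waves.
#'
#' The waveform of one cycle is a raised-cosine contraction trough of depth
#' `amplitude` occupying `duty` of the period, followed by a raised-cosine
#' dilatation bump over the remainder of the period with peak
#' `dilatation_frac * amplitude`. The default `dilatation_frac = duty/(1-duty)`
#' makes the waveform zero-mean, so dilatations appear as positive and
#' contractions as negative deflections around the resting diameter.
#'
#' @param frequency contractions per minute (>= 0).
#' @param amplitude contraction trough depth, mm (>= 0).
#' @param velocity aboral propagation speed, mm/s. Positive is oral-to-aboral,
#'   negative retrograde, `Inf` synchronous (zero lag between loci).
#' @param baseline_diameter resting gut diameter, mm (> 0).
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift, mm.
#' @param drift_period period of the slow drift, s.
#' @param ramp linear baseline ramp, mm/s (default 0).
#' @param noise_sd additive diameter noise, mm. For `noise_dist = "gaussian"`
#'   this is the standard deviation; for `"uniform"` it is the half-range
#'   (the noise is bounded in `[-noise_sd, +noise_sd]`).
#' @param noise_dist `"gaussian"` (default) or `"uniform"` (bounded).
#' @param duration recording length, s.
#' @param fps frames per second.
#' @param n_loci number of analysis loci along the segment (>= 2).
#' @param segment_length segment length, cm.
#' @param duty fraction of the period occupied by the contraction trough.
#' @param dilatation_frac dilatation peak as a fraction of `amplitude`.
#' @param seed integer seed for the noise (NULL = use current RNG state).
#' @return a list of class `wave_params`.
#' @export
wave_params <- function(frequency = 40, amplitude = 0.4, velocity = 15,
                        baseline_diameter = 2, drift_amplitude = 0,
                        drift_period = 120, ramp = 0,
                        noise_sd = 0.02, noise_dist = c("gaussian", "uniform"),
                        duration = 60, fps = 25, n_loci = 30,
                        segment_length = 2, duty = 0.4,
                        dilatation_frac = duty / (1 - duty), seed = NULL) {
  noise_dist <- match.arg(noise_dist)
  check_scalar(frequency, "frequency", lower = 0)
  check_scalar(amplitude, "amplitude", lower = 0)
  if (!is.numeric(velocity) || length(velocity) != 1L || is.na(velocity)) {
    stop("'velocity' must be a numeric scalar (may be Inf for synchronous)")
  }
  check_scalar(baseline_diameter, "baseline_diameter", lower = 1e-9)
  check_scalar(drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar(drift_period, "drift_period", lower = 1e-9)
  check_scalar(ramp, "ramp")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(duration, "duration", lower = 1e-9)
  check_scalar(fps, "fps", lower = 1e-9)
  check_scalar(n_loci, "n_loci", lower = 2)
  check_scalar(segment_length, "segment_length", lower = 1e-9)
  check_scalar(duty, "duty", lower = 0.05, upper = 0.95)
  check_scalar(dilatation_frac, "dilatation_frac", lower = 0)
  structure(list(
    frequency = frequency, amplitude = amplitude, velocity = velocity,
    baseline_diameter = baseline_diameter, drift_amplitude = drift_amplitude,
    drift_period = drift_period, ramp = ramp, noise_sd = noise_sd,
    noise_dist = noise_dist, duration = duration, fps = fps,
    n_loci = as.integer(n_loci), segment_length = segment_length,
    duty = duty, dilatation_frac = dilatation_frac, seed = seed
  ), class = "wave_params")
}

#' Construct a diameter trace object
#'
#' The central signal container: a loci x frames matrix of gut diameters (mm)
#' with temporal (`fps`) and spatial (`spacing`, mm between loci) calibration.
#' Locus 0 (row 1) is the oral end.
#'
#' @param values loci x frames numeric matrix of diameters, mm (all > 0).
#' @param fps frames per second.
#' @param spacing distance between adjacent loci, mm.
#' @param segment_length segment length, cm.
#' @return an object of class `diameter_trace`.
#' @export
diameter_trace <- function(values, fps, spacing, segment_length) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("trace values must be finite and > 0 mm")
  }
  check_scalar(fps, "fps", lower = 1e-9)
  if (ncol(values) < 2 * fps) {
    stop("trace must contain at least 2 s of signal (frames >= 2*fps)")
  }
  structure(list(values = values, fps = fps, spacing = spacing,
                 segment_length = segment_length),
            class = "diameter_trace")
}

# Zero-mean cyclic waveform evaluated at phase u in [0, 1).
# Contraction-positive sign: positive values are subtracted from the diameter.
cycle_waveform <- function(u, amplitude, duty, dilatation_frac) {
  w <- numeric(length(u))
  trough <- u < duty
  w[trough] <- amplitude * 0.5 * (1 - cos(2 * pi * u[trough] / duty))
  w[!trough] <- -dilatation_frac * amplitude * 0.5 *
    (1 - cos(2 * pi * (u[!trough] - duty) / (1 - duty)))
  w
}

#' Simulate a propagating-contraction diameter trace
#'
#' Generates a seeded loci x frames diameter matrix:
#' `diameter = baseline + drift + noise - wave`, where the wave at locus i lags
#' locus 0 by `i * spacing / velocity` seconds. The returned object carries a
#' `truth` attribute with the exact contraction-onset times per locus (the
#' descending zero crossing at the trough start of the noise-free waveform),
#' the cycle period and the per-locus lags, for parameter-recovery tests.
#'
#' @param params a [wave_params()] object.
#' @return a [diameter_trace()] with attribute `truth`.
#' @export
simulate_trace <- function(params) {
  stopifnot(inherits(params, "wave_params"))
  p <- params
  n_frames <- round(p$duration * p$fps)
  t_s <- (seq_len(n_frames) - 1) / p$fps
  spacing <- p$segment_length * 10 / p$n_loci      # mm between loci
  lags <- if (is.infinite(p$velocity)) rep(0, p$n_loci) else
    (seq_len(p$n_loci) - 1) * spacing / p$velocity # s

  period <- if (p$frequency > 0) 60 / p$frequency else Inf
  drift <- p$drift_amplitude * sin(2 * pi * t_s / p$drift_period) +
    p$ramp * t_s

  values <- matrix(p$baseline_diameter, nrow = p$n_loci, ncol = n_frames)
  truth_onsets <- vector("list", p$n_loci)
  for (i in seq_len(p$n_loci)) {
    row <- p$baseline_diameter + drift
    if (p$frequency > 0 && p$amplitude > 0) {
      u <- ((t_s - lags[i]) %% period) / period
      row <- row - cycle_waveform(u, p$amplitude, p$duty, p$dilatation_frac)
      first_k <- ceiling((0 - lags[i]) / period)
      last_k <- floor((max(t_s) - lags[i]) / period)
      ons <- lags[i] + (first_k:last_k) * period
      truth_onsets[[i]] <- ons[ons >= 0 & ons <= max(t_s)]
    } else {
      truth_onsets[[i]] <- numeric(0)
    }
    values[i, ] <- row
  }
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, {
      if (p$noise_dist == "gaussian") {
        matrix(stats::rnorm(length(values), 0, p$noise_sd), nrow = nrow(values))
      } else {
        matrix(stats::runif(length(values), -p$noise_sd, p$noise_sd),
               nrow = nrow(values))
      }
    })
    values <- values + noise
  }
  if (any(values <= 0)) {
    stop("simulated diameters are not all positive; increase baseline_diameter")
  }
  tr <- diameter_trace(values, fps = p$fps, spacing = spacing,
                       segment_length = p$segment_length)
  attr(tr, "truth") <- list(onsets = truth_onsets, period = period,
                            lags = lags, params = p)
  tr
}

#' Render a diameter trace as a synthetic frame stack
#'
#' Draws, per frame, a bright horizontal tube on a dark background whose
#' vertical extent at each locus equals the local diameter in pixels. Used as
#' a round-trip fixture for [track_edges()].
#'
#' @param trace a [diameter_trace()].
#' @param px_per_mm pixel scale (> 0).
#' @param height_px frame height in pixels; defaults to 1.5x the maximum
#'   diameter. Diameters exceeding the frame height are rejected.
#' @param cols_per_locus horizontal pixels per locus band.
#' @param fg,bg tube and background intensities in [0, 1].
#' @return numeric array `height_px x width x n_frames` with values in [0, 1].
#' @export
render_frames <- function(trace, px_per_mm, height_px = NULL,
                          cols_per_locus = 4, fg = 1, bg = 0) {
  stopifnot(inherits(trace, "diameter_trace"))
  check_scalar(px_per_mm, "px_per_mm", lower = 1e-9)
  d_px <- trace$values * px_per_mm
  if (is.null(height_px)) height_px <- 2L * ceiling(max(d_px) * 0.75 + 2)
  if (max(d_px) > height_px) {
    stop("diameter exceeds frame height; increase height_px")
  }
  n_loci <- nrow(trace$values)
  n_frames <- ncol(trace$values)
  width <- n_loci * cols_per_locus
  centre <- height_px / 2
  y <- seq_len(height_px) - 0.5            # pixel-centre coordinates
  stack <- array(bg, dim = c(height_px, width, n_frames))
  for (f in seq_len(n_frames)) {
    frame <- matrix(bg, height_px, width)
    for (i in seq_len(n_loci)) {
      on <- abs(y - centre) <= d_px[i, f] / 2
      cols <- ((i - 1) * cols_per_locus + 1):(i * cols_per_locus)
      frame[on, cols] <- fg
    }
    stack[, , f] <- frame
  }
  attr(stack, "fps") <- trace$fps
  attr(stack, "px_per_mm") <- px_per_mm
  stack
}

#' Simulate a labelled two-group cohort of diameter traces
#'
#' Draws independent seeded traces for a control and a case group; per-trace
#' seeds are derived deterministically from `seed`.
#'
#' @param wt,case [wave_params()] for each group.
#' @param n_wt,n_case group sizes (>= 2).
#' @param seed integer master seed.
#' @return list with elements `traces` (list of diameter traces) and `groups`
#'   (character vector `"WT"`/`"case"`).
#' @export
simulate_cohort <- function(wt, case, n_wt, n_case, seed = 1) {
  check_scalar(n_wt, "n_wt", lower = 2)
  check_scalar(n_case, "n_case", lower = 2)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                      n_wt + n_case))
  traces <- vector("list", n_wt + n_case)
  groups <- c(rep("WT", n_wt), rep("case", n_case))
  for (k in seq_along(traces)) {
    p <- if (k <= n_wt) wt else case
    p$seed <- seeds[k]
    traces[[k]] <- simulate_trace(p)
  }
  list(traces = traces, groups = groups)
}

#' Spike design for synthetic count matrices
#'
#' Describes a feature x sample count matrix with a set of robustly expressed
#' features, a subset spiked up in the case group, and stable housekeeping
#' features used by the normalizer. Defaults emulate an nCounter-style miRNA
#' panel: 578 features of which 166 are robustly expressed (including 4
#' housekeeping genes) and 45 are spiked 2-fold up in the case group, with
#' 5 control vs 6 case samples.
#'
#' @param n_features total features.
#' @param n_expressed robustly expressed features (includes housekeeping).
#' @param n_spiked spiked (up-regulated in case) features; never housekeeping.
#' @param fold_change linear fold change of spiked features (>= 1).
#' @param group_sizes integer c(n_WT, n_case), each >= 2.
#' @param housekeeping_names ids of the stable reference features.
#' @param dispersion negative-binomial dispersion of non-housekeeping counts.
#' @param expressed_mean,background_mean,housekeeping_level expected counts.
#' @param scale_sd log-normal sd of per-sample scale factors (0 = none).
#' @param seed integer seed.
#' @return a list of class `spike_design`.
#' @export
spike_design <- function(n_features = 578, n_expressed = 166, n_spiked = 45,
                         fold_change = 2, group_sizes = c(5, 6),
                         housekeeping_names = c("Actb", "B2m", "Gapdh", "Rpl19"),
                         dispersion = 0.05, expressed_mean = 500,
                         background_mean = 10, housekeeping_level = 2000,
                         scale_sd = 0.1, seed = 1) {
  check_scalar(fold_change, "fold_change", lower = 1)
  stopifnot(length(group_sizes) == 2, all(group_sizes >= 2))
  n_hk <- length(housekeeping_names)
  if (!(n_spiked <= n_expressed - n_hk && n_expressed <= n_features)) {
    stop("need n_spiked <= n_expressed - n_housekeeping <= n_features")
  }
  check_scalar(dispersion, "dispersion", lower = 0)
  structure(list(
    n_features = as.integer(n_features), n_expressed = as.integer(n_expressed),
    n_spiked = as.integer(n_spiked), fold_change = fold_change,
    group_sizes = as.integer(group_sizes),
    housekeeping_names = housekeeping_names, dispersion = dispersion,
    expressed_mean = expressed_mean, background_mean = background_mean,
    housekeeping_level = housekeeping_level, scale_sd = scale_sd, seed = seed
  ), class = "spike_design")
}

#' Simulate a count matrix with spiked features and known truth
#'
#' Counts are negative-binomial around feature means scaled by per-sample
#' factors; spiked features have their case-group mean multiplied by
#' `fold_change`. Housekeeping features are noise-free multiples of a common
#' level (stable by construction), so the normalizer can recover the sample
#' scale factors.
#'
#' @param design a [spike_design()].
#' @return a [count_matrix()] with attribute `truth` (data.frame of feature,
#'   spiked flag and true fold change) and attribute `scale_factors`.
#' @export
simulate_count_matrix <- function(design) {
  stopifnot(inherits(design, "spike_design"))
  d <- design
  n_wt <- d$group_sizes[1]; n_case <- d$group_sizes[2]
  n_samp <- n_wt + n_case
  n_hk <- length(d$housekeeping_names)
  feat <- c(d$housekeeping_names,
            sprintf("miR-%03d", seq_len(d$n_features - n_hk)))
  groups <- c(rep("WT", n_wt), rep("case", n_case))
  samples <- sprintf("%s_%d", groups, c(seq_len(n_wt), seq_len(n_case)))

  expressed_idx <- seq_len(d$n_expressed)          # housekeeping lead the list
  mu <- rep(d$background_mean, d$n_features)
  mu[expressed_idx] <- d$expressed_mean
  mu[seq_len(n_hk)] <- d$housekeeping_level

  counts <- with_seed(d$seed, {
    spiked_idx <- sample((n_hk + 1):d$n_expressed, d$n_spiked)
    sf <- if (d$scale_sd > 0) exp(stats::rnorm(n_samp, 0, d$scale_sd)) else
      rep(1, n_samp)
    m <- matrix(0L, d$n_features, n_samp)
    for (s in seq_len(n_samp)) {
      mu_s <- mu
      if (groups[s] == "case") mu_s[spiked_idx] <- mu_s[spiked_idx] * d$fold_change
      mu_s <- mu_s * sf[s]
      if (d$dispersion > 0) {
        m[, s] <- stats::rnbinom(d$n_features, mu = mu_s,
                                 size = 1 / d$dispersion)
      } else {
        m[, s] <- stats::rpois(d$n_features, mu_s)
      }
      m[seq_len(n_hk), s] <- round(d$housekeeping_level * sf[s])  # stable refs
    }
    attr(m, "spiked_idx") <- spiked_idx
    attr(m, "sf") <- sf
    m
  })
  spiked_idx <- attr(counts, "spiked_idx")
  sf <- attr(counts, "sf")
  attributes(counts) <- list(dim = dim(counts))
  dimnames(counts) <- list(feat, samples)

  cm <- count_matrix(counts, groups = groups,
                     housekeeping = d$housekeeping_names, kind = "miRNA_counts")
  attr(cm, "truth") <- data.frame(
    feature = feat,
    spiked = seq_len(d$n_features) %in% spiked_idx,
    fold_change = ifelse(seq_len(d$n_features) %in% spiked_idx,
                         d$fold_change, 1),
    expressed_design = seq_len(d$n_features) %in% expressed_idx,
    stringsAsFactors = FALSE
  )
  attr(cm, "scale_factors") <- sf
  cm
}

#' Simulate a fluorescence image with known positive area and object count
#'
#' Places `n_objects` disjoint rectangular blobs on a dark background so that
#' the total above-threshold pixel fraction equals `positive_fraction` to
#' within one pixel. Blobs are separated by at least `min_separation` pixels,
#' so connected-component counting recovers `n_objects` exactly.
#'
#' @param width,height image size in pixels.
#' @param positive_fraction target fraction of bright pixels in [0, 1].
#' @param n_objects number of disjoint blobs (0 allowed iff fraction is 0).
#' @param seed integer seed (controls cell shuffling only).
#' @param min_separation minimum gap between blob bounding boxes, px.
#' @param fg,bg foreground and background intensities.
#' @return numeric matrix `height x width` with attribute `truth`
#'   (list: n_positive_px, positive_fraction, n_objects).
#' @export
simulate_if_image <- function(width, height, positive_fraction, n_objects,
                              seed = 1, min_separation = 2, fg = 1, bg = 0) {
  check_scalar(positive_fraction, "positive_fraction", lower = 0, upper = 1)
  check_scalar(n_objects, "n_objects", lower = 0)
  img <- matrix(bg, nrow = height, ncol = width)
  target_px <- round(positive_fraction * width * height)
  if (target_px == 0 || n_objects == 0) {
    if (target_px > 0) stop("positive_fraction > 0 requires n_objects >= 1")
    attr(img, "truth") <- list(n_positive_px = 0L, positive_fraction = 0,
                               n_objects = 0L)
    return(img)
  }
  n_objects <- as.integer(n_objects)
  base <- target_px %/% n_objects
  areas <- rep(base, n_objects)
  areas[seq_len(target_px - base * n_objects)] <-
    areas[seq_len(target_px - base * n_objects)] + 1L
  if (any(areas < 1)) stop("positive_fraction too small for n_objects")

  # grid of cells, one blob per cell
  ncx <- ceiling(sqrt(n_objects * width / height))
  ncy <- ceiling(n_objects / ncx)
  cw <- width %/% ncx; ch <- height %/% ncy
  max_w <- cw - min_separation; max_h <- ch - min_separation
  if (max_w < 1 || max_h < 1) stop("too many objects for the image size")
  cells <- with_seed(seed, sample(ncx * ncy))[seq_len(n_objects)]
  for (k in seq_len(n_objects)) {
    a <- areas[k]
    w <- min(max_w, ceiling(sqrt(a)))
    h_full <- a %/% w
    rem <- a %% w
    if (h_full + (rem > 0) > max_h) {
      stop("infeasible positive_fraction / n_objects combination")
    }
    cell <- cells[k] - 1L
    cx <- (cell %% ncx) * cw; cy <- (cell %/% ncx) * ch
    r0 <- cy + 1L; c0 <- cx + 1L
    if (h_full > 0) img[r0:(r0 + h_full - 1L), c0:(c0 + w - 1L)] <- fg
    if (rem > 0) img[r0 + h_full, c0:(c0 + rem - 1L)] <- fg
  }
  stopifnot(sum(img == fg) == target_px)
  attr(img, "truth") <- list(n_positive_px = target_px,
                             positive_fraction = target_px / (width * height),
                             n_objects = n_objects)
  img
}
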