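# Cycle-metrics module: hysteresis-gated zero-crossing detection of
# contraction cycles and the three motility endpoints (contraction count,
# mean full-cycle interval, peristaltic wave velocity).

# Schmitt-trigger onsets for one locus. A contraction onset is registered when
# the signal, having last been above +h/2, falls below -h/2; the onset time is
# the linearly interpolated zero crossing between those two threshold
# passages. Returns onset times in seconds (0-based frames).
schmitt_onsets <- function(x, hysteresis, fps) {
  h2 <- hysteresis / 2
  s <- integer(length(x))
  s[x > h2] <- 1L
  s[x < -h2] <- -1L
  nz <- which(s != 0L)
  if (length(nz) < 2) return(numeric(0))
  v <- s[nz]
  starts <- c(TRUE, v[-1] != v[-length(v)])
  run_val <- v[starts]
  run_first <- nz[starts]
  run_last <- c(nz[which(starts)[-1] - 1L], nz[length(nz)])
  onsets <- numeric(0)
  for (k in which(run_val[-length(run_val)] == 1L & run_val[-1] == -1L)) {
    j1 <- run_last[k]         # last frame above +h/2
    j2 <- run_first[k + 1L]   # first frame below -h/2
    seg <- x[j1:j2]
    m <- max(which(seg >= 0))          # final descent through zero
    a <- j1 + m - 1L
    t0 <- ((a - 1L) + x[a] / (x[a] - x[a + 1L])) / fps
    onsets <- c(onsets, t0)
  }
  onsets
}

#' Detect contraction cycles with a hysteresis-gated zero-crossing trigger
#'
#' Runs a Schmitt-trigger state machine per locus on the signed amplitude (mm):
#' an onset ("leading edge") is the interpolated zero crossing between the last
#' passage above `+hysteresis_mm/2` and the subsequent passage below
#' `-hysteresis_mm/2`. The dual threshold suppresses noise-induced false
#' triggering by signals that stay inside the band. Only full cycles
#' (onset-to-onset) enter the interval lists; partial cycles at the trace
#' boundaries are discarded.
#'
#' @param map an `st_map` from [baseline_correct()].
#' @param hysteresis_mm total hysteresis band width, mm (> 0). Default 0.075,
#'   the midpoint of the 0.05-0.1 mm range used in ex vivo recordings.
#' @return an object of class `cycle_set`: per-locus onset times (s), per-locus
#'   full-cycle intervals (s), plus calibration.
#' @export
detect_cycles <- function(map, hysteresis_mm = 0.075) {
  stopifnot(inherits(map, "st_map"))
  check_scalar(hysteresis_mm, "hysteresis_mm", lower = 1e-12)
  onsets <- apply(map$amplitude, 1, schmitt_onsets,
                  hysteresis = hysteresis_mm, fps = map$fps,
                  simplify = FALSE)
  intervals <- lapply(onsets, function(o)
    if (length(o) >= 2) diff(o) else numeric(0))
  structure(list(onsets = onsets, intervals = intervals,
                 hysteresis = hysteresis_mm, fps = map$fps,
                 spacing = map$spacing,
                 duration = ncol(map$amplitude) / map$fps),
            class = "cycle_set")
}

#' Mean full-cycle interval
#'
#' Averages the full-cycle durations per locus, then takes the unweighted mean
#' over all loci that detected at least one full cycle (per-locus-then-grand
#' mean, not a pooled mean over all cycles).
#'
#' @param cycles a `cycle_set`.
#' @return mean interval in seconds, or `NA` if no locus has a full cycle.
#' @export
mean_interval <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  per_locus <- vapply(cycles$intervals, function(iv)
    if (length(iv)) mean(iv) else NA_real_, numeric(1))
  if (all(is.na(per_locus))) return(NA_real_)
  mean(per_locus, na.rm = TRUE)
}

#' Contraction count per reporting window
#'
#' The median over loci of the per-locus onset counts, rescaled from the trace
#' duration to the reporting window (per minute or per 10 minutes). The median
#' is robust against a dead locus at the segment edge.
#'
#' @param cycles a `cycle_set`.
#' @param window `"per_min"` or `"per_10min"`.
#' @return contractions per reporting window.
#' @export
contraction_count <- function(cycles, window = c("per_min", "per_10min")) {
  stopifnot(inherits(cycles, "cycle_set"))
  window <- match.arg(window)
  if (cycles$duration <= 0) stop("zero-duration trace")
  n <- stats::median(vapply(cycles$onsets, length, integer(1)))
  n * (if (window == "per_min") 60 else 600) / cycles$duration
}

# Assemble propagating waves by chaining onsets across adjacent loci.
# Adjacent-locus onset lag must stay below `gate` seconds.
assemble_waves <- function(onsets, gate) {
  n_loci <- length(onsets)
  used <- lapply(onsets, function(o) rep(FALSE, length(o)))
  waves <- list()
  for (i0 in seq_len(n_loci)) {
    for (j0 in seq_along(onsets[[i0]])) {
      if (used[[i0]][j0]) next
      loci <- i0; times <- onsets[[i0]][j0]
      used[[i0]][j0] <- TRUE
      t_prev <- times
      i <- i0
      while (i < n_loci) {
        i <- i + 1L
        cand <- which(!used[[i]])
        if (!length(cand)) break
        lag <- abs(onsets[[i]][cand] - t_prev)
        best <- cand[which.min(lag)]
        if (min(lag) >= gate) break
        used[[i]][best] <- TRUE
        loci <- c(loci, i); times <- c(times, onsets[[i]][best])
        t_prev <- onsets[[i]][best]
      }
      waves[[length(waves) + 1L]] <- list(loci = loci, times = times)
    }
  }
  waves
}

#' Peristaltic wave velocity
#'
#' Assembles individual contraction waves by matching onsets across adjacent
#' loci (the adjacent-locus lag must stay below half the local mean cycle
#' interval, preventing distinct waves from being chained), then fits onset
#' time against locus position by least squares for each wave spanning at
#' least `min_loci` consecutive loci. The wave velocity is the inverse slope
#' (mm/s, aboral positive); the segment velocity is the mean over accepted
#' waves. Waves whose absolute slope is below the timing resolution across the
#' segment are flagged synchronous and excluded with a warning.
#'
#' @param map an `st_map` (used for calibration).
#' @param cycles the matching `cycle_set`.
#' @param min_loci minimum loci a wave must traverse (guards against spurious
#'   short fits).
#' @return list with `velocity` (mm/s, `NA` if no wave qualifies), `n_waves`
#'   used, `wave_velocities`, and `n_synchronous` flagged waves.
#' @export
wave_velocity <- function(map, cycles, min_loci = 10) {
  stopifnot(inherits(map, "st_map"), inherits(cycles, "cycle_set"))
  mi <- mean_interval(cycles)
  if (is.na(mi)) {
    return(list(velocity = NA_real_, n_waves = 0L,
                wave_velocities = numeric(0), n_synchronous = 0L))
  }
  gate <- mi / 2
  waves <- assemble_waves(cycles$onsets, gate)
  span_mm <- (length(cycles$onsets) - 1) * cycles$spacing
  min_slope <- (1 / cycles$fps) / max(span_mm, 1e-9)  # one frame across segment
  vels <- numeric(0); n_sync <- 0L
  for (w in waves) {
    if (length(w$loci) < min_loci) next
    pos <- (w$loci - 1) * cycles$spacing
    slope <- stats::coef(stats::lm(w$times ~ pos))[["pos"]]
    if (abs(slope) < min_slope) {
      n_sync <- n_sync + 1L
    } else {
      vels <- c(vels, 1 / slope)
    }
  }
  if (n_sync > 0) {
    warning(sprintf("%d wave(s) flagged synchronous (no resolvable slope)",
                    n_sync))
  }
  list(velocity = if (length(vels)) mean(vels) else NA_real_,
       n_waves = length(vels), wave_velocities = vels,
       n_synchronous = n_sync)
}

#' Summarize motility endpoints for one segment
#'
#' Bundles [detect_cycles()], [contraction_count()], [mean_interval()] and
#' [wave_velocity()] into a single serializable summary. Missing endpoints are
#' reported as `NA`, never as fabricated zeros (a flat trace yields rate 0 but
#' interval and velocity `NA`).
#'
#' @param map an `st_map`.
#' @param hysteresis_mm hysteresis band width, mm.
#' @param window reporting window for the contraction rate.
#' @param min_loci minimum wave span for the velocity fit.
#' @return an object of class `motility_summary` (also a plain list):
#'   contraction_rate, mean_interval_s, velocity_mm_s, n_waves_used,
#'   reporting_window, hysteresis_mm.
#' @export
summarize_motility <- function(map, hysteresis_mm = 0.075,
                               window = c("per_min", "per_10min"),
                               min_loci = 10) {
  window <- match.arg(window)
  cycles <- detect_cycles(map, hysteresis_mm)
  vel <- wave_velocity(map, cycles, min_loci = min_loci)
  structure(list(
    contraction_rate = contraction_count(cycles, window),
    mean_interval_s = mean_interval(cycles),
    velocity_mm_s = vel$velocity,
    n_waves_used = vel$n_waves,
    n_synchronous = vel$n_synchronous,
    reporting_window = window,
    hysteresis_mm = hysteresis_mm
  ), class = "motility_summary")
}
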