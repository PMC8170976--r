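# Shared fixtures: canonical study conditions and pipeline shortcuts.

# Small-intestine-like recording conditions (fast cycles, 1 min).
si_params <- function(...) {
  args <- list(...)
  defaults <- list(frequency = 40, amplitude = 0.4, velocity = 15,
                   drift_amplitude = 0.5, drift_period = 120,
                   noise_sd = 0.02, duration = 60, fps = 25, n_loci = 30,
                   segment_length = 2)
  do.call(wave_params, utils::modifyList(defaults, args))
}

# Large-intestine-like recording conditions (slow cycles, 10 min).
li_params <- function(...) {
  args <- list(...)
  defaults <- list(frequency = 60 / 70, amplitude = 0.4, velocity = 0.9,
                   drift_amplitude = 0.15, drift_period = 2400,
                   noise_sd = 0.01, duration = 600, fps = 25, n_loci = 30,
                   segment_length = 2)
  do.call(wave_params, utils::modifyList(defaults, args))
}

# simulate -> baseline-correct in one step.
make_map <- function(params, window_s = 20) {
  baseline_correct(simulate_trace(params), window_s = window_s)
}

# Wrap a bare amplitude matrix (already baseline-free) as an st_map.
amplitude_map <- function(amplitude, fps = 25, spacing = 20 / nrow(amplitude),
                          segment_length = 2) {
  structure(list(amplitude = amplitude,
                 baseline = matrix(2, nrow(amplitude), ncol(amplitude)),
                 normalized = NULL, fps = fps, spacing = spacing,
                 segment_length = segment_length, window_s = NA),
            class = "st_map")
}

# Brute-force oracle: descending zero crossings of a noise-free signal.
count_descending_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(s[-1] == -1 & s[-length(s)] == 1)
}

# Minimal cycle_set for aggregation tests.
make_cycle_set <- function(onsets, duration, fps = 25, spacing = 0.667) {
  structure(list(onsets = onsets,
                 intervals = lapply(onsets, function(o)
                   if (length(o) >= 2) diff(o) else numeric(0)),
                 hysteresis = 0.075, fps = fps, spacing = spacing,
                 duration = duration),
            class = "cycle_set")
}
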