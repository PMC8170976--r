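# Motility maps: edge tracking, baseline correction, normalization, rendering
# and trace round-trips.

test_that("edge tracking recovers a constant tube exactly", {
  flat <- diameter_trace(matrix(2, 6, 60), fps = 25, spacing = 20 / 6,
                         segment_length = 2)
  st <- render_frames(flat, px_per_mm = 20)
  rec <- track_edges(st, n_loci = 6, px_per_mm = 20, fps = 25)
  expect_equal(rec$values, flat$values, tolerance = 1e-12)
})

test_that("render -> track round-trip stays within one pixel", {
  tr <- simulate_trace(si_params(duration = 10, seed = 5))
  st <- render_frames(tr, px_per_mm = 20)
  rec <- track_edges(st, n_loci = 30, px_per_mm = 20, fps = 25)
  expect_lte(max(abs(rec$values - tr$values)) * 20, 1)
})

test_that("edge tracking is invariant to affine intensity rescaling", {
  tr <- simulate_trace(si_params(duration = 5, seed = 6))
  st <- render_frames(tr, px_per_mm = 20)
  rec1 <- track_edges(st, n_loci = 30, px_per_mm = 20, fps = 25)
  rec2 <- track_edges(st * 0.4 + 0.1, n_loci = 30, px_per_mm = 20, fps = 25)
  expect_equal(rec1$values, rec2$values, tolerance = 1e-12)
})

test_that("undetectable frames are flagged, interpolated, and capped", {
  flat <- diameter_trace(matrix(2, 5, 60), fps = 25, spacing = 4,
                         segment_length = 2)
  st <- render_frames(flat, px_per_mm = 20)
  st[, , 10] <- 0                      # all-dark frame
  rec <- track_edges(st, n_loci = 5, px_per_mm = 20, fps = 25)
  expect_true(all(attr(rec, "flagged")[, 10]))
  expect_equal(rec$values[, 10], rep(2, 5), tolerance = 1e-12)

  st[, , 2:12] <- 0                    # > 10% of frames dark
  expect_error(track_edges(st, n_loci = 5, px_per_mm = 20, fps = 25),
               "undetectable")
})

test_that("baseline + amplitude reconstructs the trace exactly", {
  tr <- simulate_trace(si_params(seed = 7))
  m <- baseline_correct(tr, window_s = 20)
  expect_lt(max(abs(m$amplitude + m$baseline - tr$values)), 1e-9)
})

test_that("baseline correction acts independently per locus", {
  tr <- simulate_trace(si_params(duration = 20, seed = 8))
  perm <- sample(nrow(tr$values))
  tr_perm <- tr
  tr_perm$values <- tr$values[perm, ]
  m <- baseline_correct(tr, window_s = 10)
  m_perm <- baseline_correct(tr_perm, window_s = 10)
  expect_equal(m_perm$amplitude[order(perm), ], m$amplitude,
               tolerance = 1e-12)
})

test_that("slow components are removed and constants are preserved", {
  # pure linear drift, zero wave: amplitude ~ 0
  p <- si_params(amplitude = 0, frequency = 0, drift_amplitude = 0,
                 ramp = 0.005, noise_sd = 0, seed = 1)
  m <- baseline_correct(simulate_trace(p), window_s = 20)
  expect_lt(max(abs(m$amplitude)), 0.01)

  # constant trace: baseline equals the constant, amplitude exactly 0
  flat <- diameter_trace(matrix(1.8, 4, 200), fps = 25, spacing = 5,
                         segment_length = 2)
  mf <- baseline_correct(flat, window_s = 4)
  expect_true(all(mf$amplitude == 0))
  expect_true(all(mf$baseline == 1.8))

  expect_error(baseline_correct(flat, window_s = 0.05), "window_s")
})

test_that("drift does not move cycle metrics by more than 1%", {
  # 120 s so the integer count quantum (0.5 median step) stays below 1%
  s_drift <- summarize_motility(make_map(si_params(duration = 120, seed = 12)))
  s_clean <- summarize_motility(make_map(si_params(duration = 120,
                                                   drift_amplitude = 0,
                                                   seed = 12)))
  expect_lt(abs(s_drift$contraction_rate / s_clean$contraction_rate - 1), 0.01)
  expect_lt(abs(s_drift$mean_interval_s / s_clean$mean_interval_s - 1), 0.01)
  expect_lt(abs(s_drift$velocity_mm_s / s_clean$velocity_mm_s - 1), 0.01)
})

test_that("normalization divides by the initial diameter and keeps signs", {
  amp <- matrix(-0.2, 2, 100)
  m <- amplitude_map(amp)
  m$baseline <- matrix(2.2, 2, 100)            # raw trace = 2 mm everywhere
  nm <- normalize_map(m)
  expect_equal(nm$normalized, matrix(-0.10, 2, 100), tolerance = 1e-12)

  # doubling amplitude and initial diameter leaves normalized unchanged
  m2 <- m
  m2$amplitude <- 2 * m$amplitude
  m2$baseline <- 2 * m$baseline
  expect_equal(normalize_map(m2)$normalized, nm$normalized, tolerance = 1e-12)

  # zero-amplitude map normalizes to all zeros
  m0 <- m
  m0$amplitude <- matrix(0, 2, 100)
  expect_true(all(normalize_map(m0)$normalized == 0))

  # non-positive initial diameter is an error
  bad <- m
  bad$baseline <- matrix(0, 2, 100)
  expect_error(normalize_map(bad), "initial diameter")
})

test_that("heatmap rendering is deterministic and zero maps are mid-scale", {
  m <- amplitude_map(matrix(0, 4, 50))
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_heatmap(m, f1, limits = 0.5)
  render_heatmap(m, f2, limits = 0.5)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(all(png::readPNG(f1) == 1))      # white = zero amplitude

  # a single propagating wave leaves one oblique band whose ridge slope
  # corresponds to the generator velocity
  p <- si_params(frequency = 2, velocity = 10, duration = 30, noise_sd = 0,
                 drift_amplitude = 0, seed = 1)
  tr <- simulate_trace(p)
  ridge <- apply(tr$values, 1, which.min) / tr$fps  # trough centre per locus
  pos <- (seq_len(nrow(tr$values)) - 1) * tr$spacing
  slope <- stats::coef(stats::lm(ridge ~ pos))[["pos"]]
  expect_equal(1 / slope, 10, tolerance = 0.02)
})

test_that("traces and frame stacks survive file round-trips", {
  tr <- simulate_trace(si_params(duration = 4, n_loci = 5, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$values, tr$values, tolerance = 1e-6)
  expect_equal(back$fps, tr$fps)
  expect_equal(back$spacing, tr$spacing)

  st <- render_frames(tr, px_per_mm = 10)
  tf <- tempfile(fileext = ".tif")
  write_frames(st, tf)
  st2 <- read_frames(tf)
  expect_equal(dim(st2), dim(st))
  expect_lt(max(abs(st2 - st)), 1 / 255)
})
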