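test_that("degenerate one-state chain fills the requested duration", {
  d <- cohort_design(n_per_group = 1, handling = "TH", treatment = "Veh",
                     duration_h = 80 / 3600, seed = 1, allowed_states = "W")
  truth <- sample_hypnogram(d)
  expect_equal(nrow(truth$hypnogram), 10)
  expect_true(all(truth$hypnogram$state == "W"))
})

test_that("same seed and parameters reproduce the hypnogram exactly", {
  d <- quick_design(duration_h = 2, seed = 9)
  a <- sample_hypnogram(d, animal_index = 3)
  b <- sample_hypnogram(d, animal_index = 3)
  expect_identical(as.character(a$hypnogram$state),
                   as.character(b$hypnogram$state))
  expect_identical(a$seed, b$seed)
  # explicit seed overrides the derived one
  c1 <- sample_hypnogram(d, rng_seed = 77)
  c2 <- sample_hypnogram(d, rng_seed = 77)
  expect_identical(as.character(c1$hypnogram$state),
                   as.character(c2$hypnogram$state))
})

test_that("cage change inflates time to the first long NREM bout", {
  d <- cohort_design(duration_h = 4, seed = 3)
  mean_lat <- function(handling, n = 60) {
    mean(vapply(seq_len(n), function(i) {
      h <- sample_hypnogram(d, i, handling = handling, treatment = "Veh")$hypnogram
      l <- sleep_latency(h)
      if (l$censored) 4 * 3600 else l$latency_s
    }, numeric(1)))
  }
  expect_gt(mean_lat("CC"), mean_lat("TH"))
})

test_that("REM is never entered directly from wake", {
  d <- cohort_design(duration_h = 8, seed = 5)
  for (cell in list(c("TH", "Veh"), c("CC", "DIPH"))) {
    st <- as.character(
      sample_hypnogram(d, 1, handling = cell[1], treatment = cell[2])$hypnogram$state
    )
    r_idx <- which(st == "R")
    r_idx <- r_idx[r_idx > 1]
    expect_false(any(st[r_idx - 1] == "W"))
  }
})

test_that("long-run occupancy matches the semi-Markov stationary law", {
  sp <- default_state_params()
  for (s in names(sp)) sp[[s]]$dark_dwell_mult <- 1
  d <- cohort_design(
    n_per_group = 1, handling = "TH", treatment = "Veh",
    duration_h = 48, seed = 2, state_params = sp,
    transitions = transition_params(p_nrem_to_rem = c(light = 0.35, dark = 0.35),
                                    arousal_rate = 0)
  )
  occ_th <- stationary_occupancy(d, "light")
  emp <- rowMeans(vapply(1:8, function(i) {
    as.numeric(table(sample_hypnogram(d, i)$hypnogram$state)) / (48 * 450)
  }, numeric(3)))
  expect_lt(max(abs(occ_th - emp)), 0.02)
})

test_that("unreachable configurations raise a configuration error", {
  d <- quick_design()
  d$allowed_states <- c("W", "R") # from W only N is reachable
  expect_error(sample_hypnogram(d), "unnormalizable")
  expect_error(cohort_design(duration_h = 0), "duration")
  expect_error(cohort_design(duration_h = 1 / 3600), "whole number")
})

test_that("state parameter invariants are enforced", {
  sp <- default_state_params()
  sp$W$band_amplitudes[["delta"]] <- 10 # wake delta above NREM
  expect_error(cohort_design(state_params = sp), "delta")
  sp <- default_state_params()
  sp$N$emg_amplitude <- 5 # NREM EMG above wake
  expect_error(cohort_design(state_params = sp), "EMG")
  expect_error(state_params("W", c(delta = 1, theta = 1, sigma = 1, beta = 1),
                            emg_amplitude = -1, dwell_mean = 10,
                            dwell_shape = 0.5), "amplitudes")
})

test_that("zero amplitudes with quantization off give all-zero signals", {
  d <- quick_design(duration_h = 80 / 3600)
  truth <- sample_hypnogram(d)
  sp <- default_state_params()
  for (s in names(sp)) {
    sp[[s]]$band_amplitudes[] <- 0
    sp[[s]]$emg_amplitude <- 0
  }
  rec <- synthesize_signals(truth, state_params = sp, background = 0)
  expect_true(all(rec$eeg == 0))
  expect_true(all(rec$emg == 0))
  expect_length(rec$eeg, 10 * 8 * 125)
  expect_length(rec$emg, 10 * 8 * 250)
})

test_that("per-band epoch powers scale as amplitude squared", {
  d <- quick_design(duration_h = 0.2, seed = 6)
  truth <- sample_hypnogram(d)
  sp <- default_state_params()
  sp2 <- lapply(sp, function(p) {
    p$band_amplitudes <- p$band_amplitudes * 2
    p
  })
  r1 <- synthesize_signals(truth, sp, rng_seed = 11, background = 0)
  r2 <- synthesize_signals(truth, sp2, rng_seed = 11, background = 0)
  p1 <- eeg_band_powers(r1$eeg)
  p2 <- eeg_band_powers(r2$eeg)
  for (b in c("delta", "theta", "sigma", "beta")) {
    expect_equal(p2[[b]], 4 * p1[[b]], tolerance = 1e-8)
  }
})

test_that("synthetic NREM delta dominates sigma under a 10x amplitude ratio", {
  hyp <- hypnogram(rep("N", 40))
  sp <- default_state_params()
  sp$N$band_amplitudes <- c(delta = 2.0, theta = 0.5, sigma = 0.2, beta = 0.3)
  rec <- synthesize_signals(hyp, sp, rng_seed = 8, background = 0)
  # independent periodogram oracle on raw samples
  spec <- stats::spec.pgram(stats::ts(rec$eeg, frequency = 125), plot = FALSE,
                            taper = 0, detrend = TRUE)
  pow_in <- function(lo, hi) sum(spec$spec[spec$freq >= lo & spec$freq < hi])
  expect_gt(pow_in(0.16, 4), pow_in(10, 14))
  # matches the roughly 100x power ratio up to estimation error
  expect_gt(pow_in(0.16, 4) / pow_in(10, 14), 20)
})

test_that("wake epochs carry more EMG band power than sleep epochs", {
  d <- quick_design(duration_h = 1, seed = 13)
  truth <- sample_hypnogram(d)
  rec <- synthesize_signals(truth)
  em <- emg_band_power(rec$emg)
  st <- as.character(truth$hypnogram$state)
  expect_gt(min(em$emg_power[st == "W"]), max(em$emg_power[st != "W"]))
})

test_that("12-bit quantization stays within half a step of the input", {
  d <- quick_design(duration_h = 80 / 3600, seed = 2)
  recf <- synthesize_signals(sample_hypnogram(d), quantize = FALSE)
  fs <- 1.2 * max(abs(recf$eeg))
  rec <- synthesize_signals(sample_hypnogram(d), quantize = TRUE,
                            full_scale = fs)
  expect_lte(max(abs(rec$eeg - recf$eeg)), fs / 2047 / 2 + 1e-12)
  expect_lte(length(unique(rec$eeg)), 4096)
})

test_that("cohort generation is deterministic bookkeeping", {
  d <- cohort_design(n_per_group = 2, handling = "TH", treatment = "Veh",
                     duration_h = 0.1, seed = 4)
  m1 <- generate_cohort(d)
  expect_equal(nrow(m1), 2)
  expect_length(unique(m1$seed), 2)
  m2 <- generate_cohort(d)
  expect_identical(m1$recording[[1]]$eeg, m2$recording[[1]]$eeg)
  expect_identical(as.character(m1$truth[[2]]$hypnogram$state),
                   as.character(m2$truth[[2]]$hypnogram$state))

  full <- cohort_design(n_per_group = 8, duration_h = 0.1, seed = 4)
  mf <- generate_cohort(full, signals = FALSE)
  expect_equal(nrow(mf), 48)
  expect_equal(length(unique(mf$animal_id)), 48)
  # growing the cohort preserves existing animals
  d3 <- cohort_design(n_per_group = 3, handling = "TH", treatment = "Veh",
                      duration_h = 0.1, seed = 4)
  m3 <- generate_cohort(d3, signals = FALSE)
  expect_identical(m3$seed[1:2], m1$seed)
})

test_that("cohort files are written with a manifest", {
  dir <- withr::local_tempdir()
  d <- cohort_design(n_per_group = 1, handling = "CC", treatment = "PS150",
                     duration_h = 0.1, seed = 10)
  m <- generate_cohort(d, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(m$hypnogram_file)))
  expect_true(all(file.exists(m$signal_file)))
  rt <- read_hypnogram(m$hypnogram_file[1])
  expect_identical(as.character(rt$state),
                   as.character(m$truth[[1]]$hypnogram$state))
})
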