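#' Sample a ground-truth hypnogram from the semi-Markov generator
#'
#' Draws one animal's vigilance-state sequence on the 8-s epoch grid. Dwell
#' times are log-normal per state (rounded up to whole epochs, minimum one),
#' REM is entered only from NREM, and transition probabilities switch between
#' a light and a dark regime at ZT 12. Cage-changed animals begin with a wake
#' dwell drawn from the FNE-inflated distribution, carry early-light dwell
#' modifiers, and have NREM-to-REM entries suppressed over the first hours
#' (see [fne_params()]); treatment presets apply their multipliers (see
#' [treatment_presets()]).
#'
#' @param design A [cohort_design()].
#' @param animal_index Animal index within the design cell (used for seed
#'   derivation when `rng_seed` is not given).
#' @param rng_seed Integer seed; defaults to a hash of the design seed, the
#'   cell and `animal_index`.
#' @param handling,treatment The design cell to simulate (defaults: first
#'   listed level of each factor).
#' @return A `psg_truth` list: `hypnogram` (a [hypnogram()] tibble), `params`
#'   (the full generator configuration) and `seed`.
#' @export
#' @examples
#' d <- cohort_design(duration_h = 1, seed = 7)
#' truth <- sample_hypnogram(d, animal_index = 1)
#' table(truth$hypnogram$state)
sample_hypnogram <- function(design, animal_index = 1, rng_seed = NULL,
                             handling = design$handling[1],
                             treatment = design$treatment[1]) {
  stopifnot(inherits(design, "cohort_design"))
  handling <- match.arg(handling, c("TH", "CC"))
  treatment <- match.arg(treatment, c("Veh", "DIPH", "PS150"))
  if (is.null(rng_seed)) {
    rng_seed <- derive_seed(design$seed, handling, treatment, animal_index)
  }
  n_ep <- as.integer(round(design$duration_h * 3600 / psg_epoch_len()))
  eff <- design$effects[[treatment]] %||%
    stop("no effect preset for treatment ", treatment, call. = FALSE)
  sp <- design$state_params
  tr <- design$transitions
  fne <- design$fne
  allowed <- design$allowed_states

  states <- withr::with_seed(rng_seed, sim_state_sequence(
    n_ep, sp, tr, fne, eff, allowed, handling, design$zt_start
  ))

  hyp <- hypnogram(states,
    zt_start = design$zt_start,
    animal_id = sprintf("%s-%s-%02d", handling, treatment, animal_index),
    handling = handling, treatment = treatment
  )
  structure(
    list(
      hypnogram = hyp,
      params = list(
        state_params = sp, transitions = tr, fne = fne, effect = eff,
        handling = handling, treatment = treatment,
        duration_h = design$duration_h, zt_start = design$zt_start
      ),
      seed = rng_seed
    ),
    class = "psg_truth"
  )
}

# core sequential sampler; runs inside a seeded scope
sim_state_sequence <- function(n_ep, sp, tr, fne, eff, allowed, handling,
                               zt_start) {
  ep_len <- psg_epoch_len()
  if (length(allowed) == 1) {
    return(rep(allowed, n_ep))
  }
  start_state <- if ("W" %in% allowed) "W" else allowed[1]
  out <- character(0)
  cur <- start_state
  first <- TRUE
  t_ep <- 0L
  while (t_ep < n_ep) {
    zt <- zt_start + t_ep * ep_len
    dark <- (zt / 3600) %% 24 >= 12
    since_h <- (t_ep * ep_len) / 3600 # hours since recording start

    p <- sp[[cur]]
    m <- p$dwell_mean * if (dark) p$dark_dwell_mult else 1
    s <- p$dwell_shape
    if (first && cur == "W" && handling == "CC") {
      m <- fne$initial_wake_mean * eff$initial_wake_mult
      s <- fne$initial_wake_shape
    } else if (handling == "CC" && since_h < fne$early_hours) {
      if (cur == "W") m <- m * fne$early_wake_mult
      if (cur == "N") m <- m * fne$early_nrem_mult
    }
    if (cur == "R") m <- m * eff$rem_dwell_mult
    dwell_s <- rlnorm(1, meanlog = log(m) - s^2 / 2, sdlog = s)
    k <- max(1L, as.integer(ceiling(dwell_s / ep_len)))
    run <- rep(cur, k)
    if (cur == "N" && k >= 3 && "W" %in% allowed) {
      rate <- tr$arousal_rate * eff$arousal_mult
      run <- insert_arousals(k, rate, tr$arousal_len_epochs)
    }
    out <- c(out, run)
    t_ep <- t_ep + length(run)
    first <- FALSE

    cur <- next_state(cur, tr, dark, since_h, handling, fne, allowed)
  }
  out[seq_len(n_ep)]
}

# brief wake interruptions at interior positions of a NREM run; the run always
# starts and ends in NREM so REM can never directly follow wake
insert_arousals <- function(k, rate, len_choices) {
  interior <- 2:(k - 1)
  hits <- interior[runif(length(interior)) < rate]
  if (length(hits) == 0) return(rep("N", k))
  pieces <- list()
  prev <- 0L
  for (h in hits) {
    pieces <- c(pieces, list(rep("N", h - prev)),
                list(rep("W", len_choices[sample.int(length(len_choices), 1)])))
    prev <- h
  }
  pieces <- c(pieces, list(rep("N", k - prev)))
  unlist(pieces)
}

next_state <- function(cur, tr, dark, since_h, handling, fne, allowed) {
  phase <- if (dark) "dark" else "light"
  probs <- c(W = 0, N = 0, R = 0)
  if (cur == "W") {
    probs["N"] <- 1
  } else if (cur == "N") {
    p_r <- unname(tr$p_nrem_to_rem[phase])
    if (handling == "CC") {
      h_idx <- floor(since_h) + 1
      if (h_idx <= length(fne$rem_suppression)) {
        p_r <- p_r * fne$rem_suppression[h_idx]
      }
    }
    probs["R"] <- p_r
    probs["W"] <- 1 - p_r
  } else {
    probs["W"] <- tr$p_rem_to_wake
    probs["N"] <- 1 - tr$p_rem_to_wake
  }
  probs[setdiff(names(probs), allowed)] <- 0
  tot <- sum(probs)
  if (tot <= 0) {
    stop("unnormalizable transition probabilities from state ", cur,
         " with allowed states {", paste(allowed, collapse = ","), "}",
         call. = FALSE)
  }
  sample(names(probs), 1, prob = probs / tot)
}

#' Gaussian noise band-limited by Fourier masking
#'
#' White Gaussian noise whose spectrum is zeroed outside `[lo, hi)`,
#' normalized to unit standard deviation. Used as the building block of the
#' synthetic EEG/EMG channels.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges (Hz).
#' @param exponent Spectral tilt: amplitude weighted by `f^exponent` inside
#'   the band (0 = flat; -0.5 gives a 1/f power background).
#' @return Numeric vector of length `n` with `sd` 1 (all-zero if the band is
#'   empty).
#' @export
band_noise <- function(n, fs, lo, hi, exponent = 0) {
  # draw only the in-band Hermitian spectrum, then one inverse FFT
  kk <- which_band_bins(n, fs, lo, hi)
  if (length(kk) == 0) return(numeric(n))
  x_f <- complex(length.out = n)
  f <- (kk - 1) * fs / n
  amp <- if (exponent == 0) rep(1, length(kk)) else pmax(f, fs / n)^exponent
  z <- complex(real = rnorm(length(kk)), imaginary = rnorm(length(kk))) * amp
  x_f[kk] <- z
  x_f[n + 2 - kk] <- Conj(z)
  x <- Re(fft(x_f, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  x / s
}

# 1-based indices of positive-frequency bins with lo <= f < hi (DC and
# Nyquist excluded)
which_band_bins <- function(n, fs, lo, hi) {
  k_lo <- max(2L, as.integer(ceiling(lo * n / fs)) + 1L)
  k_hi <- min(as.integer(ceiling(hi * n / fs)), (n + 1L) %/% 2L)
  if (k_hi < k_lo) integer(0) else k_lo:k_hi
}

#' Synthesize EEG/EMG signals for a ground-truth hypnogram
#'
#' Per epoch, the EEG is a sum of four band-limited Gaussian noise
#' components (one per analysis band) scaled by the epoch state's band
#' amplitudes, plus a low 1/f background; the EMG is 32-64 Hz band-limited
#' noise scaled by the state's EMG amplitude plus a broadband background.
#' Each epoch's segment is synthesized in the frequency domain (the band
#' components occupy disjoint bins, so one inverse FFT per epoch yields the
#' complete mixture) and consecutive segments are overlap-added with
#' complementary linear ramps spanning `crossfade` seconds, realizing the
#' amplitude cross-fade at state boundaries. An optional 12-bit uniform
#' quantizer emulates the acquisition ADC.
#'
#' @param truth A `psg_truth` from [sample_hypnogram()], or a bare
#'   [hypnogram()] tibble.
#' @param state_params Named list of [state_params()] (defaults to the
#'   truth's own parameters when available).
#' @param rng_seed Integer seed (defaults to the truth's seed + 1).
#' @param fs_eeg,fs_emg Sampling rates, Hz.
#' @param background Amplitude of the 1/f EEG background and of the broadband
#'   EMG background (arbitrary units; 0 disables it).
#' @param crossfade Cross-fade duration at epoch boundaries, seconds.
#' @param quantize If `TRUE`, apply a 12-bit uniform quantizer.
#' @param full_scale Full-scale range of the quantizer; defaults to 1.2 times
#'   the absolute signal maximum.
#' @return A `psg_recording` (see [psg_recording()]).
#' @export
#' @examples
#' d <- cohort_design(duration_h = 1, seed = 7)
#' truth <- sample_hypnogram(d)
#' rec <- synthesize_signals(truth)
#' rec
synthesize_signals <- function(truth, state_params = NULL, rng_seed = NULL,
                               fs_eeg = 125, fs_emg = 250,
                               background = 0.15, crossfade = 0.5,
                               quantize = FALSE, full_scale = NULL) {
  if (inherits(truth, "psg_truth")) {
    hyp <- truth$hypnogram
    if (is.null(state_params)) state_params <- truth$params$state_params
    if (is.null(rng_seed)) rng_seed <- truth$seed + 1L
  } else if (inherits(truth, "psg_hypnogram")) {
    hyp <- truth
    if (is.null(rng_seed)) rng_seed <- 1L
  } else {
    stop("truth must be a psg_truth or psg_hypnogram", call. = FALSE)
  }
  if (is.null(state_params)) state_params <- default_state_params()
  missing_states <- setdiff(levels(hyp$state), names(state_params))
  if (length(missing_states) > 0) {
    stop("state_params missing parameters for state(s): ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  }
  st <- as.character(hyp$state)
  ep_len <- hyp_epoch_len(hyp)
  bands <- psg_bands()
  state_idx <- match(st, psg_states())

  amp_eeg <- vapply(psg_states(), function(s) {
    if (s %in% names(state_params)) state_params[[s]]$band_amplitudes
    else rep(0, nrow(bands))
  }, numeric(nrow(bands)))
  amp_emg <- matrix(vapply(psg_states(), function(s) {
    if (s %in% names(state_params)) state_params[[s]]$emg_amplitude else 0
  }, numeric(1)), nrow = 1)
  # EMG: the 32-64 Hz component plus a flat broadband floor spanning the
  # acquisition band, one-fifth of the EEG background amplitude
  emg_band_tbl <- tibble::tibble(
    band = c("emg", "emg_floor"),
    lo = c(psg_emg_band()[1], 0.72), hi = c(psg_emg_band()[2], 112.88)
  )
  amp_emg <- rbind(amp_emg, rep(0.2 * background, ncol(amp_emg)))

  sig <- withr::with_seed(rng_seed, {
    eeg <- synth_epoch_channel(state_idx, ep_len, fs_eeg, bands, amp_eeg,
                               background, crossfade)
    emg <- synth_epoch_channel(state_idx, ep_len, fs_emg, emg_band_tbl,
                               amp_emg, 0, crossfade)
    list(eeg = eeg, emg = emg)
  })

  if (quantize) {
    sig$eeg <- quantize_12bit(sig$eeg, full_scale)
    sig$emg <- quantize_12bit(sig$emg, full_scale)
  }
  psg_recording(
    eeg = sig$eeg, emg = sig$emg, fs_eeg = fs_eeg, fs_emg = fs_emg,
    zt_start = attr(hyp, "zt_start") %||% 0,
    animal_id = attr(hyp, "animal_id"),
    handling = attr(hyp, "handling"), treatment = attr(hyp, "treatment")
  )
}

# Synthesize one channel epoch by epoch in the frequency domain. Each band
# contributes amp^2 of time-domain variance spread uniformly over its bins;
# the 1/f background adds in quadrature. Epochs of the same state share a
# spectral envelope, so two independent segments come out of each inverse
# FFT (real and imaginary parts of a circularly-symmetric spectrum), and
# segments are overlap-added with complementary linear ramps.
synth_epoch_channel <- function(state_idx, ep_len, fs, band_tbl, amp_mat,
                                bg_sd, crossfade) {
  spe <- as.integer(ep_len * fs)
  hf <- max(1L, as.integer(round(fs * crossfade / 2)))
  seg_n <- spe + 2L * hf
  kk <- 2:((seg_n + 1L) %/% 2L)
  f <- (kk - 1) * fs / seg_n
  sig2 <- matrix(0, length(kk), ncol(amp_mat))
  for (b in seq_len(nrow(band_tbl))) {
    sel <- which_band_bins(seg_n, fs, band_tbl$lo[b], band_tbl$hi[b]) - 1L
    m <- length(sel)
    if (m == 0) next
    sig2[sel, ] <- sig2[sel, ] +
      rep(amp_mat[b, ]^2 * seg_n^2 / (2 * m), each = m)
  }
  if (bg_sd > 0) {
    w <- pmax(f, fs / seg_n)^(-0.5)
    w <- w / sqrt(2 * sum(w^2) / seg_n^2)
    sig2 <- sig2 + (bg_sd * w)^2
  }
  n_ep <- length(state_idx)
  if (all(sig2 == 0)) return(numeric(n_ep * spe))
  seg <- matrix(0, seg_n, n_ep)
  for (s in sort(unique(state_idx))) {
    eps <- which(state_idx == s)
    n_s <- length(eps)
    n_pair <- (n_s + 1L) %/% 2L
    sfull <- numeric(seg_n)
    sfull[kk] <- sqrt(sig2[, s])
    sfull[seg_n + 2L - kk] <- sfull[kk]
    z <- matrix(complex(
      real = rnorm(seg_n * n_pair), imaginary = rnorm(seg_n * n_pair)
    ), seg_n, n_pair) * sfull
    x <- stats::mvfft(z, inverse = TRUE) / seg_n
    seg[, eps[seq_len(n_pair)]] <- Re(x)
    if (n_s > n_pair) {
      seg[, eps[(n_pair + 1L):n_s]] <- Im(x[, seq_len(n_s - n_pair)])
    }
  }
  overlap_add(seg, spe, hf)
}

# overlap-add epoch segments of length spe + 2*hf: linear up/down ramps of
# 2*hf samples are amplitude-complementary across adjacent segments
overlap_add <- function(seg, spe, hf) {
  seg_n <- nrow(seg)
  n_ep <- ncol(seg)
  ramp <- seq(0, 1, length.out = 2L * hf + 2L)[2:(2L * hf + 1L)]
  w <- c(ramp, rep(1, spe - 2L * hf), rev(ramp))
  seg <- seg * w
  x <- numeric(n_ep * spe + 2L * hf)
  for (e in seq_len(n_ep)) {
    i <- (e - 1L) * spe + seq_len(seg_n)
    x[i] <- x[i] + seg[, e]
  }
  x[(hf + 1L):(hf + n_ep * spe)]
}

# 12-bit midtread quantizer over [-full_scale, full_scale]
quantize_12bit <- function(x, full_scale = NULL) {
  if (all(x == 0)) return(x)
  if (is.null(full_scale)) full_scale <- 1.2 * max(abs(x))
  step <- full_scale / 2047
  pmin(pmax(round(x / step), -2048), 2047) * step
}

#' Generate a full synthetic cohort
#'
#' Simulates `n_per_group` animals for every (handling, treatment) cell of
#' the design, with per-animal seeds derived deterministically from the
#' design seed so that regenerating a design is byte-identical and growing
#' the cohort does not reshuffle existing animals.
#'
#' @param design A [cohort_design()].
#' @param signals If `TRUE` (default), synthesize the EEG/EMG signals for
#'   each animal; with long recordings and large cohorts this holds
#'   substantial data in memory, so pipeline code processes animals one at a
#'   time instead (see [run_pipeline()]).
#' @param dir Optional directory: when given, per-animal signals and
#'   ground-truth hypnograms are written as delimited text alongside a
#'   `manifest.csv`, and file paths are added to the returned manifest.
#' @param ... Passed to [synthesize_signals()].
#' @return A manifest tibble with one row per animal (`animal_id`,
#'   `handling`, `treatment`, `seed`) and list-columns `truth` (and
#'   `recording` when `signals = TRUE`).
#' @export
#' @examples
#' d <- cohort_design(n_per_group = 2, handling = "TH", treatment = "Veh",
#'                    duration_h = 0.5, seed = 3)
#' generate_cohort(d, signals = FALSE)
generate_cohort <- function(design, signals = TRUE, dir = NULL, ...) {
  stopifnot(inherits(design, "cohort_design"))
  grid <- expand.grid(
    animal = seq_len(design$n_per_group),
    treatment = design$treatment, handling = design$handling,
    stringsAsFactors = FALSE
  )
  rows <- purrr::pmap(grid, function(animal, treatment, handling) {
    truth <- sample_hypnogram(design, animal_index = animal,
                              handling = handling, treatment = treatment)
    rec <- if (signals) synthesize_signals(truth, ...) else NULL
    tibble::tibble(
      animal_id = attr(truth$hypnogram, "animal_id"),
      handling = handling, treatment = treatment,
      seed = truth$seed,
      truth = list(truth),
      recording = list(rec)
    )
  })
  manifest <- dplyr::bind_rows(rows)
  if (!signals) manifest$recording <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$hypnogram_file <- vapply(seq_len(nrow(manifest)), function(i) {
      f <- file.path(dir, paste0(manifest$animal_id[i], "_truth.csv"))
      write_hypnogram(manifest$truth[[i]]$hypnogram, f)
      f
    }, character(1))
    if (signals) {
      manifest$signal_file <- vapply(seq_len(nrow(manifest)), function(i) {
        f <- file.path(dir, paste0(manifest$animal_id[i], "_signals.csv"))
        write_recording(manifest$recording[[i]], f)
        f
      }, character(1))
    }
    readr::write_csv(
      manifest[, setdiff(names(manifest), c("truth", "recording"))],
      file.path(dir, "manifest.csv")
    )
  }
  manifest
}

#' Stationary state occupancy implied by a generator configuration
#'
#' Closed-form occupancy of the semi-Markov chain in a single phase: the
#' stationary distribution of the embedded transition chain weighted by the
#' expected dwell length in epochs (the expectation of the ceiling of the
#' log-normal dwell over the 8-s grid, computed by direct summation).
#' Brief-arousal insertions are ignored (their rate is small); use as the
#' analytic reference for long-run occupancy checks.
#'
#' @param design A [cohort_design()].
#' @param phase `"light"` or `"dark"`.
#' @return Named numeric vector of occupancy fractions over W/N/R.
#' @export
stationary_occupancy <- function(design, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  tr <- design$transitions
  p_r <- unname(tr$p_nrem_to_rem[phase])
  p_rw <- tr$p_rem_to_wake
  # embedded chain: rows W, N, R
  P <- rbind(
    W = c(W = 0, N = 1, R = 0),
    N = c(W = 1 - p_r, N = 0, R = p_r),
    R = c(W = p_rw, N = 1 - p_rw, R = 0)
  )
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  nu <- v / sum(v)
  dark <- phase == "dark"
  mean_epochs <- vapply(psg_states(), function(s) {
    p <- design$state_params[[s]]
    m <- p$dwell_mean * if (dark) p$dark_dwell_mult else 1
    expected_ceil_lnorm(m, p$dwell_shape, psg_epoch_len())
  }, numeric(1))
  occ <- nu * mean_epochs
  setNames(occ / sum(occ), psg_states())
}

# E[max(1, ceil(X / ep))] for X ~ lognormal with mean m, sdlog s
expected_ceil_lnorm <- function(m, s, ep_len) {
  mu <- log(m) - s^2 / 2
  kmax <- ceiling(exp(mu + 10 * s) / ep_len) + 1
  k <- seq_len(kmax)
  pk <- stats::plnorm(k * ep_len, mu, s) - stats::plnorm((k - 1) * ep_len, mu, s)
  sum(k * pk) + (1 - stats::plnorm(kmax * ep_len, mu, s)) * kmax
}
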