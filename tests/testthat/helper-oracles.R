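# Brute-force single-pass reference implementations of the architecture
# metrics, written independently of the package internals (plain loops over
# the state vector), plus small signal/fixture builders.

random_states <- function(n, prob = c(0.4, 0.45, 0.15)) {
  sample(c("W", "N", "R"), n, replace = TRUE, prob = prob)
}

# run-length decomposition by explicit scan
bf_episodes <- function(st) {
  out <- list()
  start <- 1
  for (i in seq_along(st)) {
    if (i == length(st) || st[i + 1] != st[i]) {
      out[[length(out) + 1]] <- list(state = st[i], start = start - 1,
                                     len = i - start + 1)
      start <- i + 1
    }
  }
  out
}

bf_totals <- function(st, ep_len = 8) {
  sapply(c("W", "N", "R"), function(s) sum(st == s) * ep_len)
}

bf_transitions <- function(st) {
  counts <- matrix(0, 3, 3, dimnames = list(c("W", "N", "R"), c("W", "N", "R")))
  eps <- bf_episodes(st)
  if (length(eps) > 1) {
    for (i in 2:length(eps)) {
      counts[eps[[i - 1]]$state, eps[[i]]$state] <-
        counts[eps[[i - 1]]$state, eps[[i]]$state] + 1
    }
  }
  counts
}

bf_interruptions <- function(st, cap_s = 64, ep_len = 8) {
  eps <- bf_episodes(st)
  n <- 0
  if (length(eps) >= 3) {
    for (i in 2:(length(eps) - 1)) {
      if (eps[[i]]$state == "W" && eps[[i]]$len * ep_len <= cap_s &&
          eps[[i - 1]]$state == "N" && eps[[i + 1]]$state == "N") {
        n <- n + 1
      }
    }
  }
  n
}

# printed definition: time to start of first NREM bout strictly > min_bout
bf_latency <- function(st, min_bout = 300, ep_len = 8) {
  eps <- bf_episodes(st)
  for (e in eps) {
    if (e$state == "N" && e$len * ep_len > min_bout) return(e$start * ep_len)
  }
  NA_real_
}

bf_bout_counts <- function(st, state, edge = 300, ep_len = 8) {
  eps <- bf_episodes(st)
  durs <- vapply(Filter(function(e) e$state == state, eps),
                 function(e) e$len * ep_len, numeric(1))
  c(le = sum(durs <= edge), gt = sum(durs > edge))
}

# direct-summation DFT band power of one Hann-tapered, demeaned window,
# scaled like the package periodogram (unit sinusoid -> ~0.5 in its bin)
bf_window_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  k_all <- 0:(n %/% 2)
  f <- k_all * fs / n
  pow <- vapply(k_all, function(k) {
    ph <- -2i * pi * k * (seq_len(n) - 1) / n
    Mod(sum(xw * exp(ph)))^2
  }, numeric(1))
  pow <- pow * 2 / sum(w)^2
  pow[1] <- pow[1] / 2
  if (n %% 2 == 0) pow[length(pow)] <- pow[length(pow)] / 2
  sum(pow[f >= lo & f < hi])
}

tone <- function(freq, dur_s, fs, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs))
}

# minimal band-power series for staging tests (epoch grid attributes set)
make_series <- function(emg, st, delta, sigma = NULL, theta = NULL) {
  n <- length(emg)
  if (is.null(sigma)) sigma <- sqrt(st)
  if (is.null(theta)) theta <- st / sigma
  structure(
    tibble::tibble(
      epoch_index = seq_len(n) - 1L, zt_seconds = (seq_len(n) - 1L) * 8,
      delta = delta, theta = theta, sigma = sigma, beta = delta * 0 + 1,
      sigma_theta = sigma * theta, emg_power = emg
    ),
    class = c("psg_bands_series", class(tibble::tibble())),
    epoch_len = 8, zt_start = 0
  )
}

# small single-cell design for fast simulations
quick_design <- function(duration_h = 1, seed = 1, ...) {
  cohort_design(n_per_group = 1, handling = "TH", treatment = "Veh",
                duration_h = duration_h, seed = seed, ...)
}
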