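#' Zero-phase band-pass filtering
#'
#' Applies the acquisition-style analog band-pass digitally and with zero
#' phase: the squared magnitude response of an order-2 Butterworth high-pass
#' at `lo` cascaded with an order-9 Butterworth low-pass at `hi` (the
#' forward-backward application of that cascade) is applied in the frequency
#' domain. The response keeps mid-band sinusoids within 5% of unit gain and
#' attenuates tones one octave outside either edge by more than 20 dB, and —
#' unlike a direct-form recursion — is numerically exact for very low edges
#' such as 0.16 Hz at a 125 Hz sampling rate. Defaults for the two channels
#' are 0.16-53.05 Hz (EEG) and 0.72-112.88 Hz (EMG).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param lo,hi Band edges, Hz, `0 < lo < hi`. A `hi` at or above the Nyquist
#'   frequency is clipped just below it with a warning.
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 4 - 1 / 125, by = 1 / 125)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass(x, 125, 0.16, 53.05)
bandpass <- function(x, fs, lo, hi) {
  if (!(lo > 0 && lo < hi)) {
    stop("band edges must satisfy 0 < lo < hi", call. = FALSE)
  }
  nyq <- fs / 2
  if (hi >= nyq) {
    warning(sprintf(
      "upper edge %.4g Hz is at or above Nyquist (%.4g Hz); clipping", hi, nyq
    ), call. = FALSE)
    hi <- 0.99 * nyq
  }
  n <- length(x)
  if (n == 0 || all(x == 0)) return(x)
  n_half <- n %/% 2 + 1
  f <- (seq_len(n_half) - 1) * fs / n
  g <- bp_gain(f, lo, hi)
  gain <- g[c(seq_len(n_half), if (n > 2) ((n - n_half + 1):2))]
  Re(fft(fft(x) * gain, inverse = TRUE)) / n
}

# zero-phase amplitude response: squared magnitude of an order-2 Butterworth
# high-pass at lo cascaded with an order-9 Butterworth low-pass at hi
bp_gain <- function(f, lo, hi) {
  f <- pmax(f, .Machine$double.eps)
  g <- 1 / ((1 + (lo / f)^4) * (1 + (f / hi)^18))
  g[f <= .Machine$double.eps] <- 0
  g
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# One-sided windowed periodogram powers for a set of equal-length windows.
# x: signal; starts: 0-based start samples; win_n: window length.
# Returns list(power): power is (n_freq x n_windows), scaled so a
# unit-amplitude sinusoid carries ~0.5 (its mean square) in its bin.
# Windows are transformed two at a time (real pair packed into one complex
# FFT and unpacked by Hermitian symmetry).
windowed_periodograms <- function(x, starts, win_n) {
  idx <- outer(seq_len(win_n), starts, `+`)
  m <- matrix(x[idx], nrow = win_n)
  m <- sweep(m, 2, colMeans(m)) # per-window detrend keeps DC out of delta
  w <- hann_window(win_n)
  m <- m * w
  s1 <- sum(w)
  n_win <- ncol(m)
  n_pair <- (n_win + 1L) %/% 2L
  if (2L * n_pair > n_win) m <- cbind(m, 0)
  z <- m[, seq_len(n_pair), drop = FALSE] +
    1i * m[, n_pair + seq_len(n_pair), drop = FALSE]
  ft <- stats::mvfft(z)
  n_freq <- win_n %/% 2 + 1
  mirror <- c(1L, win_n:2L)[seq_len(n_freq)]
  zk <- ft[seq_len(n_freq), , drop = FALSE]
  zm <- Conj(ft[mirror, , drop = FALSE])
  p1 <- Mod(zk + zm)^2 / 4
  p2 <- Mod(zk - zm)^2 / 4
  p <- cbind(p1, p2)[, seq_len(n_win), drop = FALSE] * (2 / s1^2)
  p[1, ] <- p[1, ] / 2
  if (win_n %% 2 == 0) p[n_freq, ] <- p[n_freq, ] / 2
  list(power = p)
}

# integrate periodogram rows over [lo, hi) bands
integrate_bands <- function(power, freq, bands) {
  out <- lapply(seq_len(nrow(bands)), function(b) {
    sel <- freq >= bands$lo[b] & freq < bands$hi[b]
    colSums(power[sel, , drop = FALSE])
  })
  names(out) <- bands$band
  out
}

#' Per-epoch EEG band powers
#'
#' Fourier analysis on 16-s windows with 50% overlap (hop 8 s): each 8-s
#' epoch's estimate comes from the 16-s Hann-tapered window centred on it
#' (the first and last epochs use the nearest fully contained window). At
#' 125 Hz a window holds 2000 samples giving 0.0625 Hz resolution; powers
#' are integrated over each analysis band with half-open bin membership
#' (`lo <= f < hi`).
#'
#' @param eeg Numeric EEG signal.
#' @param fs Sampling rate, Hz (default 125).
#' @param epoch_len Epoch length, seconds (default 8).
#' @param window_len Analysis window, seconds (default 16).
#' @param bands Band definition tibble, see [psg_bands()].
#' @param filter Optional length-2 band-pass edges (Hz): the zero-phase
#'   Butterworth response of [bandpass()] is applied to each window's power
#'   spectrum before integration (spectrally equivalent to filtering the
#'   signal first, without the full-length transforms).
#' @return Tibble with one row per epoch: `epoch_index` and one power column
#'   per band.
#' @export
#' @examples
#' t <- seq(0, 80 - 1 / 125, by = 1 / 125)
#' p <- eeg_band_powers(sin(2 * pi * 2 * t))
#' colMeans(p[-1])
eeg_band_powers <- function(eeg, fs = 125, epoch_len = psg_epoch_len(),
                            window_len = 16, bands = psg_bands(),
                            filter = NULL) {
  win_n <- round(window_len * fs)
  if (length(eeg) < win_n) {
    stop("signal shorter than one analysis window (", window_len, " s)",
         call. = FALSE)
  }
  n_ep <- floor(length(eeg) / (epoch_len * fs))
  total_n <- length(eeg)
  # window centred on epoch i starts at epoch_len*i - (window_len-epoch_len)/2
  centre_off <- (window_len - epoch_len) / 2 * fs
  starts <- round((seq_len(n_ep) - 1) * epoch_len * fs - centre_off)
  starts <- pmin(pmax(starts, 0), total_n - win_n)
  pg <- windowed_periodograms(eeg, starts, win_n)
  freq <- (seq_len(win_n %/% 2 + 1) - 1) * fs / win_n
  p <- pg$power
  if (!is.null(filter)) p <- p * bp_gain(freq, filter[1], filter[2])^2
  bp <- integrate_bands(p, freq, bands)
  tibble::tibble(epoch_index = seq_len(n_ep) - 1L, !!!bp)
}

#' Per-epoch EMG power (32-64 Hz)
#'
#' Fourier analysis on 2-s windows; the 32-64 Hz power of the four
#' non-overlapping windows inside each 8-s epoch is averaged to one value
#' per epoch.
#'
#' @param emg Numeric EMG signal.
#' @param fs Sampling rate, Hz (default 250).
#' @param epoch_len Epoch length, seconds (default 8).
#' @param window_len Analysis window, seconds (default 2).
#' @param band Length-2 integration band in Hz, see [psg_emg_band()].
#' @param filter Optional length-2 band-pass edges (Hz), applied to the
#'   window spectra as in [eeg_band_powers()].
#' @return Tibble with `epoch_index` and `emg_power`.
#' @export
emg_band_power <- function(emg, fs = 250, epoch_len = psg_epoch_len(),
                           window_len = 2, band = psg_emg_band(),
                           filter = NULL) {
  win_n <- round(window_len * fs)
  if (length(emg) < epoch_len * fs) {
    stop("signal shorter than one epoch (", epoch_len, " s)", call. = FALSE)
  }
  n_ep <- floor(length(emg) / (epoch_len * fs))
  per_ep <- as.integer(epoch_len / window_len)
  starts <- (seq_len(n_ep * per_ep) - 1) * win_n
  pg <- windowed_periodograms(emg, starts, win_n)
  freq <- (seq_len(win_n %/% 2 + 1) - 1) * fs / win_n
  p <- pg$power
  if (!is.null(filter)) p <- p * bp_gain(freq, filter[1], filter[2])^2
  sel <- freq >= band[1] & freq < band[2]
  win_pow <- colSums(p[sel, , drop = FALSE])
  tibble::tibble(
    epoch_index = seq_len(n_ep) - 1L,
    emg_power = colMeans(matrix(win_pow, nrow = per_ep))
  )
}

#' Build the aligned per-epoch band-power table of a recording
#'
#' Band-pass filters both channels (EEG 0.16-53.05 Hz, EMG 0.72-112.88 Hz by
#' default), computes per-epoch EEG band powers and EMG power, and assembles
#' the aligned table including the sigma*theta product used by the staging
#' rules. A trailing partial epoch is discarded with a message. By default
#' the channel filters are applied as the zero-phase Butterworth response on
#' the window spectra (`filter_domain = "stft"`); `"time"` filters the raw
#' signals with [bandpass()] first (same response, full-length transforms),
#' and `"none"` skips filtering.
#'
#' @param recording A [psg_recording()].
#' @param eeg_filter,emg_filter Length-2 band edges (Hz) of the channel
#'   filters; `NULL` skips filtering.
#' @param epoch_len Epoch length, seconds.
#' @param bands EEG band definitions ([psg_bands()]).
#' @param emg_band EMG integration band ([psg_emg_band()]).
#' @param filter_domain `"stft"`, `"time"` or `"none"`.
#' @return A `psg_bands_series` tibble: `epoch_index`, `zt_seconds`, `delta`,
#'   `theta`, `sigma`, `beta`, `sigma_theta`, `emg_power`.
#' @export
#' @examples
#' d <- cohort_design(duration_h = 0.5, seed = 11)
#' rec <- synthesize_signals(sample_hypnogram(d))
#' head(band_power_series(rec))
band_power_series <- function(recording,
                              eeg_filter = c(0.16, 53.05),
                              emg_filter = c(0.72, 112.88),
                              epoch_len = psg_epoch_len(),
                              bands = psg_bands(),
                              emg_band = psg_emg_band(),
                              filter_domain = c("stft", "time", "none")) {
  stopifnot(inherits(recording, "psg_recording"))
  eeg <- recording$eeg
  emg <- recording$emg
  spe <- epoch_len * recording$fs_eeg
  n_ep <- floor(length(eeg) / spe)
  dropped <- length(eeg) - n_ep * spe
  if (dropped > 0) {
    message("discarding trailing partial epoch (", dropped, " EEG samples)")
    eeg <- eeg[seq_len(n_ep * spe)]
  }
  emg <- emg[seq_len(min(length(emg), n_ep * epoch_len * recording$fs_emg))]
  filter_domain <- match.arg(filter_domain)
  if (filter_domain == "none") {
    eeg_filter <- NULL
    emg_filter <- NULL
  }
  if (filter_domain == "time") {
    if (!is.null(eeg_filter)) {
      eeg <- bandpass(eeg, recording$fs_eeg, eeg_filter[1], eeg_filter[2])
    }
    if (!is.null(emg_filter)) {
      emg <- bandpass(emg, recording$fs_emg, emg_filter[1], emg_filter[2])
    }
    eeg_filter <- NULL
    emg_filter <- NULL
  }
  ep <- eeg_band_powers(eeg, recording$fs_eeg, epoch_len, bands = bands,
                        filter = eeg_filter)
  em <- emg_band_power(emg, recording$fs_emg, epoch_len, band = emg_band,
                       filter = emg_filter)
  n <- min(nrow(ep), nrow(em))
  out <- dplyr::bind_cols(
    ep[seq_len(n), ],
    em[seq_len(n), "emg_power"]
  )
  out$sigma_theta <- out$sigma * out$theta
  out$zt_seconds <- recording$zt_start + out$epoch_index * epoch_len
  out <- out[, c("epoch_index", "zt_seconds", "delta", "theta", "sigma",
                 "beta", "sigma_theta", "emg_power")]
  structure(out,
    class = c("psg_bands_series", class(out)),
    epoch_len = epoch_len, zt_start = recording$zt_start,
    animal_id = recording$animal_id, handling = recording$handling,
    treatment = recording$treatment
  )
}
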