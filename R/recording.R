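#' Construct a polysomnographic recording
#'
#' Container for one animal's raw signals: EEG sampled at `fs_eeg` (125 Hz by
#' default) and EMG at `fs_emg` (250 Hz), with the Zeitgeber-time offset of
#' the first sample and the animal's group labels. EEG and EMG must cover the
#' same duration to within one epoch.
#'
#' @param eeg,emg Numeric sample vectors.
#' @param fs_eeg,fs_emg Sampling rates in Hz (strictly positive).
#' @param zt_start Start time in seconds from ZT 0 (lights on).
#' @param animal_id,handling,treatment Optional labels.
#' @return A `psg_recording` object.
#' @export
psg_recording <- function(eeg, emg, fs_eeg = 125, fs_emg = 250, zt_start = 0,
                          animal_id = NA_character_, handling = NA_character_,
                          treatment = NA_character_) {
  stopifnot(fs_eeg > 0, fs_emg > 0)
  dur_eeg <- length(eeg) / fs_eeg
  dur_emg <- length(emg) / fs_emg
  if (abs(dur_eeg - dur_emg) > psg_epoch_len()) {
    stop(sprintf(
      "EEG (%.1f s) and EMG (%.1f s) durations differ by more than one epoch",
      dur_eeg, dur_emg
    ), call. = FALSE)
  }
  structure(
    list(
      eeg = as.numeric(eeg), emg = as.numeric(emg),
      fs_eeg = fs_eeg, fs_emg = fs_emg, zt_start = zt_start,
      animal_id = animal_id, handling = handling, treatment = treatment
    ),
    class = "psg_recording"
  )
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf(
    "<psg_recording> %s  EEG: %d samples @ %g Hz  EMG: %d samples @ %g Hz  (%.2f h, ZT start %gs)\n",
    x$animal_id %||% "?", length(x$eeg), x$fs_eeg, length(x$emg), x$fs_emg,
    length(x$eeg) / x$fs_eeg / 3600, x$zt_start
  ))
  invisible(x)
}

#' Duration of a recording in seconds (EEG channel).
#' @param x A `psg_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(x) length(x$eeg) / x$fs_eeg
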