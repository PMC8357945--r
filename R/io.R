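#' Read and write pipeline artifacts as delimited text
#'
#' All intermediates are plain text so runs are diffable: hypnograms as
#' `epoch_index, zt_seconds, state`; band-power series as
#' `epoch_index, zt_seconds, delta, theta, sigma, beta, sigma_theta,
#' emg_power`; recordings in long form `channel, time, value` (EEG and EMG
#' have different sampling rates, so a long layout keeps a single file
#' unambiguous); threshold models as YAML.
#'
#' @param hyp,series,rec,model Objects to write.
#' @param path File path.
#' @name psg_io
NULL

#' @rdname psg_io
#' @export
write_hypnogram <- function(hyp, path) {
  readr::write_csv(
    tibble::tibble(
      epoch_index = hyp$epoch_index, zt_seconds = hyp$zt_seconds,
      state = as.character(hyp$state)
    ),
    path
  )
  invisible(path)
}

#' @rdname psg_io
#' @param animal_id,handling,treatment Optional labels restored on read.
#' @export
read_hypnogram <- function(path, animal_id = NA_character_,
                           handling = NA_character_,
                           treatment = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ep_len <- if (nrow(df) > 1) diff(df$zt_seconds[1:2]) else psg_epoch_len()
  hypnogram(df$state, zt_start = df$zt_seconds[1], epoch_len = ep_len,
            animal_id = animal_id, handling = handling, treatment = treatment)
}

#' @rdname psg_io
#' @export
write_band_series <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path)
  invisible(path)
}

#' @rdname psg_io
#' @export
read_band_series <- function(path, animal_id = NA_character_,
                             handling = NA_character_,
                             treatment = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ep_len <- if (nrow(df) > 1) diff(df$zt_seconds[1:2]) else psg_epoch_len()
  structure(tibble::as_tibble(df),
    class = c("psg_bands_series", class(tibble::tibble())),
    epoch_len = ep_len, zt_start = df$zt_seconds[1],
    animal_id = animal_id, handling = handling, treatment = treatment
  )
}

#' @rdname psg_io
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "psg_recording"))
  df <- dplyr::bind_rows(
    tibble::tibble(
      channel = "eeg",
      time = rec$zt_start + (seq_along(rec$eeg) - 1) / rec$fs_eeg,
      value = rec$eeg
    ),
    tibble::tibble(
      channel = "emg",
      time = rec$zt_start + (seq_along(rec$emg) - 1) / rec$fs_emg,
      value = rec$emg
    )
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname psg_io
#' @export
read_recording <- function(path, animal_id = NA_character_,
                           handling = NA_character_,
                           treatment = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  eeg <- df[df$channel == "eeg", ]
  emg <- df[df$channel == "emg", ]
  fs_eeg <- 1 / diff(eeg$time[1:2])
  fs_emg <- 1 / diff(emg$time[1:2])
  psg_recording(eeg$value, emg$value, round(fs_eeg), round(fs_emg),
                zt_start = eeg$time[1], animal_id = animal_id,
                handling = handling, treatment = treatment)
}

#' @rdname psg_io
#' @export
write_thresholds <- function(model, path) {
  stopifnot(inherits(model, "psg_thresholds"))
  yaml::write_yaml(list(
    emg_cut = model$emg_cut, st_cut = model$st_cut,
    delta_cut = model$delta_cut,
    fit_method = as.list(model$fit_method),
    n_epochs = model$n_epochs, epoch_len = model$epoch_len,
    diagnostics = lapply(seq_len(nrow(model$diagnostics)), function(i) {
      as.list(model$diagnostics[i, ])
    })
  ), path)
  invisible(path)
}

#' @rdname psg_io
#' @export
read_thresholds <- function(path) {
  y <- yaml::read_yaml(path)
  structure(
    list(
      emg_cut = y$emg_cut, st_cut = y$st_cut, delta_cut = y$delta_cut,
      fit_method = unlist(y$fit_method),
      diagnostics = dplyr::bind_rows(lapply(y$diagnostics, tibble::as_tibble)),
      n_epochs = y$n_epochs, epoch_len = y$epoch_len
    ),
    class = "psg_thresholds"
  )
}

#' Tidy a threshold model
#' @param x A `psg_thresholds`.
#' @param ... Unused.
#' @return The diagnostics tibble with the fitted cut per channel.
#' @method tidy psg_thresholds
#' @export
tidy.psg_thresholds <- function(x, ...) {
  cuts <- c(emg_power = x$emg_cut, sigma_theta = x$st_cut, delta = x$delta_cut)
  d <- x$diagnostics
  d$cut <- unname(cuts[d$channel])
  d$fit_method <- unname(x$fit_method[d$channel])
  tibble::as_tibble(d)
}

#' Glance at a threshold model
#' @param x A `psg_thresholds`.
#' @param ... Unused.
#' @return One-row tibble of the three cuts.
#' @method glance psg_thresholds
#' @export
glance.psg_thresholds <- function(x, ...) {
  tibble::tibble(emg_cut = x$emg_cut, st_cut = x$st_cut,
                 delta_cut = x$delta_cut, n_epochs = x$n_epochs %||% NA_integer_)
}
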