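#' Fit per-recording staging thresholds
#'
#' The scoring rules compare each epoch's EMG power, sigma*theta product and
#' delta power against "high"/"low" cuts that are fitted per animal. Each cut
#' is obtained by splitting the log10 power distribution into two Gaussian
#' components (model-based EM via \pkg{mclust}, run under a fixed seed) and
#' placing the threshold at the equal-posterior point between the component
#' means; when the mixture fit fails or the components are not separated,
#' the fallback is the midpoint between the 25th and 75th log-power
#' percentiles. The delta cut is fitted only on putative sleep epochs
#' (EMG below the EMG cut), because the NREM/REM delta contrast is defined
#' within sleep.
#'
#' @param series A `psg_bands_series` from [band_power_series()].
#' @param min_epochs Below this epoch count a warning is issued (default 50).
#' @return A `psg_thresholds` object: `emg_cut`, `st_cut`, `delta_cut` (on
#'   the power scale), `fit_method` per channel, and a `diagnostics` tibble
#'   (component means, sds, mixing proportions and a standardized separation
#'   statistic per discriminant).
#' @export
#' @examples
#' d <- cohort_design(duration_h = 1, seed = 5)
#' rec <- synthesize_signals(sample_hypnogram(d))
#' fit_thresholds(band_power_series(rec))
fit_thresholds <- function(series, min_epochs = 50) {
  check_series(series)
  if (nrow(series) < min_epochs) {
    warning("threshold fit on only ", nrow(series),
            " epochs; cuts may be unstable", call. = FALSE)
  }
  emg <- log_channel(series$emg_power, "emg_power")
  st <- log_channel(series$sigma_theta, "sigma_theta")
  f_emg <- split_two_components(emg)
  f_st <- split_two_components(st)
  sleep <- series$emg_power <= 10^f_emg$cut
  if (sum(sleep) < 2) {
    stop("no sleep epochs below the fitted EMG cut; cannot fit delta_cut",
         call. = FALSE)
  }
  delta <- log_channel(series$delta[sleep], "delta")
  f_delta <- split_two_components(delta)
  diagnostics <- dplyr::bind_rows(
    tibble::tibble(channel = "emg_power", !!!f_emg$diag),
    tibble::tibble(channel = "sigma_theta", !!!f_st$diag),
    tibble::tibble(channel = "delta", !!!f_delta$diag)
  )
  structure(
    list(
      emg_cut = 10^f_emg$cut, st_cut = 10^f_st$cut, delta_cut = 10^f_delta$cut,
      fit_method = c(emg_power = f_emg$method, sigma_theta = f_st$method,
                     delta = f_delta$method),
      diagnostics = diagnostics,
      n_epochs = nrow(series), epoch_len = attr(series, "epoch_len")
    ),
    class = "psg_thresholds"
  )
}

log_channel <- function(x, name) {
  if (any(!is.finite(x))) {
    stop("non-finite powers in channel ", name, call. = FALSE)
  }
  lx <- log10(pmax(x, .Machine$double.xmin))
  if (sd(lx) < 1e-10) {
    stop("channel ", name, " is constant; cannot fit a threshold",
         call. = FALSE)
  }
  lx
}

# two-component 1-D Gaussian split on log powers; returns cut on log scale
split_two_components <- function(lx) {
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the calling frame
  fit <- withr::with_seed(20220816, try(suppressWarnings(
    mclust::Mclust(lx, G = 2, modelNames = c("V", "E"), verbose = FALSE)
  ), silent = TRUE))
  fallback <- function() {
    q <- quantile(lx, c(0.25, 0.75), names = FALSE)
    list(
      cut = mean(q), method = "quartile_midpoint",
      diag = list(mean_lo = q[1], mean_hi = q[2], sd_lo = NA_real_,
                  sd_hi = NA_real_, prop_lo = NA_real_, separation = NA_real_)
    )
  }
  if (inherits(fit, "try-error") || is.null(fit)) return(fallback())
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(rep_len(as.numeric(fit$parameters$variance$sigmasq), 2))
  pro <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]; pro <- pro[o]
  sep <- abs(diff(mu)) / sqrt(mean(sig^2))
  if (!is.finite(sep) || sep < 0.5 || diff(mu) < 1e-8) return(fallback())
  # equal weighted posterior between the two means
  h <- function(x) {
    dnorm(x, mu[1], sig[1], log = TRUE) + log(pro[1]) -
      dnorm(x, mu[2], sig[2], log = TRUE) - log(pro[2])
  }
  cut <- if (h(mu[1]) > 0 && h(mu[2]) < 0) {
    uniroot(h, c(mu[1], mu[2]))$root
  } else {
    mean(mu)
  }
  list(
    cut = cut, method = "gaussian_mixture",
    diag = list(mean_lo = mu[1], mean_hi = mu[2], sd_lo = sig[1],
                sd_hi = sig[2], prop_lo = pro[1], separation = sep)
  )
}

#' @export
print.psg_thresholds <- function(x, ...) {
  cat("<psg_thresholds>\n")
  cat(sprintf("  emg_cut:   %.4g  (%s)\n", x$emg_cut, x$fit_method[["emg_power"]]))
  cat(sprintf("  st_cut:    %.4g  (%s)\n", x$st_cut, x$fit_method[["sigma_theta"]]))
  cat(sprintf("  delta_cut: %.4g  (%s)\n", x$delta_cut, x$fit_method[["delta"]]))
  invisible(x)
}

#' Classify epochs into wake / NREM / REM
#'
#' Applies the printed scoring rules with fixed precedence: an epoch is WAKE
#' when its EMG power exceeds the EMG cut (high EMG); otherwise, a low-EMG
#' epoch whose sigma*theta product is at or below the sigma*theta cut fits
#' neither sleep description and is scored WAKE ("quiet wake", counted in
#' the attributes); remaining sleep epochs are NREM when delta power exceeds
#' the delta cut (high delta) and REM otherwise.
#'
#' @param series A `psg_bands_series`.
#' @param model A `psg_thresholds` fitted on the same or a comparable
#'   recording.
#' @return A [hypnogram()] tibble with attribute `n_quiet_wake`.
#' @export
classify_epochs <- function(series, model) {
  check_series(series)
  stopifnot(inherits(model, "psg_thresholds"))
  if (!is.null(model$epoch_len) &&
      !isTRUE(all.equal(model$epoch_len, attr(series, "epoch_len")))) {
    stop("threshold model and series use different epoch grids", call. = FALSE)
  }
  wake_hi <- series$emg_power > model$emg_cut
  quiet <- !wake_hi & series$sigma_theta <= model$st_cut
  state <- ifelse(wake_hi | quiet, "W",
                  ifelse(series$delta > model$delta_cut, "N", "R"))
  hyp <- hypnogram(state,
    zt_start = attr(series, "zt_start") %||% series$zt_seconds[1],
    epoch_len = attr(series, "epoch_len") %||% psg_epoch_len(),
    animal_id = attr(series, "animal_id"),
    handling = attr(series, "handling"), treatment = attr(series, "treatment")
  )
  attr(hyp, "n_quiet_wake") <- sum(quiet)
  hyp
}

check_series <- function(series) {
  need <- c("delta", "theta", "sigma", "beta", "sigma_theta", "emg_power")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    stop("band-power series is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(series)
}

#' Majority smoothing of a hypnogram
#'
#' Optional post-hoc cleanup standing in for manual rescoring: runs shorter
#' than `min_run` epochs are re-assigned to the flanking state when both
#' flanking runs agree; `min_run = 1` is the identity. The default pipeline
#' applies no smoothing.
#'
#' @param hyp A [hypnogram()].
#' @param min_run Minimum run length, epochs (`>= 1`).
#' @return A smoothed [hypnogram()].
#' @export
#' @examples
#' h <- hypnogram(c("W", "W", "N", "W", "W"))
#' as.character(smooth_hypnogram(h, min_run = 2)$state)
smooth_hypnogram <- function(hyp, min_run = 1) {
  stopifnot(inherits(hyp, "psg_hypnogram"), min_run >= 1)
  st <- as.character(hyp$state)
  repeat {
    r <- rle(st)
    k <- length(r$lengths)
    short <- which(r$lengths < min_run)
    short <- short[short > 1 & short < k]
    short <- short[r$values[short - 1] == r$values[short + 1]]
    if (length(short) == 0) break
    r$values[short] <- r$values[short - 1]
    st <- inverse.rle(r)
  }
  out <- hyp
  out$state <- as_state_factor(st)
  out
}
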