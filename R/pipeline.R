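#' Pipeline run configuration
#'
#' Bundles every tunable of a full simulate-score-summarize-test run. The
#' defaults are the acquisition and analysis parameters of the cage-change
#' experiment: 125/250 Hz sampling, 16-s EEG FFT windows with 50% overlap,
#' 2-s EMG windows, 8-s epochs, the printed band edges, a 300-s latency
#' threshold, and the ZT 0-8 / ZT 12-24 reporting windows (clipped to the
#' simulated duration).
#'
#' @param design A [cohort_design()].
#' @param windows Named list of reporting ZT windows (seconds).
#' @param latency_min_bout,interruption_max,bout_edges See
#'   [summarize_architecture()].
#' @param eeg_filter,emg_filter Channel band-pass edges, Hz.
#' @param background,quantize Signal-synthesis options
#'   ([synthesize_signals()]).
#' @param smooth_min_run Hypnogram smoothing run length (1 = no smoothing,
#'   the default).
#' @return A `psg_run_config` list.
#' @export
run_config <- function(design = cohort_design(),
                       windows = NULL,
                       latency_min_bout = 300, interruption_max = 64,
                       bout_edges = 300,
                       eeg_filter = c(0.16, 53.05),
                       emg_filter = c(0.72, 112.88),
                       background = 0.15, quantize = FALSE,
                       smooth_min_run = 1) {
  if (is.null(windows)) {
    dur_s <- design$duration_h * 3600
    windows <- list()
    if (dur_s > 0) windows$light <- c(0, min(8 * 3600, dur_s))
    if (dur_s > 12 * 3600) windows$dark <- c(12 * 3600, min(24 * 3600, dur_s))
  }
  structure(
    list(
      design = design, windows = windows,
      latency_min_bout = latency_min_bout,
      interruption_max = interruption_max, bout_edges = bout_edges,
      eeg_filter = eeg_filter, emg_filter = emg_filter,
      background = background, quantize = quantize,
      smooth_min_run = smooth_min_run
    ),
    class = "psg_run_config"
  )
}

#' Simulate, score and summarize one animal
#'
#' The per-animal unit of the pipeline: draw the ground-truth hypnogram,
#' synthesize signals, compute band powers, fit thresholds, classify epochs,
#' and summarize architecture from the scored hypnogram. Signals are
#' discarded after scoring so cohorts of any size stream in constant memory.
#'
#' @param config A [run_config()].
#' @param handling,treatment Design cell.
#' @param animal_index Animal index within the cell.
#' @return List with `truth` (ground-truth hypnogram), `scored` (scored
#'   hypnogram), `series`, `thresholds`, `summary` (a `psg_architecture`).
#' @export
score_animal <- function(config, handling, treatment, animal_index) {
  truth <- sample_hypnogram(config$design, animal_index = animal_index,
                            handling = handling, treatment = treatment)
  rec <- synthesize_signals(truth, background = config$background,
                            quantize = config$quantize)
  series <- band_power_series(rec, eeg_filter = config$eeg_filter,
                              emg_filter = config$emg_filter)
  thresholds <- fit_thresholds(series)
  scored <- classify_epochs(series, thresholds)
  if (config$smooth_min_run > 1) {
    scored <- smooth_hypnogram(scored, config$smooth_min_run)
  }
  summary <- summarize_architecture(
    scored, series, windows = config$windows,
    latency_min_bout = config$latency_min_bout,
    interruption_max = config$interruption_max,
    bout_edges = config$bout_edges
  )
  list(truth = truth$hypnogram, scored = scored, series = series,
       thresholds = thresholds, summary = summary)
}

#' Confusion matrix between two hypnograms on the same grid
#'
#' @param truth,scored Hypnograms of equal length.
#' @return 3x3 table (rows: truth, columns: scored).
#' @export
staging_confusion <- function(truth, scored) {
  stopifnot(nrow(truth) == nrow(scored))
  table(truth = truth$state, scored = scored$state)
}

#' Epoch agreement and per-state recall from a confusion matrix
#' @param cm Confusion table from [staging_confusion()].
#' @return One-row tibble: `agreement`, `recall_W`, `recall_N`, `recall_R`.
#' @export
staging_agreement <- function(cm) {
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  tibble::tibble(
    agreement = sum(diag(cm)) / sum(cm),
    recall_W = rec[["W"]], recall_N = rec[["N"]], recall_R = rec[["R"]]
  )
}

#' Run the full pipeline
#'
#' Orchestrates simulate, spectra, stage, metrics and stats over the whole
#' cohort, one animal at a time, deterministically under the design seed.
#' When `out_dir` is given, every intermediate is written as delimited text
#' (per-animal ground-truth and scored hypnograms, band-power series,
#' threshold YAML, manifest, cohort metric table, statistics tables, the
#' staging confusion matrix and the config itself).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param stats_metrics Metrics to test in the statistics layer (default:
#'   the totals, episode counts, transition rates, interruptions and
#'   latency).
#' @param progress Print per-animal progress lines.
#' @return A `psg_run` list: `manifest`, `metrics` (long cohort table),
#'   `stats`, `confusion` (pooled staging confusion matrix), `agreement`,
#'   `config`.
#' @export
#' @examples
#' cfg <- run_config(cohort_design(n_per_group = 2, handling = "TH",
#'                                 treatment = "Veh", duration_h = 0.5,
#'                                 seed = 21))
#' run <- run_pipeline(cfg)
#' run$agreement
run_pipeline <- function(config, out_dir = NULL, stats_metrics = NULL,
                         progress = FALSE) {
  stopifnot(inherits(config, "psg_run_config"))
  design <- config$design
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config_as_list(config), file.path(out_dir, "config.yaml"))
  }
  grid <- expand.grid(
    animal = seq_len(design$n_per_group),
    treatment = design$treatment, handling = design$handling,
    stringsAsFactors = FALSE
  )
  cm_total <- NULL
  metrics <- list()
  manifest <- list()
  for (i in seq_len(nrow(grid))) {
    h <- grid$handling[i]; tr <- grid$treatment[i]; a <- grid$animal[i]
    res <- tryCatch(
      score_animal(config, h, tr, a),
      error = function(e) {
        stop(sprintf("pipeline failed at animal %s-%s-%02d: %s",
                     h, tr, a, conditionMessage(e)), call. = FALSE)
      }
    )
    id <- attr(res$truth, "animal_id")
    if (progress) message(sprintf("scored %s", id))
    cm <- staging_confusion(res$truth, res$scored)
    cm_total <- if (is.null(cm_total)) cm else cm_total + cm
    metrics[[i]] <- tidy(res$summary)
    manifest[[i]] <- tibble::tibble(
      animal_id = id, handling = h, treatment = tr,
      seed = derive_seed(design$seed, h, tr, a),
      agreement = staging_agreement(cm)$agreement
    )
    if (!is.null(out_dir)) {
      write_hypnogram(res$truth, file.path(out_dir, paste0(id, "_truth.csv")))
      write_hypnogram(res$scored, file.path(out_dir, paste0(id, "_scored.csv")))
      write_band_series(res$series, file.path(out_dir, paste0(id, "_bands.csv")))
      write_thresholds(res$thresholds,
                       file.path(out_dir, paste0(id, "_thresholds.yaml")))
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  metrics <- dplyr::bind_rows(metrics)
  if (is.null(stats_metrics)) {
    stats_metrics <- c(
      paste0("total_", psg_states()), paste0("episodes_", psg_states()),
      "trans_W_N_per_h", "trans_N_W_per_h", "trans_N_R_per_h",
      "trans_R_W_per_h", "nrem_interruptions", "latency_s"
    )
  }
  n_cells <- length(unique(paste(manifest$handling, manifest$treatment)))
  stats <- if (n_cells >= 2 && design$n_per_group >= 2) {
    cohort_stats(metrics, metrics = stats_metrics)
  } else {
    tibble::tibble()
  }
  agreement <- staging_agreement(cm_total)
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(metrics, file.path(out_dir, "cohort_metrics.csv"))
    if (nrow(stats) > 0) {
      readr::write_csv(stats, file.path(out_dir, "stats.csv"))
    }
    readr::write_csv(as.data.frame(cm_total),
                     file.path(out_dir, "staging_confusion.csv"))
    readr::write_csv(agreement, file.path(out_dir, "staging_agreement.csv"))
  }
  structure(
    list(manifest = manifest, metrics = metrics, stats = stats,
         confusion = cm_total, agreement = agreement, config = config),
    class = "psg_run"
  )
}

config_as_list <- function(config) {
  d <- config$design
  list(
    design = list(
      n_per_group = d$n_per_group, handling = d$handling,
      treatment = d$treatment, duration_h = d$duration_h, seed = d$seed,
      zt_start = d$zt_start,
      state_params = lapply(d$state_params, function(p) {
        list(band_amplitudes = as.list(p$band_amplitudes),
             emg_amplitude = p$emg_amplitude, dwell_mean = p$dwell_mean,
             dwell_shape = p$dwell_shape, dark_dwell_mult = p$dark_dwell_mult)
      }),
      transitions = d$transitions, fne = d$fne, effects = d$effects
    ),
    windows = config$windows,
    latency_min_bout = config$latency_min_bout,
    interruption_max = config$interruption_max,
    bout_edges = config$bout_edges,
    eeg_filter = config$eeg_filter, emg_filter = config$emg_filter,
    background = config$background, quantize = config$quantize,
    smooth_min_run = config$smooth_min_run
  )
}

#' @export
print.psg_run <- function(x, ...) {
  cat(sprintf("<psg_run> %d animals, staging agreement %.3f\n",
              nrow(x$manifest), x$agreement$agreement))
  invisible(x)
}
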