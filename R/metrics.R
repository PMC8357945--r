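#' Consolidate a hypnogram into episodes
#'
#' Maximal-run decomposition of the state sequence: each episode is a run of
#' consecutive epochs in one state. Episodes tile the hypnogram exactly, and
#' concatenating them reproduces the input.
#'
#' @param hyp A [hypnogram()].
#' @return An episode tibble: `state`, `start_epoch` (0-based),
#'   `start_zt` (s), `n_epochs`, `duration` (s).
#' @export
#' @examples
#' consolidate_episodes(hypnogram(c("W", "W", "N", "N", "N", "R")))
consolidate_episodes <- function(hyp) {
  stopifnot(inherits(hyp, "psg_hypnogram"))
  if (nrow(hyp) == 0) stop("empty hypnogram", call. = FALSE)
  ep_len <- hyp_epoch_len(hyp)
  r <- rle(as.character(hyp$state))
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  tibble::tibble(
    state = as_state_factor(r$values),
    start_epoch = start,
    start_zt = hyp$zt_seconds[1] + start * ep_len,
    n_epochs = r$lengths,
    duration = r$lengths * ep_len
  )
}

# validate a [lo, hi) ZT window against the recorded span
check_window <- function(hyp, window) {
  ep_len <- hyp_epoch_len(hyp)
  span <- c(hyp$zt_seconds[1], hyp$zt_seconds[nrow(hyp)] + ep_len)
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9 ||
      window[2] <= window[1]) {
    stop(sprintf(
      "window [%g, %g) outside recorded span [%g, %g)",
      window[1], window[2], span[1], span[2]
    ), call. = FALSE)
  }
  invisible(window)
}

#' Time in each state within a ZT window
#'
#' Each epoch credits its full 8 s to its state; epochs belong to the
#' half-open window `[lo, hi)` by their start time, so the totals sum
#' exactly to the window length on fully recorded windows.
#'
#' @param hyp A [hypnogram()].
#' @param window Length-2 ZT window in seconds, `c(lo, hi)`; default the full
#'   recording.
#' @return Tibble `state`, `seconds`.
#' @export
state_totals <- function(hyp, window = NULL) {
  stopifnot(inherits(hyp, "psg_hypnogram"))
  ep_len <- hyp_epoch_len(hyp)
  if (is.null(window)) {
    window <- c(hyp$zt_seconds[1], hyp$zt_seconds[nrow(hyp)] + ep_len)
  }
  check_window(hyp, window)
  inside <- hyp$zt_seconds >= window[1] & hyp$zt_seconds < window[2]
  counts <- table(hyp$state[inside])
  tibble::tibble(
    state = as_state_factor(names(counts)),
    seconds = as.numeric(counts) * ep_len
  )
}

#' Bout-length histogram for one state
#'
#' Bins the durations of one state's episodes into right-closed duration
#' bins, always including an open top bin (e.g. the "> 300 s" wake-bout
#' class).
#'
#' @param episodes Episode tibble from [consolidate_episodes()].
#' @param state State to histogram (`"W"`, `"N"` or `"R"`).
#' @param bin_edges Strictly increasing edges in seconds (default 300, i.e.
#'   bins `<= 300 s` and `> 300 s`).
#' @return Tibble `bin`, `lo`, `hi`, `count`.
#' @export
#' @examples
#' eps <- consolidate_episodes(hypnogram(rep(c("W", "N"), c(50, 10))))
#' bout_histogram(eps, "W")
bout_histogram <- function(episodes, state, bin_edges = 300) {
  state <- match.arg(state, psg_states())
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  lo <- c(0, bin_edges)
  hi <- c(bin_edges, Inf)
  d <- episodes$duration[episodes$state == state]
  count <- vapply(seq_along(lo), function(i) sum(d > lo[i] & d <= hi[i]),
                  numeric(1))
  tibble::tibble(
    bin = ifelse(is.finite(hi), paste0("<=", hi), paste0(">", lo)),
    lo = lo, hi = hi, count = count
  )
}

#' State-transition counts and hourly rates
#'
#' Counts each ordered pair of adjacent episodes (s to t, s != t) and
#' normalizes to transitions per hour.
#'
#' @param episodes Episode tibble from [consolidate_episodes()].
#' @param window_hours Window length in hours used for the rate (`> 0`).
#' @return Tibble `from`, `to`, `count`, `per_hour` covering all six ordered
#'   state pairs.
#' @export
transition_analysis <- function(episodes, window_hours) {
  stopifnot(window_hours > 0)
  pairs <- expand.grid(from = psg_states(), to = psg_states(),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  s <- as.character(episodes$state)
  n <- length(s)
  from <- if (n > 1) s[-n] else character(0)
  to <- if (n > 1) s[-1] else character(0)
  count <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(from == pairs$from[i] & to == pairs$to[i])
  }, numeric(1))
  tibble::tibble(
    from = pairs$from, to = pairs$to,
    count = count, per_hour = count / window_hours
  )
}

#' Count NREM interruptions
#'
#' A NREM interruption is a brief wake episode — duration at most
#' `max_interruption` seconds — whose flanking episodes are both NREM.
#'
#' @param episodes Episode tibble from [consolidate_episodes()].
#' @param max_interruption Maximum wake duration to count, seconds
#'   (default 64, i.e. 8 epochs).
#' @return Integer count.
#' @export
nrem_interruptions <- function(episodes, max_interruption = 64) {
  stopifnot(max_interruption >= psg_epoch_len())
  s <- as.character(episodes$state)
  n <- length(s)
  if (n < 3) return(0L)
  i <- 2:(n - 1)
  sum(s[i] == "W" & episodes$duration[i] <= max_interruption &
        s[i - 1] == "N" & s[i + 1] == "N")
}

#' Sleep latency
#'
#' Elapsed time from the first epoch (the intervention, ZT 0 by design) to
#' the start of the first NREM episode lasting strictly longer than
#' `min_bout` seconds ("longer than 5 min": a 296-s bout does not qualify).
#' When no such episode exists the latency is undefined: `NA` with
#' `censored = TRUE` (group-level code substitutes the window length).
#'
#' @param hyp A [hypnogram()].
#' @param min_bout Qualifying bout duration threshold, seconds (default 300).
#' @return One-row tibble `latency_s`, `censored`.
#' @export
#' @examples
#' h <- hypnogram(rep(c("W", "N", "W", "N"), c(10, 37, 5, 40)))
#' sleep_latency(h) # 416 s: the 296-s bout fails "longer than 5 min"
sleep_latency <- function(hyp, min_bout = 300) {
  eps <- consolidate_episodes(hyp)
  ok <- which(eps$state == "N" & eps$duration > min_bout)
  if (length(ok) == 0) {
    return(tibble::tibble(latency_s = NA_real_, censored = TRUE))
  }
  ep_len <- hyp_epoch_len(hyp)
  tibble::tibble(latency_s = eps$start_epoch[ok[1]] * ep_len,
                 censored = FALSE)
}

#' Hourly state totals, REM accumulation and relative NREM-delta power
#'
#' Per clock hour from ZT 0: seconds in each state, per-hour and cumulative
#' REM seconds, and — when a band-power series is supplied — the mean delta
#' power over that hour's NREM epochs normalized within-animal by the mean
#' NREM delta power over `ref_window` (default the light phase, ZT 0-8,
#' clipped to the recording). Hours without any NREM epoch get `NA`.
#'
#' @param hyp A [hypnogram()].
#' @param series Optional `psg_bands_series` on the same epoch grid.
#' @param ref_window Normalization window for NREM-delta, ZT seconds.
#' @return Tibble `hour`, `wake_s`, `nrem_s`, `rem_s`, `rem_cum_s`,
#'   `nrem_delta_rel`.
#' @export
hourly_profiles <- function(hyp, series = NULL, ref_window = c(0, 8 * 3600)) {
  stopifnot(inherits(hyp, "psg_hypnogram"))
  ep_len <- hyp_epoch_len(hyp)
  if (!is.null(series)) {
    if (nrow(series) != nrow(hyp) ||
        any(abs(series$zt_seconds - hyp$zt_seconds) > 1e-9)) {
      stop("hypnogram and band-power series are on different epoch grids",
           call. = FALSE)
    }
  }
  hour <- floor(hyp$zt_seconds / 3600)
  df <- tibble::tibble(hour = hour, state = hyp$state)
  if (!is.null(series)) df$delta <- series$delta
  is_n <- df$state == "N"
  ref <- NA_real_
  if (!is.null(series)) {
    in_ref <- hyp$zt_seconds >= ref_window[1] & hyp$zt_seconds < ref_window[2]
    if (any(is_n & in_ref)) ref <- mean(series$delta[is_n & in_ref])
  }
  out <- df |>
    dplyr::group_by(hour = .data$hour) |>
    dplyr::summarise(
      wake_s = sum(.data$state == "W") * ep_len,
      nrem_s = sum(.data$state == "N") * ep_len,
      rem_s = sum(.data$state == "R") * ep_len,
      nrem_delta_rel = if (is.null(series) || !is.finite(ref)) NA_real_ else {
        n_sel <- .data$state == "N"
        if (any(n_sel)) mean(.data$delta[n_sel]) / ref else NA_real_
      },
      .groups = "drop"
    )
  out$rem_cum_s <- cumsum(out$rem_s)
  out[, c("hour", "wake_s", "nrem_s", "rem_s", "rem_cum_s", "nrem_delta_rel")]
}

#' Full architecture summary of one animal
#'
#' Computes every architecture metric per analysis window (half-open ZT
#' intervals, default the full recording): state totals, episode counts,
#' bout histograms, transition counts and per-hour rates, NREM
#' interruptions; plus the recording-level sleep latency and hourly profiles
#' (including cumulative REM accumulation and relative NREM-delta power when
#' a band-power series is given). Episodes straddling a window boundary are
#' truncated at the boundary for totals but counted once — in the window
#' containing their start — for episode and transition counts.
#'
#' @param hyp A [hypnogram()].
#' @param series Optional `psg_bands_series` on the same grid.
#' @param windows Named list of ZT windows in seconds (each `c(lo, hi)`);
#'   default one window spanning the recording.
#' @param latency_min_bout Latency qualifying-bout threshold, seconds.
#' @param interruption_max NREM-interruption wake cap, seconds.
#' @param bout_edges Bout histogram edges, seconds.
#' @param ref_window NREM-delta normalization window ([hourly_profiles()]).
#' @return A `psg_architecture` object; use [tidy()] for the long metric
#'   table.
#' @export
#' @examples
#' d <- cohort_design(duration_h = 2, seed = 9)
#' truth <- sample_hypnogram(d)
#' summ <- summarize_architecture(truth$hypnogram)
#' tidy(summ)
summarize_architecture <- function(hyp, series = NULL, windows = NULL,
                                   latency_min_bout = 300,
                                   interruption_max = 64,
                                   bout_edges = 300,
                                   ref_window = c(0, 8 * 3600)) {
  stopifnot(inherits(hyp, "psg_hypnogram"))
  ep_len <- hyp_epoch_len(hyp)
  span <- c(hyp$zt_seconds[1], hyp$zt_seconds[nrow(hyp)] + ep_len)
  if (is.null(windows)) windows <- list(full = span)
  if (is.null(names(windows)) || any(names(windows) == "")) {
    names(windows) <- vapply(windows, function(w) {
      sprintf("zt%g_%g", w[1] / 3600, w[2] / 3600)
    }, character(1))
  }
  eps_all <- consolidate_episodes(hyp)
  ref_window <- c(max(ref_window[1], span[1]), min(ref_window[2], span[2]))

  per_window <- lapply(windows, function(w) {
    check_window(hyp, w)
    hours <- (w[2] - w[1]) / 3600
    # episodes counted in the window containing their start
    eps <- eps_all[eps_all$start_zt >= w[1] & eps_all$start_zt < w[2], ]
    trans_all <- transition_analysis(eps_all, hours)
    # a transition happens at the start of the second episode of the pair
    s <- as.character(eps_all$state)
    n <- length(s)
    if (n > 1) {
      at <- eps_all$start_zt[-1]
      keep <- at >= w[1] & at < w[2]
      from <- s[-n][keep]
      to <- s[-1][keep]
      trans <- trans_all
      trans$count <- vapply(seq_len(nrow(trans)), function(i) {
        sum(from == trans$from[i] & to == trans$to[i])
      }, numeric(1))
      trans$per_hour <- trans$count / hours
    } else {
      trans <- trans_all
    }
    list(
      window = w,
      totals = state_totals(hyp, w),
      episode_counts = eps |>
        dplyr::count(.data$state, name = "count", .drop = FALSE),
      bouts = purrr::map(setNames(psg_states(), psg_states()),
                         ~ bout_histogram(eps, .x, bout_edges)),
      transitions = trans,
      nrem_interruptions = nrem_interruptions(eps, interruption_max)
    )
  })

  structure(
    list(
      windows = per_window,
      latency = sleep_latency(hyp, latency_min_bout),
      hourly = hourly_profiles(hyp, series, ref_window),
      meta = list(
        animal_id = attr(hyp, "animal_id"), handling = attr(hyp, "handling"),
        treatment = attr(hyp, "treatment"),
        latency_min_bout = latency_min_bout,
        interruption_max = interruption_max, bout_edges = bout_edges,
        ref_window = ref_window, recording_span = span
      )
    ),
    class = "psg_architecture"
  )
}

#' @export
print.psg_architecture <- function(x, ...) {
  cat("<psg_architecture>", x$meta$animal_id %||% "", "\n")
  for (w in names(x$windows)) {
    tot <- x$windows[[w]]$totals
    cat(sprintf(
      "  %s: %s | interruptions %d\n", w,
      paste(sprintf("%s %gs", tot$state, tot$seconds), collapse = ", "),
      x$windows[[w]]$nrem_interruptions
    ))
  }
  lat <- x$latency
  cat(sprintf("  latency: %s\n",
              if (lat$censored) "undefined (censored)"
              else paste0(lat$latency_s, " s")))
  invisible(x)
}

#' Tidy an architecture summary into a long metric table
#'
#' One row per (window, metric): totals (`total_W` ... seconds), episode
#' counts (`episodes_W` ...), transition rates (`trans_W_N_per_h` ...),
#' bout-bin counts (`bouts_W_gt300` ...), `nrem_interruptions`, plus
#' recording-level `latency_s` (censored latencies carried as the recording
#' span with `censored = 1`) and hourly metrics (`wake_s_h0`,
#' `nrem_delta_rel_h0`, `rem_cum_s_h0`, ...) under window `"hourly"`.
#'
#' @param x A `psg_architecture`.
#' @param ... Unused.
#' @return Tibble `animal_id`, `handling`, `treatment`, `window`, `metric`,
#'   `value`, `censored`.
#' @method tidy psg_architecture
#' @export
tidy.psg_architecture <- function(x, ...) {
  m <- x$meta
  rows <- list()
  for (w in names(x$windows)) {
    wl <- x$windows[[w]]
    tot <- setNames(wl$totals$seconds, paste0("total_", wl$totals$state))
    epc <- setNames(wl$episode_counts$count,
                    paste0("episodes_", wl$episode_counts$state))
    tr <- setNames(wl$transitions$per_hour,
                   paste0("trans_", wl$transitions$from, "_",
                          wl$transitions$to, "_per_h"))
    bt <- unlist(lapply(psg_states(), function(s) {
      b <- wl$bouts[[s]]
      setNames(b$count, paste0(
        "bouts_", s, "_",
        ifelse(is.finite(b$hi), paste0("le", b$hi), paste0("gt", b$lo))
      ))
    }))
    v <- c(tot, epc, tr, bt, nrem_interruptions = wl$nrem_interruptions)
    rows[[w]] <- tibble::tibble(window = w, metric = names(v),
                                value = as.numeric(v), censored = 0)
  }
  span_len <- diff(m$recording_span)
  lat_val <- if (x$latency$censored) span_len else x$latency$latency_s
  rows[["latency"]] <- tibble::tibble(
    window = "recording", metric = "latency_s", value = lat_val,
    censored = as.numeric(x$latency$censored)
  )
  h <- x$hourly
  hv <- c(
    setNames(h$wake_s, paste0("wake_s_h", h$hour)),
    setNames(h$nrem_s, paste0("nrem_s_h", h$hour)),
    setNames(h$rem_s, paste0("rem_s_h", h$hour)),
    setNames(h$rem_cum_s, paste0("rem_cum_s_h", h$hour)),
    setNames(h$nrem_delta_rel, paste0("nrem_delta_rel_h", h$hour))
  )
  rows[["hourly"]] <- tibble::tibble(window = "hourly", metric = names(hv),
                                     value = as.numeric(hv), censored = 0)
  out <- dplyr::bind_rows(rows)
  tibble::tibble(
    animal_id = m$animal_id %||% NA_character_,
    handling = m$handling %||% NA_character_,
    treatment = m$treatment %||% NA_character_,
    out
  )
}

#' Glance at an architecture summary
#' @param x A `psg_architecture`.
#' @param ... Unused.
#' @return One-row tibble with headline metrics of the first window.
#' @method glance psg_architecture
#' @export
glance.psg_architecture <- function(x, ...) {
  w1 <- x$windows[[1]]
  tot <- setNames(w1$totals$seconds, paste0("total_", w1$totals$state))
  tibble::tibble(
    animal_id = x$meta$animal_id %||% NA_character_,
    !!!as.list(tot),
    nrem_interruptions = w1$nrem_interruptions,
    latency_s = x$latency$latency_s,
    latency_censored = x$latency$censored
  )
}
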