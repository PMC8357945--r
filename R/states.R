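#' Vigilance states
#'
#' The three vigilance states scored on the 8-s epoch grid: `"W"` (wake),
#' `"N"` (NREM sleep), `"R"` (REM sleep).
#'
#' @return Character vector of the three state codes, in canonical order.
#' @export
#' @examples
#' psg_states()
psg_states <- function() c("W", "N", "R")

#' Seconds per scoring epoch (8 s throughout the package).
#' @return A number, 8.
#' @export
psg_epoch_len <- function() 8

# coerce a character vector to the canonical state factor, validating values
as_state_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), psg_states())
  if (length(bad) > 0) {
    stop("invalid vigilance state(s): ", paste(bad, collapse = ", "),
         " (allowed: W, N, R)", call. = FALSE)
  }
  factor(x, levels = psg_states())
}

#' Construct a hypnogram tibble
#'
#' A hypnogram is the per-epoch sequence of vigilance states. It is stored as
#' a tibble with one row per 8-s epoch: `epoch_index` (0-based),
#' `zt_seconds` (epoch start, seconds from Zeitgeber time 0) and `state`
#' (factor with levels W/N/R).
#'
#' @param states Character or factor vector of per-epoch states (W/N/R).
#' @param zt_start Start of the first epoch, seconds from ZT 0.
#' @param epoch_len Epoch length in seconds (default 8).
#' @param animal_id,handling,treatment Optional labels carried as attributes.
#' @return A `psg_hypnogram` tibble.
#' @export
#' @examples
#' hypnogram(c("W", "W", "N", "N", "R"))
hypnogram <- function(states, zt_start = 0, epoch_len = psg_epoch_len(),
                      animal_id = NA_character_, handling = NA_character_,
                      treatment = NA_character_) {
  st <- as_state_factor(states)
  n <- length(st)
  if (n == 0) stop("hypnogram must contain at least one epoch", call. = FALSE)
  out <- tibble::tibble(
    epoch_index = seq_len(n) - 1L,
    zt_seconds = zt_start + (seq_len(n) - 1L) * epoch_len,
    state = st
  )
  structure(out,
    class = c("psg_hypnogram", class(out)),
    epoch_len = epoch_len, zt_start = zt_start,
    animal_id = animal_id, handling = handling, treatment = treatment
  )
}

hyp_epoch_len <- function(hyp) attr(hyp, "epoch_len") %||% psg_epoch_len()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psg_hypnogram <- function(x, ...) {
  n <- nrow(x)
  tab <- table(x$state)
  cat(sprintf(
    "<psg_hypnogram> %d epochs x %gs (%.2f h), ZT start %gs\n",
    n, hyp_epoch_len(x), n * hyp_epoch_len(x) / 3600, attr(x, "zt_start") %||% 0
  ))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  NextMethod()
}
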