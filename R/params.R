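#' EEG analysis bands
#'
#' Frequency bands used for per-epoch EEG power integration: delta 0.16-4 Hz,
#' theta 6-9 Hz, sigma 10-14 Hz, beta 14-32 Hz. The bands deliberately leave
#' gaps at 4-6 and 9-10 Hz; band membership is half-open (`lo <= f < hi`) so
#' adjacent bands such as sigma and beta never double-count an edge bin.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' psg_bands()
psg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "sigma", "beta"),
    lo = c(0.16, 6, 10, 14),
    hi = c(4, 9, 14, 32)
  )
}

#' EMG integration band (32-64 Hz).
#' @return Numeric length-2 vector `c(lo, hi)` in Hz.
#' @export
psg_emg_band <- function() c(32, 64)

#' Per-state generator parameters
#'
#' Describes how one vigilance state expresses itself in the synthetic
#' signals and in the dwell-time process: EEG band amplitudes (arbitrary
#' units; per-epoch band power scales with amplitude squared), EMG amplitude,
#' and a log-normal dwell-time law with mean `dwell_mean` seconds and
#' log-scale standard deviation `dwell_shape`. `dark_dwell_mult` rescales the
#' dwell mean in the dark phase (ZT 12-24).
#'
#' @param state One of `"W"`, `"N"`, `"R"`.
#' @param band_amplitudes Named numeric vector with entries delta, theta,
#'   sigma, beta (all `>= 0`).
#' @param emg_amplitude EMG amplitude, `>= 0`.
#' @param dwell_mean Mean dwell time in seconds (`> 0`), light phase.
#' @param dwell_shape Log-normal `sdlog` of the dwell distribution.
#' @param dark_dwell_mult Multiplier applied to `dwell_mean` in the dark phase.
#' @return A `state_params` list.
#' @export
state_params <- function(state, band_amplitudes, emg_amplitude,
                         dwell_mean, dwell_shape, dark_dwell_mult = 1) {
  state <- match.arg(state, psg_states())
  need <- psg_bands()$band
  if (!all(need %in% names(band_amplitudes))) {
    stop("band_amplitudes must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  band_amplitudes <- band_amplitudes[need]
  if (any(band_amplitudes < 0) || emg_amplitude < 0) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (dwell_mean <= 0) stop("dwell_mean must be > 0", call. = FALSE)
  structure(
    list(
      state = state, band_amplitudes = band_amplitudes,
      emg_amplitude = emg_amplitude, dwell_mean = dwell_mean,
      dwell_shape = dwell_shape, dark_dwell_mult = dark_dwell_mult
    ),
    class = "state_params"
  )
}

#' Default state parameters for the synthetic cohort
#'
#' Defaults encode the spectral signatures the staging rules assume:
#' delta-dominant NREM, theta-dominant REM, broadband low-amplitude wake EEG;
#' high wake EMG, low NREM EMG, near-atonic REM EMG; and sigma*theta power
#' higher in both sleep states than in wake. Dwell means give a light-phase
#' occupancy of roughly 35% wake / 58% NREM / 7% REM with long wake bouts in
#' the dark phase, in line with C57BL/6 baseline sleep.
#'
#' @return Named list of [state_params()] for W, N and R.
#' @export
default_state_params <- function() {
  list(
    W = state_params("W",
      band_amplitudes = c(delta = 1.0, theta = 1.2, sigma = 0.4, beta = 1.0),
      emg_amplitude = 3.0, dwell_mean = 250, dwell_shape = 1.0,
      dark_dwell_mult = 4
    ),
    N = state_params("N",
      band_amplitudes = c(delta = 3.5, theta = 0.8, sigma = 1.5, beta = 0.5),
      emg_amplitude = 0.5, dwell_mean = 400, dwell_shape = 0.7,
      dark_dwell_mult = 0.6
    ),
    R = state_params("R",
      band_amplitudes = c(delta = 0.5, theta = 2.5, sigma = 1.2, beta = 0.6),
      emg_amplitude = 0.15, dwell_mean = 120, dwell_shape = 0.4,
      dark_dwell_mult = 0.8
    )
  )
}

validate_state_params <- function(sp) {
  stopifnot(all(psg_states() %in% names(sp)))
  amp <- function(s, b) sp[[s]]$band_amplitudes[[b]]
  if (!(amp("N", "delta") > amp("W", "delta") &&
        amp("N", "delta") > amp("R", "delta"))) {
    stop("NREM delta amplitude must exceed both wake and REM delta amplitudes",
         call. = FALSE)
  }
  emg <- vapply(sp, function(p) p$emg_amplitude, numeric(1))
  if (!(emg[["W"]] > emg[["N"]] && emg[["N"]] >= emg[["R"]])) {
    stop("EMG amplitudes must satisfy wake > NREM >= REM", call. = FALSE)
  }
  st <- function(s) (amp(s, "sigma") * amp(s, "theta"))^2
  if (!(st("N") > st("W") && st("R") > st("W"))) {
    stop("sigma*theta power must be higher in NREM and REM than in wake",
         call. = FALSE)
  }
  invisible(sp)
}

#' Transition and arousal parameters of the semi-Markov generator
#'
#' REM is reachable only from NREM; wake is reachable from both sleep states;
#' wake always yields to NREM. `p_nrem_to_rem` is the probability that a NREM
#' bout ends in a NREM-to-REM transition (per light/dark phase);
#' `p_rem_to_wake` the probability a REM bout ends in wake. `arousal_rate` is
#' the per-epoch probability that an interior NREM epoch is followed by a
#' brief wake interruption of `arousal_len_epochs` epochs before NREM
#' resumes — the process behind NREM fragmentation.
#'
#' @param p_nrem_to_rem Named vector `c(light = , dark = )`, probabilities.
#' @param p_rem_to_wake Probability.
#' @param arousal_rate Per-epoch brief-arousal probability within NREM bouts.
#' @param arousal_len_epochs Integer vector of possible interruption lengths.
#' @return A list of transition parameters.
#' @export
transition_params <- function(p_nrem_to_rem = c(light = 0.35, dark = 0.25),
                              p_rem_to_wake = 0.7,
                              arousal_rate = 0.004,
                              arousal_len_epochs = 1:3) {
  stopifnot(
    all(p_nrem_to_rem >= 0 & p_nrem_to_rem <= 1),
    p_rem_to_wake >= 0, p_rem_to_wake <= 1,
    arousal_rate >= 0, arousal_rate < 1
  )
  list(
    p_nrem_to_rem = p_nrem_to_rem, p_rem_to_wake = p_rem_to_wake,
    arousal_rate = arousal_rate, arousal_len_epochs = as.integer(arousal_len_epochs)
  )
}

#' First-night-effect parameters of the cage-change manipulation
#'
#' Cage-changed (CC) animals start the recording with a wake dwell drawn from
#' an inflated distribution (`initial_wake_mean` seconds), have wake dwells
#' lengthened and NREM dwells shortened during the first `early_hours` hours,
#' and have the NREM-to-REM transition probability multiplied by
#' `rem_suppression[h]` during hour `h` after the cage change (1 after the
#' listed hours) — emulating prolonged initial wakefulness, reduced
#' light-phase NREM and delayed REM recovery.
#'
#' @param initial_wake_mean,initial_wake_shape Log-normal mean (s) and sdlog
#'   of the CC initial wake dwell.
#' @param early_hours Duration of the early-light suppression window (h).
#' @param early_wake_mult,early_nrem_mult Dwell-mean multipliers in that window.
#' @param rem_suppression Per-hour multipliers on the NREM-to-REM probability.
#' @return A list of FNE parameters.
#' @export
fne_params <- function(initial_wake_mean = 3000, initial_wake_shape = 0.3,
                       early_hours = 2, early_wake_mult = 2,
                       early_nrem_mult = 0.5,
                       rem_suppression = c(0, 0.3, 0.7)) {
  stopifnot(initial_wake_mean > 0, early_hours >= 0,
            all(rem_suppression >= 0 & rem_suppression <= 1))
  list(
    initial_wake_mean = initial_wake_mean,
    initial_wake_shape = initial_wake_shape,
    early_hours = early_hours, early_wake_mult = early_wake_mult,
    early_nrem_mult = early_nrem_mult, rem_suppression = rem_suppression
  )
}

#' Treatment presets
#'
#' Per-treatment multiplicative adjustments to the generator:
#' * `Veh` — no adjustment.
#' * `DIPH` (antihistamine-like) — halves the REM dwell mean and quadruples
#'   the brief-arousal rate, emulating REM suppression and NREM
#'   fragmentation.
#' * `PS150` (probiotic-like) — shortens the FNE-inflated initial wake dwell
#'   only (multiplier 1/3), emulating restored sleep onset.
#'
#' @return Named list of per-treatment effect lists with elements
#'   `rem_dwell_mult`, `arousal_mult`, `initial_wake_mult`.
#' @export
treatment_presets <- function() {
  base <- list(rem_dwell_mult = 1, arousal_mult = 1, initial_wake_mult = 1)
  list(
    Veh = base,
    DIPH = utils::modifyList(base, list(rem_dwell_mult = 0.5, arousal_mult = 4)),
    PS150 = utils::modifyList(base, list(initial_wake_mult = 1 / 3))
  )
}

#' Cohort design for the cage-change experiment
#'
#' Describes a (handling x treatment) factorial cohort: `handling` TH
#' (tail-handled) or CC (cage change), `treatment` Veh / DIPH / PS150, with
#' `n_per_group` animals per cell and `duration_h` hours of recording
#' starting at ZT 0.
#'
#' @param n_per_group Animals per design cell (`>= 1`).
#' @param handling Character vector of handling levels (subset of TH, CC).
#' @param treatment Character vector of treatment levels.
#' @param duration_h Recording duration in hours (must be a whole number of
#'   8-s epochs).
#' @param seed Integer master seed; per-animal seeds are derived from it.
#' @param state_params Named list of [state_params()]; validated against the
#'   staging-rule invariants.
#' @param transitions [transition_params()].
#' @param fne [fne_params()].
#' @param effects Named list of per-treatment effect lists
#'   ([treatment_presets()]).
#' @param allowed_states States the chain may visit (default all three).
#' @param zt_start Recording start in seconds from ZT 0.
#' @return A `cohort_design` list.
#' @export
#' @examples
#' d <- cohort_design(n_per_group = 2, duration_h = 1, seed = 42)
cohort_design <- function(n_per_group = 8,
                          handling = c("TH", "CC"),
                          treatment = c("Veh", "DIPH", "PS150"),
                          duration_h = 8, seed = 1,
                          state_params = default_state_params(),
                          transitions = transition_params(),
                          fne = fne_params(),
                          effects = treatment_presets(),
                          allowed_states = psg_states(),
                          zt_start = 0) {
  stopifnot(n_per_group >= 1, duration_h > 0)
  handling <- match.arg(handling, c("TH", "CC"), several.ok = TRUE)
  treatment <- match.arg(treatment, c("Veh", "DIPH", "PS150"), several.ok = TRUE)
  n_ep <- duration_h * 3600 / psg_epoch_len()
  if (abs(n_ep - round(n_ep)) > 1e-9) {
    stop("duration_h must correspond to a whole number of 8-s epochs",
         call. = FALSE)
  }
  allowed_states <- match.arg(allowed_states, psg_states(), several.ok = TRUE)
  validate_state_params(state_params)
  structure(
    list(
      n_per_group = as.integer(n_per_group), handling = handling,
      treatment = treatment, duration_h = duration_h, seed = as.integer(seed),
      state_params = state_params, transitions = transitions, fne = fne,
      effects = effects, allowed_states = allowed_states, zt_start = zt_start
    ),
    class = "cohort_design"
  )
}

# deterministic per-animal seed: polynomial hash of (seed, cell, animal)
# mod 2^31 - 1, safe in double arithmetic (intermediate < 2^48)
derive_seed <- function(seed, handling, treatment, animal_index) {
  cell <- match(handling, c("TH", "CC")) * 3 +
    match(treatment, c("Veh", "DIPH", "PS150"))
  v <- 0
  for (x in c(seed, cell, animal_index)) {
    v <- (v * 69069 + as.numeric(x)) %% 2147483647
  }
  as.integer(v %% 2147483629 + 1)
}
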