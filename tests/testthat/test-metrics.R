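test_that("episode consolidation is exact run-length decomposition", {
  eps <- consolidate_episodes(hypnogram(c("W", "W", "N", "N", "N", "R")))
  expect_equal(as.character(eps$state), c("W", "N", "R"))
  expect_equal(eps$n_epochs, c(2L, 3L, 1L))
  expect_equal(eps$duration, c(16, 24, 8))
  expect_equal(eps$start_epoch, c(0L, 2L, 5L))

  one <- consolidate_episodes(hypnogram(rep("N", 10)))
  expect_equal(nrow(one), 1)
  expect_equal(one$duration, 80)
})

test_that("episodes tile random hypnograms exactly", {
  withr::local_seed(21)
  for (i in 1:200) {
    st <- random_states(sample(5:200, 1))
    eps <- consolidate_episodes(hypnogram(st))
    rebuilt <- rep(as.character(eps$state), eps$n_epochs)
    expect_identical(rebuilt, st)
    if (nrow(eps) > 1) { # adjacent episodes always differ in state
      expect_true(all(as.character(eps$state)[-1] !=
                        as.character(eps$state)[-nrow(eps)]))
    }
  }
})

test_that("state totals credit 8 s per epoch and sum to the window", {
  allw <- hypnogram(rep("W", 8 * 450))
  tot <- state_totals(allw, c(0, 8 * 3600))
  expect_equal(tot$seconds[tot$state == "W"], 28800)
  expect_equal(sum(tot$seconds), 28800)

  cyc <- hypnogram(rep(c("W", "N", "R"), 3600))
  tc <- state_totals(cyc)
  expect_true(all(tc$seconds == 3600 * 8))

  withr::local_seed(22)
  st <- random_states(500)
  tr <- state_totals(hypnogram(st))
  expect_equal(setNames(tr$seconds, tr$state), bf_totals(st))
  expect_error(state_totals(allw, c(0, 10 * 3600)), "outside")
})

test_that("bout histograms bin durations with an open top bin", {
  st <- rep(c("W", "N", "W", "N", "W", "N"), c(10, 5, 40, 5, 50, 5))
  eps <- consolidate_episodes(hypnogram(st))
  h <- bout_histogram(eps, "W", 300)
  expect_equal(h$count, c(1, 2)) # 80 s; 320 s and 400 s
  expect_equal(h$bin, c("<=300", ">300"))
  expect_true(all(bout_histogram(eps, "R")$count == 0))
  expect_error(bout_histogram(eps, "W", c(300, 100)), "increasing")

  withr::local_seed(23)
  for (i in 1:100) {
    stx <- random_states(sample(20:300, 1))
    epsx <- consolidate_episodes(hypnogram(stx))
    for (s in c("W", "N", "R")) {
      hx <- bout_histogram(epsx, s, c(16, 40, 300))
      expect_equal(sum(hx$count), sum(epsx$state == s))
      expect_equal(unname(bf_bout_counts(stx, s)["gt"]),
                   bout_histogram(epsx, s, 300)$count[2])
    }
  }
})

test_that("transition counts cover ordered pairs and conserve episodes", {
  st <- rep(c("W", "N", "R", "N", "W"), each = 4)
  tr <- transition_analysis(consolidate_episodes(hypnogram(st)), 2)
  get <- function(a, b) tr$count[tr$from == a & tr$to == b]
  expect_equal(get("W", "N"), 1)
  expect_equal(get("N", "R"), 1)
  expect_equal(get("R", "N"), 1)
  expect_equal(get("N", "W"), 1)
  expect_equal(sum(tr$count), 4)
  expect_equal(tr$per_hour, tr$count / 2)

  single <- transition_analysis(consolidate_episodes(hypnogram(rep("N", 5))), 1)
  expect_true(all(single$count == 0))

  withr::local_seed(24)
  for (i in 1:100) {
    stx <- random_states(sample(10:300, 1))
    epsx <- consolidate_episodes(hypnogram(stx))
    trx <- transition_analysis(epsx, 1)
    expect_equal(sum(trx$count), nrow(epsx) - 1)
    bf <- bf_transitions(stx)
    for (j in seq_len(nrow(trx))) {
      expect_equal(trx$count[j], bf[trx$from[j], trx$to[j]])
    }
  }
})

test_that("NREM interruptions are capped brief wake bouts flanked by NREM", {
  st <- rep(c("N", "W", "N"), c(10, 2, 10))
  expect_equal(nrem_interruptions(consolidate_episodes(hypnogram(st))), 1)
  st2 <- rep(c("N", "W", "N"), c(10, 20, 10)) # 160 s wake exceeds the cap
  expect_equal(nrem_interruptions(consolidate_episodes(hypnogram(st2))), 0)

  withr::local_seed(25)
  for (i in 1:100) {
    stx <- random_states(sample(10:300, 1))
    epsx <- consolidate_episodes(hypnogram(stx))
    got <- nrem_interruptions(epsx, 64)
    expect_equal(got, bf_interruptions(stx, 64))
    expect_lte(got, sum(epsx$state == "W"))
  }
})

test_that("sleep latency follows the strictly-longer-than rule", {
  h <- hypnogram(rep(c("W", "N", "W", "N"), c(10, 37, 5, 40)))
  lat <- sleep_latency(h)
  expect_equal(lat$latency_s, 416) # 296-s bout fails "longer than 5 min"
  expect_false(lat$censored)

  expect_equal(sleep_latency(hypnogram(rep("N", 39)))$latency_s, 0)
  allw <- sleep_latency(hypnogram(rep("W", 100)))
  expect_true(allw$censored)
  expect_true(is.na(allw$latency_s))

  # monotonicity: k prepended wake epochs add exactly 8k seconds
  withr::local_seed(26)
  base <- c(rep("W", 5), rep("N", 45), random_states(50))
  l0 <- sleep_latency(hypnogram(base))$latency_s
  for (k in c(1, 7, 20)) {
    lk <- sleep_latency(hypnogram(c(rep("W", k), base)))$latency_s
    expect_equal(lk, l0 + 8 * k)
  }
})

test_that("latency agrees with the brute-force scan on random inputs", {
  withr::local_seed(27)
  for (i in 1:200) {
    stx <- random_states(sample(30:400, 1), prob = c(0.3, 0.6, 0.1))
    lat <- sleep_latency(hypnogram(stx))
    expect_equal(lat$latency_s, bf_latency(stx))
  }
})

test_that("hourly profiles normalize NREM-delta within the animal", {
  n <- 4 * 450 # 4 h
  st <- rep(rep(c("N", "W"), c(40, 5)), length.out = n)
  delta <- rep(5, n)
  delta[floor((0:(n - 1)) * 8 / 3600) == 2] <- 10 # doubled in hour 2
  series <- make_series(rep(1, n), rep(4, n), delta)
  hyp <- hypnogram(st)
  hp <- hourly_profiles(hyp, series, ref_window = c(0, 4 * 3600))
  expect_equal(nrow(hp), 4)
  expect_equal(hp$wake_s + hp$nrem_s + hp$rem_s, rep(3600, 4))
  expect_equal(hp$nrem_delta_rel[3] / hp$nrem_delta_rel[1], 2, tolerance = 1e-9)
  expect_equal(hp$rem_cum_s, cumsum(hp$rem_s))

  # constant delta: exactly 1.0 every defined hour
  s2 <- make_series(rep(1, n), rep(4, n), rep(5, n))
  hp2 <- hourly_profiles(hyp, s2, ref_window = c(0, 4 * 3600))
  expect_equal(hp2$nrem_delta_rel, rep(1, 4))

  # an all-wake hour has undefined NREM-delta
  st3 <- c(rep("W", 450), rep("N", 450))
  s3 <- make_series(rep(1, 900), rep(4, 900), rep(5, 900))
  hp3 <- hourly_profiles(hypnogram(st3), s3, ref_window = c(0, 7200))
  expect_true(is.na(hp3$nrem_delta_rel[1]))
  expect_false(is.na(hp3$nrem_delta_rel[2]))

  expect_error(hourly_profiles(hypnogram(st3), s2), "different epoch grids")
})

test_that("architecture summaries hold their conservation invariants", {
  withr::local_seed(28)
  for (i in 1:25) {
    n <- 2 * 450
    st <- random_states(n)
    hyp <- hypnogram(st)
    summ <- summarize_architecture(
      hyp, windows = list(h1 = c(0, 3600), h2 = c(3600, 7200))
    )
    for (w in names(summ$windows)) {
      wl <- summ$windows[[w]]
      expect_equal(sum(wl$totals$seconds), 3600)
      for (s in c("W", "N", "R")) {
        expect_equal(sum(wl$bouts[[s]]$count),
                     wl$episode_counts$count[wl$episode_counts$state == s])
      }
    }
    # transitions across both windows sum to episodes - 1
    tot_trans <- sum(vapply(summ$windows,
                            function(wl) sum(wl$transitions$count), numeric(1)))
    expect_equal(tot_trans, nrow(consolidate_episodes(hyp)) - 1)
  }
})

test_that("degenerate single-state summaries are consistent", {
  hyp <- hypnogram(rep("W", 450))
  summ <- summarize_architecture(hyp)
  wl <- summ$windows[[1]]
  expect_equal(wl$totals$seconds[wl$totals$state == "W"], 3600)
  expect_equal(wl$episode_counts$count,
               c(1L, 0L, 0L))
  expect_true(all(wl$transitions$count == 0))
  expect_equal(wl$nrem_interruptions, 0L)
  expect_true(summ$latency$censored)
})

test_that("tidied summaries produce one long row per metric", {
  d <- quick_design(duration_h = 2, seed = 29)
  truth <- sample_hypnogram(d)
  summ <- summarize_architecture(truth$hypnogram,
                                 windows = list(light = c(0, 7200)))
  td <- tidy(summ)
  expect_true(all(c("animal_id", "window", "metric", "value", "censored")
                  %in% names(td)))
  expect_equal(sum(td$metric == "latency_s"), 1)
  expect_equal(td$value[td$metric == "total_W" & td$window == "light"] +
                 td$value[td$metric == "total_N" & td$window == "light"] +
                 td$value[td$metric == "total_R" & td$window == "light"], 7200)
  g <- glance(summ)
  expect_equal(nrow(g), 1)
})
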