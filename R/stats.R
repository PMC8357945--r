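#' Group summary (mean, SEM, n)
#'
#' @param data A data frame.
#' @param value Column with the response (tidy-eval).
#' @param ... Grouping columns (tidy-eval).
#' @return Tibble with `mean`, `sem`, `n` per group.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 4), y = rnorm(8))
#' group_summary(df, y, g)
group_summary <- function(data, value, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      mean = mean({{ value }}, na.rm = TRUE),
      sem = sd({{ value }}, na.rm = TRUE) / sqrt(sum(!is.na({{ value }}))),
      n = sum(!is.na({{ value }})),
      .groups = "drop"
    )
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' Classical one-way analysis of variance across groups followed by Tukey's
#' honestly-significant-difference pairwise comparisons on the studentized
#' range distribution. When the response has zero total variance no test is
#' possible and the result carries `no_test = TRUE`.
#'
#' @param data A data frame with one row per animal.
#' @param value Response column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param alpha Significance level for the `significant` flags (default 0.05).
#' @return A `psg_anova` object: `effects` (term, df, sumsq, statistic,
#'   p.value), `contrasts` (Tukey pairwise tibble), `method`, `no_test`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 5),
#'                  y = rnorm(15) + rep(c(0, 0, 2), each = 5))
#' fit <- anova_oneway_tukey(df, y, g)
#' tidy(fit)
anova_oneway_tukey <- function(data, value, group, alpha = 0.05) {
  df <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    g = factor(dplyr::pull(data, {{ group }}))
  )
  df <- df[complete.cases(df), ]
  tab <- table(df$g)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("one-way ANOVA needs >= 2 groups with n >= 2 each; got cells: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
         call. = FALSE)
  }
  if (sd(df$y) < .Machine$double.eps^0.5 * (1 + abs(mean(df$y)))) {
    return(structure(
      list(effects = NULL, contrasts = NULL, method = "one_way_tukey",
           no_test = TRUE, alpha = alpha),
      class = "psg_anova"
    ))
  }
  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  effects <- tibble::tibble(
    term = c("group", "Residuals"),
    df = s[["Df"]],
    sumsq = s[["Sum Sq"]],
    statistic = s[["F value"]],
    p.value = s[["Pr(>F)"]]
  )
  tk <- TukeyHSD(fit)$g
  contrasts <- tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  structure(
    list(effects = effects, contrasts = contrasts,
         method = "one_way_tukey", no_test = FALSE, alpha = alpha),
    class = "psg_anova"
  )
}

#' Two-way ANOVA with Bonferroni-corrected cell contrasts
#'
#' Fits the handling x treatment factorial, reports Type-II sums of squares
#' for the two main effects and the interaction, and computes the planned
#' cell contrasts — pairwise treatment comparisons within each handling
#' level and pairwise handling comparisons within each treatment level —
#' with Bonferroni adjustment (each p multiplied by the number of contrasts
#' in its family, capped at 1).
#'
#' @param data A data frame with one row per animal.
#' @param value Response column (tidy-eval).
#' @param handling,treatment Factor columns (tidy-eval).
#' @param alpha Significance level for the `significant` flags.
#' @return A `psg_anova` object with `effects` and `contrasts` tibbles.
#' @export
anova_twoway_bonferroni <- function(data, value, handling, treatment,
                                    alpha = 0.05) {
  df <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    handling = factor(dplyr::pull(data, {{ handling }})),
    treatment = factor(dplyr::pull(data, {{ treatment }}))
  )
  df <- df[complete.cases(df), ]
  cells <- table(df$handling, df$treatment)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "), call. = FALSE)
  }
  fit <- lm(y ~ handling * treatment, data = df)
  a2 <- car::Anova(fit, type = 2)
  effects <- tibble::tibble(
    term = rownames(a2)[seq_len(nrow(a2))],
    df = a2[["Df"]],
    sumsq = a2[["Sum Sq"]],
    statistic = a2[["F value"]],
    p.value = a2[["Pr(>F)"]]
  )
  contrasts <- dplyr::bind_rows(
    emmeans_pairs(fit, "treatment", "handling"),
    emmeans_pairs(fit, "handling", "treatment")
  )
  contrasts$significant <- contrasts$adj.p.value < alpha
  structure(
    list(effects = effects, contrasts = contrasts,
         method = "two_way_bonferroni", no_test = FALSE, alpha = alpha),
    class = "psg_anova"
  )
}

emmeans_pairs <- function(fit, primary, by) {
  if (length(unique(fit$model[[primary]])) < 2) return(NULL)
  em <- emmeans::emmeans(fit, primary, by = by)
  pr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "bonferroni"))
  tibble::tibble(
    contrast = paste0(pr$contrast, " | ", by, "=", pr[[by]]),
    estimate = pr$estimate,
    adj.p.value = pr$p.value
  )
}

#' @export
print.psg_anova <- function(x, ...) {
  cat("<psg_anova>", x$method, "\n")
  if (isTRUE(x$no_test)) {
    cat("  zero total variance: no test performed\n")
    return(invisible(x))
  }
  print(x$effects)
  invisible(x)
}

#' @describeIn anova_oneway_tukey Tidy the effect table (or the contrasts
#'   with `type = "contrasts"`).
#' @param x A `psg_anova`.
#' @param type `"effects"` or `"contrasts"`.
#' @param ... Unused.
#' @method tidy psg_anova
#' @export
tidy.psg_anova <- function(x, type = c("effects", "contrasts"), ...) {
  type <- match.arg(type)
  if (isTRUE(x$no_test)) return(tibble::tibble())
  tibble::as_tibble(x[[type]])
}

#' @describeIn anova_oneway_tukey One-row model summary.
#' @method glance psg_anova
#' @export
glance.psg_anova <- function(x, ...) {
  if (isTRUE(x$no_test)) {
    return(tibble::tibble(method = x$method, no_test = TRUE,
                          statistic = NA_real_, p.value = NA_real_))
  }
  main <- x$effects[!x$effects$term %in% "Residuals", ]
  tibble::tibble(
    method = x$method, no_test = FALSE,
    statistic = main$statistic[1], p.value = main$p.value[1]
  )
}

#' Run the cohort statistics layer over a long metric table
#'
#' For each requested (window, metric), fits the two-way ANOVA with
#' Bonferroni contrasts (when both factors vary) or the one-way ANOVA with
#' Tukey HSD (single factor), returning one combined effects table.
#' Censored latencies enter at their substituted value (the recording span);
#' set `drop_censored = TRUE` for the sensitivity re-run that excludes them.
#'
#' @param table Long table from [tidy.psg_architecture()] rows bound over
#'   animals (columns `animal_id`, `handling`, `treatment`, `window`,
#'   `metric`, `value`, `censored`).
#' @param metrics Character vector of metric names to test (default: all).
#' @param windows Character vector of window labels to test (default: all).
#' @param drop_censored Exclude censored values before testing.
#' @param alpha Significance level.
#' @return Tibble of effect rows keyed by `window`, `metric`, `term`.
#' @export
cohort_stats <- function(table, metrics = NULL, windows = NULL,
                         drop_censored = FALSE, alpha = 0.05) {
  if (drop_censored) table <- table[table$censored == 0, ]
  if (is.null(metrics)) metrics <- unique(table$metric)
  if (is.null(windows)) windows <- unique(table$window)
  keys <- table |>
    dplyr::filter(.data$metric %in% metrics, .data$window %in% windows) |>
    dplyr::distinct(.data$window, .data$metric)
  purrr::pmap_dfr(keys, function(window, metric) {
    d <- table[table$window == window & table$metric == metric, ]
    two_factor <- length(unique(d$handling)) > 1 &&
      length(unique(d$treatment)) > 1
    fit <- if (two_factor) {
      anova_twoway_bonferroni(d, value, handling, treatment, alpha = alpha)
    } else if (length(unique(d$handling)) > 1) {
      anova_oneway_tukey(d, value, handling, alpha = alpha)
    } else {
      anova_oneway_tukey(d, value, treatment, alpha = alpha)
    }
    eff <- tidy(fit)
    if (nrow(eff) == 0) return(NULL)
    tibble::tibble(window = window, metric = metric, eff)
  })
}
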