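#' Per-target report accuracy by condition and exposure
#'
#' For each (condition, exposure) cell, the number of correctly reported
#' targets divided by the number of displayed targets. A report is correct
#' when its identity appears among the displayed targets; intrusions do not
#' count. Cells with no trials are absent from the output rather than zero.
#'
#' @param trials A trial table (one observer or pooled, as required).
#' @return Tibble with `condition`, `exposure_ms`, `n_trials`, `accuracy`.
#' @export
per_target_accuracy <- function(trials) {
  rep_chr <- trials$reported
  rep_chr[is.na(rep_chr)] <- ""
  correct <- vapply(seq_len(nrow(trials)), function(r) {
    tchars <- strsplit(trials$displayed_targets[r], "")[[1]]
    rchars <- strsplit(rep_chr[r], "")[[1]]
    sum(!is.na(match(rchars, tchars)))
  }, numeric(1))
  df <- tibble::tibble(condition = trials$condition,
                       exposure_ms = trials$exposure_ms,
                       correct = correct, n_targets = trials$n_targets)
  df |>
    dplyr::group_by(.data$condition, .data$exposure_ms) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     accuracy = sum(.data$correct) / sum(.data$n_targets),
                     .groups = "drop")
}

#' Paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`,
#' with `n - 1` degrees of freedom and a two-sided p value. If every
#' difference is exactly zero the statistic is defined as t = 0, p = 1; zero
#' variance around a nonzero mean is undefined and raises an error.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return List with `t`, `df`, `p`.
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1))
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
  s <- sd(d)
  if (s == 0)
    stop("undefined statistic: paired differences have zero variance",
         call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors of equal length (n >= 3) with nonzero variance.
#' @return List with `r`, `df`, `p` (two-sided, via the t transform with
#'   n - 2 df).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined statistic: zero variance", call. = FALSE)
  n <- length(x)
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, df = n - 2, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, df = n - 2, p = 2 * pt(-abs(t), n - 2))
}

#' Congruence-contrast report
#'
#' The study's headline tables: per group and parameter, the mean (sd) of
#' the per-observer estimates in the congruent and incongruent conditions
#' and a paired t test on the within-observer congruence difference; a
#' matched-pairs difference-of-differences test comparing the synesthetes'
#' congruence effect with their shadowed controls'; and, when trials are
#' supplied, per-target accuracy congruence deltas in percentage points
#' (accuracies pooled with equal cell weighting, matching the balanced
#' design).
#'
#' @param fits Tibble from [fit_cohort()] (or equivalent) with columns
#'   `observer`, `group`, `pair`, `condition` and the four parameters
#'   `t0`, `C`, `K`, `alpha`; both conditions must be present for every
#'   observer.
#' @param trials Optional trial table for the accuracy contrast.
#' @return List of tibbles: `table1` (group x parameter x condition means,
#'   sds, paired t, df, p), `dod` (difference-of-differences tests) and
#'   `accuracy` (per-group accuracy deltas, percentage points), or NULL when
#'   trials are not supplied.
#' @export
congruence_contrast_report <- function(fits, trials = NULL) {
  pars <- c("t0", "C", "K", "alpha")
  need <- c("observer", "group", "pair", "condition", pars)
  stopifnot(all(need %in% names(fits)))
  wide <- tidyr::pivot_wider(fits[, need], names_from = "condition",
                             values_from = dplyr::all_of(pars))
  if (anyNA(wide) || !all(table(fits$observer) == 2))
    stop("both conditions must be fitted for every observer", call. = FALSE)
  groups <- unique(wide$group)
  table1 <- list()
  for (g in groups) {
    sub <- wide[wide$group == g, ]
    sub <- sub[order(sub$pair), ]
    for (p in pars) {
      co <- sub[[paste0(p, "_congruent")]]
      inc <- sub[[paste0(p, "_incongruent")]]
      tt <- paired_t(co, inc)
      table1[[length(table1) + 1L]] <- tibble::tibble(
        group = g, parameter = p,
        mean_congruent = mean(co), sd_congruent = sd(co),
        mean_incongruent = mean(inc), sd_incongruent = sd(inc),
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  table1 <- dplyr::bind_rows(table1)

  dod <- NULL
  if (all(c("synesthete", "control") %in% groups)) {
    syn <- wide[wide$group == "synesthete", ]
    ctl <- wide[wide$group == "control", ]
    if (!setequal(syn$pair, ctl$pair))
      stop("unmatched observer pairs between groups", call. = FALSE)
    syn <- syn[order(syn$pair), ]
    ctl <- ctl[order(ctl$pair), ]
    dod <- dplyr::bind_rows(lapply(pars, function(p) {
      ds <- syn[[paste0(p, "_congruent")]] - syn[[paste0(p, "_incongruent")]]
      dc <- ctl[[paste0(p, "_congruent")]] - ctl[[paste0(p, "_incongruent")]]
      tt <- paired_t(ds, dc)
      tibble::tibble(parameter = p, mean_syn_delta = mean(ds),
                     mean_ctrl_delta = mean(dc), t = tt$t, df = tt$df,
                     p = tt$p)
    }))
  }

  accuracy <- NULL
  if (!is.null(trials)) {
    acc <- trials |>
      dplyr::group_by(.data$observer, .data$group, .data$pair) |>
      dplyr::group_modify(function(d, key) {
        a <- per_target_accuracy(d)
        # equal cell weighting over exposures
        a |>
          dplyr::group_by(.data$condition) |>
          dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
      }) |>
      dplyr::ungroup()
    accw <- tidyr::pivot_wider(acc, names_from = "condition",
                               values_from = "accuracy")
    accuracy <- accw |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(function(d, key) {
        tt <- paired_t(d$congruent, d$incongruent)
        tibble::tibble(
          delta_pp = 100 * mean(d$congruent - d$incongruent),
          t = tt$t, df = tt$df, p = tt$p)
      }) |>
      dplyr::ungroup()
  }
  list(table1 = table1, dod = dod, accuracy = accuracy)
}
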