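test_that("paired t matches the textbook formula and the reference oracle", {
  r <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # x = y: defined as a null result
  expect_equal(paired_t(1:5, 1:5), list(t = 0, df = 4, p = 1))
  # zero variance around a nonzero mean is undefined
  expect_error(paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  # antisymmetry
  set.seed(12)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(paired_t(x, y)$t, -paired_t(y, x)$t)
  # reference implementation
  tt <- stats::t.test(x, y, paired = TRUE)
  r <- paired_t(x, y)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
})

test_that("Pearson correlation matches the reference oracle", {
  x <- c(0.2, 1.4, 2.2, 3.1, 4.7, 5.0, 6.3, 7.1, 8.8)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  set.seed(13)
  y <- rnorm(9)
  ct <- stats::cor.test(x, y)
  r <- pearson_correlation(x, y)
  expect_equal(r$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(r$p, ct$p.value, tolerance = 1e-10)
  expect_equal(r$df, unname(ct$parameter))
  expect_error(pearson_correlation(rep(1, 5), y[1:5]), "zero variance")
  # independent noise at large n is near zero
  set.seed(14)
  big <- pearson_correlation(rnorm(5000), rnorm(5000))
  expect_lt(abs(big$r), 0.05)
})

test_that("per-target accuracy counts correct reports over displayed targets", {
  tr <- rbind(one_trial(roles = "TTTTTT", targets = "ABCDEF", reported = "ABCDEF"),
              one_trial(roles = "TTDTTD", targets = "GHIJ", distractors = "12",
                        reported = "GH"))
  acc <- per_target_accuracy(tr)
  expect_equal(acc$accuracy[acc$exposure_ms == 80], (6 + 2) / (6 + 4))
  # all-empty reports give zero, intrusions do not count
  tr$reported <- c("", "99")
  acc0 <- per_target_accuracy(tr)
  expect_equal(acc0$accuracy, 0)
  # simulated observer tracks the model's expected score curve
  p <- ref_params()
  d <- display_config("TTTTTT", 50)
  set.seed(15)
  counts <- simulate_display_reports(p, d, 2e4)
  sizes <- ifelse(names(counts) == "-", 0L,
                  lengths(strsplit(names(counts), ",")))
  emp <- sum(sizes * counts) / (6 * sum(counts))
  model <- expected_score_curve(p, d, 50)$expected_score / 6
  expect_equal(emp, model, tolerance = 3 * sqrt(0.25 / (6 * 2e4)) / model)
})

make_fits <- function(effect_C = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("synesthete", "control"))
    for (i in 1:9)
      for (cond in c("congruent", "incongruent")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          observer = paste0(substr(g, 1, 1), i), group = g, pair = i,
          condition = cond,
          t0 = rnorm(1, 11, 2), C = rnorm(1, 90, 8) +
            if (g == "synesthete" && cond == "congruent") effect_C else 0,
          K = rnorm(1, 3.5, 0.2), alpha = rnorm(1, 0.5, 0.05))
      }
  dplyr::bind_rows(rows)
}

test_that("the congruence report reproduces the table structure and group means", {
  fits <- make_fits(effect_C = 25)
  rep <- congruence_contrast_report(fits)
  expect_equal(nrow(rep$table1), 2 * 4)
  expect_setequal(rep$table1$parameter, c("t0", "C", "K", "alpha"))
  expect_true(all(rep$table1$df == 8))
  # group means are plain arithmetic means of the per-observer values
  syn_C <- fits$C[fits$group == "synesthete" & fits$condition == "congruent"]
  expect_equal(rep$table1$mean_congruent[rep$table1$group == "synesthete" &
                                           rep$table1$parameter == "C"],
               mean(syn_C))
  # the injected C effect is picked up by the difference-of-differences test
  expect_lt(rep$dod$p[rep$dod$parameter == "C"], 0.05)
  # reruns are identical
  expect_identical(congruence_contrast_report(fits), rep)
  # unmatched pairs are an error
  bad <- fits[!(fits$group == "control" & fits$pair == 9), ]
  bad$pair[bad$group == "control" & bad$pair == 8] <- 9
  expect_error(congruence_contrast_report(bad))
})

test_that("accuracy deltas are reported per group in percentage points", {
  sim <- simulate_group(group_spec(n_pairs = 2, delta_C = 40, delta_K = 0.4,
                                   seed = 6))
  fits <- make_fits()[make_fits()$pair <= 2, ]
  fits <- fits[fits$pair <= 2, ]
  fits$observer <- paste0(substr(fits$group, 1, 1) == "s", fits$pair)
  fits$observer <- ifelse(fits$group == "synesthete",
                          sprintf("S%02d", fits$pair),
                          sprintf("C%02d", fits$pair))
  rep <- congruence_contrast_report(fits, trials = sim$trials)
  expect_setequal(rep$accuracy$group, c("synesthete", "control"))
  # the synthetic synesthetes got a big congruent boost
  dsyn <- rep$accuracy$delta_pp[rep$accuracy$group == "synesthete"]
  expect_gt(dsyn, 0)
})
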