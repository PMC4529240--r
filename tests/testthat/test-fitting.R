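test_that("negative log-likelihood is additive and agrees with the per-trial route", {
  tr <- one_trial(reported = "")
  pl <- ref_params(p_lapse = 1)
  expect_equal(as.numeric(negative_log_likelihood(pl, tr)), 0)

  set.seed(77)
  spec <- group_spec(n_pairs = 1, delta_C = 0, delta_K = 0, seed = 5)
  sim <- simulate_group(spec)
  tr <- head(sim$trials[sim$trials$observer == "S01" &
                          sim$trials$condition == "congruent", ], 100)
  p <- ref_params()
  nll <- negative_log_likelihood(p, tr)
  # doubling the data doubles the objective
  expect_equal(as.numeric(negative_log_likelihood(p, rbind(tr, tr))),
               2 * as.numeric(nll))
  # kernel route vs the R report_distribution route, trial by trial
  by_hand <- sum(vapply(seq_len(nrow(tr)), function(r) {
    d <- display_config(tr$location_roles[r], tr$exposure_ms[r])
    tl <- which(d$roles == "target")
    tchars <- strsplit(tr$displayed_targets[r], "")[[1]]
    rchars <- strsplit(tr$reported[r], "")[[1]]
    locs <- tl[match(rchars, tchars)]
    -log(report_set_likelihood(p, d, locs))
  }, numeric(1)))
  expect_equal(as.numeric(nll), by_hand, tolerance = 1e-10)
  expect_error(negative_log_likelihood(p, tr[0, ]), "empty")
})

test_that("likelihood matches a Monte-Carlo likelihood oracle", {
  set.seed(88)
  spec <- group_spec(n_pairs = 1, delta_C = 0, delta_K = 0, seed = 5)
  sim <- simulate_group(spec)
  tr <- head(sim$trials[sim$trials$observer == "S01" &
                          sim$trials$condition == "congruent" &
                          sim$trials$exposure_ms >= 30, ], 12)
  p <- ref_params()
  n_mc <- 2e5
  ll_exact <- 0
  ll_mc <- 0
  for (r in seq_len(nrow(tr))) {
    d <- display_config(tr$location_roles[r], tr$exposure_ms[r])
    tl <- which(d$roles == "target")
    tchars <- strsplit(tr$displayed_targets[r], "")[[1]]
    rchars <- strsplit(tr$reported[r], "")[[1]]
    locs <- tl[match(rchars, tchars)]
    lab <- if (length(locs) == 0) "-" else paste(sort(locs), collapse = ",")
    counts <- simulate_display_reports(p, d, n_mc)
    ll_mc <- ll_mc + log(max(counts[[lab]], 0.5) / n_mc)
    ll_exact <- ll_exact + log(report_set_likelihood(p, d, locs))
  }
  expect_equal(ll_mc, ll_exact, tolerance = 0.005)
})

test_that("fits are deterministic, order-invariant and improve with restarts", {
  spec <- group_spec(n_pairs = 1, delta_C = 0, delta_K = 0, seed = 9)
  sim <- simulate_group(spec)
  tr <- sim$trials[sim$trials$observer == "S01" &
                     sim$trials$condition == "congruent", ]
  cfg <- fit_config(seed = 3, restarts = 1, quad_nodes = 8, maxit = 120,
                    polish_maxit = 120)
  f1 <- fit_observer(tr, cfg)
  f2 <- fit_observer(tr, cfg)
  expect_identical(f1$summaries, f2$summaries)
  expect_identical(f1$nll, f2$nll)
  # shuffling trials changes nothing
  set.seed(1)
  f3 <- fit_observer(tr[sample(nrow(tr)), ], cfg)
  expect_equal(f3$summaries, f1$summaries, tolerance = 1e-10)
  # more restarts can only improve the returned objective
  cfg4 <- cfg; cfg4$restarts <- 4
  f4 <- fit_observer(tr, cfg4)
  expect_lte(f4$nll, f1$nll)
})

test_that("degenerate all-empty data drives the fit to a flagged boundary", {
  spec <- group_spec(n_pairs = 1, delta_C = 0, delta_K = 0, seed = 9)
  sim <- simulate_group(spec)
  tr <- sim$trials[sim$trials$observer == "S01" &
                     sim$trials$condition == "congruent", ]
  tr$reported <- ""
  cfg <- fit_config(seed = 3, restarts = 1, quad_nodes = 8, maxit = 250,
                    polish_maxit = 250)
  fit <- fit_observer(tr, cfg)
  # no report at any exposure: lapse heads to 1 and/or threshold exceeds the
  # longest exposure
  expect_true(fit$params$p_lapse > 0.9 || fit$params$mu_t0 > 150 ||
                fit$status == "boundary")
})

test_that("alpha is fixed at 1 when the data contain no distractor trials", {
  spec <- group_spec(n_pairs = 1, delta_C = 0, delta_K = 0, seed = 9)
  sim <- simulate_group(spec)
  tr <- sim$trials[sim$trials$observer == "S01" &
                     sim$trials$condition == "congruent" &
                     sim$trials$n_distractors == 0, ]
  cfg <- fit_config(seed = 3, restarts = 1, quad_nodes = 8, maxit = 120,
                    polish_maxit = 120)
  fit <- suppressWarnings(fit_observer(tr, cfg))  # 180 trials: small-n warning
  expect_true(fit$alpha_fixed)
  expect_equal(fit$summaries$alpha, 1)
})

test_that("derived summaries reduce the capacity distribution to its mean", {
  p4 <- ref_params(pK = c(0, 0, 0, 1, 0, 0))
  expect_equal(derive_summaries(p4)$K, 4)
  pu <- ref_params(pK = rep(1 / 6, 6))
  expect_equal(derive_summaries(pu)$K, 3.5)
  expect_equal(derive_summaries(ref_params(C = 93))$C, 93)
})

test_that("fit_observer rejects mixed observers and warns on tiny samples", {
  t1 <- one_trial(observer = "S01")
  t2 <- one_trial(observer = "S02")
  expect_error(fit_observer(rbind(t1, t2)), "single observer")
  cfg <- fit_config(restarts = 1, quad_nodes = 8, maxit = 5, polish_maxit = 5)
  expect_warning(fit_observer(rbind(t1, t1, t1), cfg), "200 trials")
})
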