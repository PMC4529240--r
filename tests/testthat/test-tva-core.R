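test_that("element rates split C by attentional weight and role", {
  p <- ref_params(C = 60, alpha = 0.5)
  v <- element_rates(p, display_config("TTTTTT", 80))
  expect_equal(v, rep(10, 6))

  d <- display_config("TTTDDD", 80)
  v <- element_rates(p, d)
  expect_equal(v[1:3], rep(2 * 60 / 9, 3))
  expect_equal(v[4:6], rep(60 / 9, 3))
  expect_equal(sum(v), 60)

  p0 <- ref_params(alpha = 0)
  v0 <- element_rates(p0, d)
  expect_equal(v0[4:6], rep(0, 3))
  expect_equal(sum(v0[1:3]), p0$C)

  pz <- ref_params(w = c(0, 0, 0, 1, 1, 1))
  expect_error(element_rates(pz, display_config("TTTEEE", 80)), "degenerate")
})

test_that("hypoexponential CDF matches closed forms and a convolution oracle", {
  expect_equal(hypoexp_cdf(5, 0.2), 1 - exp(-1), tolerance = 1e-12)
  # Erlang-2 with equal rates
  expect_equal(hypoexp_cdf(c(4, 4), 0.3), 1 - exp(-1.2) * (1 + 1.2),
               tolerance = 1e-12)
  # distinct rates against numerical convolution
  expect_equal(hypoexp_cdf(c(3, 5, 7), 0.4), conv3_cdf(c(3, 5, 7), 0.4),
               tolerance = 1e-8)
  # near-equal rates: stable branch agrees with the nearby Erlang
  near <- hypoexp_cdf(c(5, 5 * (1 + 1e-8), 5), 0.4)
  expect_equal(near, stats::pgamma(0.4, 3, rate = 5), tolerance = 1e-6)
  # nondecreasing in tau, bounded in [0, 1]
  taus <- seq(0, 1, by = 0.05)
  vals <- hypoexp_cdf(c(3, 5, 7), taus)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(hypoexp_cdf(c(3, -1), 0.1), "positive")
})

test_that("encoding-set distribution has its closed-form limits", {
  # single element with v*tau = ln 2 and k = 1
  e <- encoding_set_distribution(log(2) / 0.05, 0.05, k = 1)
  expect_equal(unname(e["-"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(e["1"]), 0.5, tolerance = 1e-12)
  # one element, k = 1: P(encoded) = 1 - exp(-C tau) exactly
  expect_equal(unname(encoding_set_distribution(80, 0.03, 1)["1"]),
               1 - exp(-80 * 0.03), tolerance = 1e-12)
  # two equal racers, k = 1, effectively infinite exposure
  e2 <- encoding_set_distribution(c(10, 10), 1e3, k = 1)
  expect_equal(unname(e2["1"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(e2["2"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(e2["-"]), 0, tolerance = 1e-9)
  expect_equal(unname(e2["1,2"]), 0)
  # zero-rate elements are never encoded
  e3 <- encoding_set_distribution(c(10, 0), 0.1, k = 2)
  expect_equal(unname(e3["2"]), 0)
  expect_equal(unname(e3["1,2"]), 0)
  expect_error(encoding_set_distribution(c(10, 10), -0.1, 1), "tau")
})

test_that("encoding-set distribution sums to 1 and matches the ordering-sum oracle", {
  rates <- c(20, 15, 10, 8, 5, 2)
  for (k in 1:6) {
    for (tau in c(0.01, 0.05, 0.15)) {
      e <- encoding_set_distribution(rates, tau, k)
      expect_equal(sum(e), 1, tolerance = 1e-9)
      expect_true(all(e >= -1e-15))
      # oracle check on every full-store set
      sizes <- ifelse(names(e) == "-", 0L, lengths(strsplit(names(e), ",")))
      full <- which(sizes == k)
      for (i in full) {
        S <- as.integer(strsplit(names(e)[i], ",")[[1]])
        expect_equal(unname(e[i]), ordering_sum_oracle(rates, tau, S),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("encoding-set distribution is equivariant under relabeling", {
  rates <- c(20, 15, 10, 8, 5, 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  e1 <- encoding_set_distribution(rates, 0.08, 4)
  e2 <- encoding_set_distribution(rates[perm], 0.08, 4)
  # element j of the permuted rate vector carries the rate of element perm[j]
  relabel <- function(nm) {
    if (nm == "-") return("-")
    paste(sort(perm[as.integer(strsplit(nm, ",")[[1]])]), collapse = ",")
  }
  # probability of S under permuted rates = probability of mapped set
  for (nm in names(e2)) {
    mapped <- relabel(nm)
    expect_equal(unname(e2[nm]), unname(e1[mapped]), tolerance = 1e-12)
  }
})

test_that("encoding-set distribution matches a Monte-Carlo race", {
  set.seed(401)
  rates <- c(20, 15, 10, 8, 5, 2)
  n <- 1e5
  emp <- mc_race_oracle(rates, 0.08, k = 4, n = n)
  e <- encoding_set_distribution(rates, 0.08, 4)
  se <- sqrt(e * (1 - e) / n)
  z <- (as.numeric(emp) - e) / pmax(se, 1e-12)
  expect_lt(max(abs(z[e > 5 / n])), 4)
})

test_that("report likelihood handles the lapse and sub-threshold boundaries", {
  d <- display_config("TTDTTD", 50)
  pl <- ref_params(p_lapse = 1)
  expect_equal(report_set_likelihood(pl, d, integer(0)), 1)
  expect_equal(report_set_likelihood(pl, d, c(1, 2)), 0)
  # exposure entirely below threshold: nothing is ever encoded
  ps <- ref_params(mu_t0 = 15, sigma_t0 = 0.1, p_lapse = 0)
  d10 <- display_config("TTDTTD", 10)
  expect_equal(report_set_likelihood(ps, d10, integer(0)), 1, tolerance = 1e-12)
  expect_error(report_set_likelihood(ref_params(), d, 3), "not targets")
})

test_that("report distribution is normalized and P(empty) falls with exposure", {
  p <- ref_params()
  for (roles in c("TTTTTT", "TTDTTD", "TDTDTD")) {
    rd <- report_distribution(p, display_config(roles, 50))
    expect_equal(sum(rd), 1, tolerance = 1e-8)
  }
  p_empty <- vapply(c(10, 20, 30, 50, 80, 150), function(e) {
    unname(report_distribution(p, display_config("TTDTTD", e))["-"])
  }, numeric(1))
  expect_true(all(diff(p_empty) <= 1e-12))
})

test_that("expected score curve has the threshold intercept, slope C and capacity asymptote", {
  d6 <- display_config("TTTTTT", 80)
  # asymptote: point-mass capacity 4, no lapse
  p4 <- ref_params(pK = c(0, 0, 0, 1, 0, 0), p_lapse = 0, C = 200)
  sc <- expected_score_curve(p4, d6, c(500, 2000))
  expect_equal(sc$expected_score[2], 4, tolerance = 1e-6)
  # intercept: at the threshold itself the expected score is ~0 (the tiny
  # residual is the sub-millisecond threshold spread)
  p0 <- ref_params(mu_t0 = 15, sigma_t0 = 1e-3, p_lapse = 0)
  sc0 <- expected_score_curve(p0, d6, 15)
  expect_lt(sc0$expected_score, 1e-3)
  # initial slope equals C (numerical derivative just above threshold)
  pC <- ref_params(mu_t0 = 15, sigma_t0 = 1e-3, C = 80, p_lapse = 0)
  dt <- 0.2
  sl <- expected_score_curve(pC, d6, 15 + dt)$expected_score / (dt / 1000)
  expect_equal(sl, pC$C, tolerance = 0.02 * pC$C)
  # monotone in duration
  sc2 <- expected_score_curve(ref_params(), d6, c(10, 20, 30, 50, 80, 150))
  expect_true(all(diff(sc2$expected_score) >= 0))
})
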