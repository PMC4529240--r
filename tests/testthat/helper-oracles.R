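# Independent oracles for the race probabilities.

# Ordering-sum oracle: P(first |S| finishers are exactly S and the last of
# them finishes by tau), summed over all orderings of S. Stage j of an
# ordering is a race among all still-unfinished elements, so its rate is the
# total rate minus the rates already finished; the k-th finish time is then
# hypoexponential in the stage rates. Exponentially slower than the
# package's inclusion-exclusion route, and independent of it.
ordering_sum_oracle <- function(rates, tau, S) {
  total <- sum(rates)
  k <- length(S)
  orders <- if (k == 1) matrix(S, 1) else pracma::perms(S)
  p <- 0
  for (i in seq_len(nrow(orders))) {
    ord <- orders[i, ]
    stage_rates <- total - cumsum(c(0, rates[ord[-k]]))
    sel <- prod(rates[ord] / stage_rates)
    p <- p + sel * hypoexp_cdf(stage_rates, tau)
  }
  p
}

# Brute-force Monte-Carlo race: independent exponential finish times,
# encoded = among first k finishers and within tau.
mc_race_oracle <- function(rates, tau, k, n) {
  m <- length(rates)
  tm <- matrix(Inf, n, m)
  for (j in seq_len(m)) if (rates[j] > 0) tm[, j] <- rexp(n, rates[j])
  keys <- apply(tm, 1, function(x) {
    o <- order(x)[seq_len(min(k, m))]
    enc <- o[x[o] <= tau]
    paste(sort(enc), collapse = ",")
  })
  lv <- vapply(0:(2^m - 1L), function(mask) {
    paste(which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L), collapse = ",")
  }, character(1))
  table(factor(keys, levels = lv)) / n
}

# numerical convolution CDF of a sum of three independent exponentials
conv3_cdf <- function(r, tau) {
  inner <- function(s) {
    if (s <= 0) return(0)
    stats::integrate(function(y) {
      stats::dexp(y, r[2]) * stats::pexp(s - y, r[3])
    }, 0, s, rel.tol = 1e-11)$value
  }
  stats::integrate(function(x) {
    stats::dexp(x, r[1]) * vapply(tau - x, inner, numeric(1))
  }, 0, tau, rel.tol = 1e-10)$value
}

# small standard parameter set used across tests
ref_params <- function(...) {
  args <- list(mu_t0 = 12, sigma_t0 = 4, C = 80, alpha = 0.5,
               pK = c(0, 0.1, 0.3, 0.4, 0.15, 0.05), p_lapse = 0.02)
  args[names(list(...))] <- list(...)
  do.call(tva_params, args)
}

# minimal trial table wrapping a single display + report, for likelihood
# bookkeeping tests
one_trial <- function(roles = "TTTTTT", exposure = 80, targets = "ABCDEF",
                      distractors = "", reported = "",
                      observer = "S01", condition = "congruent") {
  tibble::tibble(observer = observer, group = "synesthete", condition = condition,
                 block = 1, trial_index = 1, exposure_ms = exposure,
                 n_targets = sum(strsplit(roles, "")[[1]] == "T"),
                 n_distractors = sum(strsplit(roles, "")[[1]] == "D"),
                 location_roles = roles, displayed_targets = targets,
                 displayed_distractors = distractors, reported = reported)
}
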