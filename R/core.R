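#' Per-location processing rates
#'
#' The race model distributes the total processing rate `C` over the occupied
#' display locations in proportion to their attentional weights:
#' `v_x = C * u_x / sum(u)`, with `u_x = w_x` for targets, `u_x = alpha * w_x`
#' for distractors and `u_x = 0` for empty locations. Rates therefore sum to
#' `C` whenever every occupied location carries positive weight.
#'
#' @param params A [tva_params()] object.
#' @param display A [display_config()] object.
#' @return Numeric length-6 vector of rates (elements/s); 0 at empty
#'   locations.
#' @examples
#' p <- tva_params(12, 4, C = 60)
#' element_rates(p, display_config("TTTTTT", 80))
#' @export
element_rates <- function(params, display) {
  stopifnot(inherits(params, "tva_params"), inherits(display, "display_config"))
  u <- params$w
  u[display$roles == "distractor"] <- u[display$roles == "distractor"] * params$alpha
  u[display$roles == "empty"] <- 0
  if (sum(u) <= 0)
    stop("degenerate display: all occupied locations have zero attentional weight",
         call. = FALSE)
  params$C * u / sum(u)
}

#' Hypoexponential cumulative distribution function
#'
#' CDF at `tau` of a sum of independent exponential stage durations with the
#' given rates — the distribution of the k-th finish time of the race, where
#' stage j runs at the summed rate of the elements still unfinished. Distinct
#' rates use the partial-fraction expansion; equal rates use the Erlang form;
#' near-equal rates (relative gap below `1e-7`) fall back to a matrix-
#' exponential evaluation of the underlying Markov chain, which is stable
#' where naive partial fractions cancel catastrophically.
#'
#' @param rates Positive stage rates (per second).
#' @param tau Time (seconds), >= 0. May be a vector.
#' @return Probability (or vector of probabilities) in `[0, 1]`.
#' @examples
#' hypoexp_cdf(5, 0.2)               # 1 - exp(-1)
#' hypoexp_cdf(c(3, 5, 7), 0.4)
#' @export
hypoexp_cdf <- function(rates, tau) {
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all stage rates must be positive and finite", call. = FALSE)
  if (any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  k <- length(rates)
  if (k == 1L) return(1 - exp(-rates * tau))
  rng <- diff(range(rates))
  if (rng < 1e-9 * mean(rates))
    return(stats::pgamma(tau, shape = k, rate = mean(rates)))
  gaps <- abs(outer(rates, rates, "-")) / mean(rates)
  diag(gaps) <- Inf
  if (min(gaps) < 1e-7) {
    # transient Markov chain: upper-bidiagonal generator, absorb at stage k+1
    Q <- diag(-rates, k)
    Q[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <- rates[seq_len(k - 1L)]
    vapply(tau, function(t1) {
      P <- as.matrix(Matrix::expm(Q * t1))
      1 - sum(P[1, ])
    }, numeric(1))
  } else {
    coef <- vapply(seq_len(k), function(i) {
      prod(rates[-i] / (rates[-i] - rates[i]))
    }, numeric(1))
    pmin(1, pmax(0, 1 - drop(exp(-outer(tau, rates)) %*% coef)))
  }
}

# Subsets of locations are labelled by comma-separated indices; the empty
# set is labelled "-" (an empty string cannot be used as a vector name).
subset_label <- function(locs) {
  if (length(locs) == 0) "-" else paste(locs, collapse = ",")
}

subset_sizes <- function(labels) {
  ifelse(labels == "-", 0L, lengths(strsplit(labels, ",")))
}

# free/fill pieces of the exact race probability, R implementation mirroring
# the kernel; exported machinery goes through encoding_set_distribution().
race_set_pieces <- function(rates, tau, S) {
  m <- length(rates)
  E <- exp(-rates * tau)
  out_idx <- setdiff(seq_len(m), S)
  pfree <- prod(1 - E[S]) * prod(E[out_idx])
  Q <- sum(rates[out_idx])
  EQ <- prod(E[out_idx])
  fill <- 0
  t <- length(S)
  if (t > 0) {
    for (mask in seq_len(2^t - 1L)) {
      B <- S[which(bitwAnd(mask, 2^(seq_len(t) - 1L)) > 0L)]
      VB <- sum(rates[B])
      if (VB + Q > 0) {
        term <- VB / (VB + Q) * (1 - prod(E[B]) * EQ)
        fill <- fill + (-1)^(length(B) + 1) * term
      }
    }
  }
  list(free = pfree, fill = fill)
}

#' Exact distribution over encoded element sets
#'
#' Each displayed element finishes at an independent exponential time with
#' its rate; an element is encoded iff it finishes within the effective
#' exposure `tau` and is among the first `k` finishers (the store holds `k`
#' items). For sets smaller than `k` the probability is the product of
#' finish/no-finish terms; for sets of size exactly `k` it is the probability
#' that those elements win the race and the k-th finish falls within `tau`.
#' Zero-rate elements are never encoded.
#'
#' @param rates Non-negative per-element rates (per second).
#' @param tau Effective exposure, seconds (>= 0).
#' @param k Capacity, integer in 1..6.
#' @return Named numeric vector of probabilities over element subsets; names
#'   are comma-separated element indices (`"-"` = empty set). Sums to 1.
#' @examples
#' encoding_set_distribution(c(10, 10), tau = 0.05, k = 1)
#' @export
encoding_set_distribution <- function(rates, tau, k) {
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (!(k %in% 1:6)) stop("`k` must be an integer in 1..6", call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  m <- length(rates)
  stopifnot(m >= 1, m <= 6)
  masks <- 0:(2^m - 1L)
  probs <- numeric(length(masks))
  names(probs) <- vapply(masks, function(mask) {
    subset_label(which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L))
  }, character(1))
  for (i in seq_along(masks)) {
    S <- which(bitwAnd(masks[i], 2^(seq_len(m) - 1L)) > 0L)
    s <- length(S)
    if (s > k) next
    pieces <- race_set_pieces(rates, tau, S)
    probs[i] <- if (s < k) pieces$free else pieces$fill
  }
  probs
}

# Gauss-Legendre rule for the normally distributed threshold t0: nodes span
# mu +/- 4 sigma, weights are GL weights times the normal density,
# renormalized (mass beyond 4 sigma ~ 6e-5). Negative effective exposures
# are collapsed to tau = 0. This is the likelihood's only numerical
# approximation.
t0_quadrature <- function(mu_t0, sigma_t0, n_nodes = 24) {
  key <- paste0("gl", n_nodes)
  gl <- .tva_cache[[key]]
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(n_nodes, -1, 1)
    .tva_cache[[key]] <- gl
  }
  a <- mu_t0 - 4 * sigma_t0
  b <- mu_t0 + 4 * sigma_t0
  t0 <- (b - a) / 2 * gl$x + (a + b) / 2
  w <- gl$w * dnorm(t0, mu_t0, sigma_t0) * (b - a) / 2
  list(t0 = t0, w = w / sum(w))
}

tau_nodes <- function(quad, exposure_ms) {
  pmax(0, exposure_ms - quad$t0) / 1000
}

#' Distribution over reported target sets for one display
#'
#' Marginalizes the race over the threshold draw (Gauss-Legendre quadrature),
#' the capacity distribution `pK`, encoded distractor subsets (which occupy
#' store slots silently) and the lapse probability (a lapse yields the empty
#' report). The result is the exact model probability of every possible
#' report.
#'
#' @param params A [tva_params()] object.
#' @param display A [display_config()] object.
#' @param n_nodes Number of quadrature nodes for the threshold integral.
#' @return Named numeric vector over target-location subsets (names are
#'   comma-separated location indices, `"-"` = empty report). Sums to 1.
#' @export
report_distribution <- function(params, display, n_nodes = 24) {
  v <- element_rates(params, display)
  quad <- t0_quadrature(params$mu_t0, params$sigma_t0, n_nodes)
  tau <- tau_nodes(quad, display$exposure_ms)
  p <- cpp_report_dist(v, role_codes(display$roles), tau, quad$w, params$pK)
  tl <- which(display$roles == "target")
  nT <- length(tl)
  names(p) <- vapply(0:(2^nT - 1L), function(mask) {
    subset_label(tl[which(bitwAnd(mask, 2^(seq_len(nT) - 1L)) > 0L)])
  }, character(1))
  p <- (1 - params$p_lapse) * p
  p[1] <- p[1] + params$p_lapse
  p
}

#' Likelihood of one observed report
#'
#' Probability under the model that the observer reports exactly the target
#' locations in `reported` (order-free). See [report_distribution()] for the
#' marginalization.
#'
#' @param params A [tva_params()] object.
#' @param display A [display_config()] object.
#' @param reported Integer vector of reported target locations (subset of the
#'   display's target locations); `integer(0)` for an omitted response.
#' @param n_nodes Quadrature nodes for the threshold integral.
#' @return A probability.
#' @export
report_set_likelihood <- function(params, display, reported, n_nodes = 24) {
  reported <- sort(unique(as.integer(reported)))
  tl <- which(display$roles == "target")
  if (!all(reported %in% tl))
    stop("reported location(s) ", paste(setdiff(reported, tl), collapse = ","),
         " are not targets in this display", call. = FALSE)
  p <- report_distribution(params, display, n_nodes)
  unname(p[subset_label(reported)])
}

#' Expected report score as a function of exposure duration
#'
#' The mean number of correctly reported targets. The curve rises from an
#' x-intercept at the perceptual threshold with initial slope `C` (for a
#' pure-target display) towards an asymptote at the attainable capacity.
#'
#' @param params A [tva_params()] object.
#' @param display_template A [display_config()]; its exposure is ignored.
#' @param durations Exposure durations, ms.
#' @param n_nodes Quadrature nodes.
#' @return A tibble with `duration_ms` and `expected_score`.
#' @export
expected_score_curve <- function(params, display_template, durations,
                                 n_nodes = 24) {
  stopifnot(all(durations > 0))
  score <- vapply(durations, function(d) {
    disp <- display_template
    disp$exposure_ms <- d
    p <- report_distribution(params, disp, n_nodes)
    sum(subset_sizes(names(p)) * p)
  }, numeric(1))
  tibble::tibble(duration_ms = durations, expected_score = score)
}
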