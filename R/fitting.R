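softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

# theta layout (unconstrained scale):
#   mu_t0 | log sigma_t0 | log C | [log alpha] | aw (5, softmax w) |
#   ak (5, softmax pK) | logit lapse
pack_theta <- function(params, fit_alpha) {
  w <- pmax(params$w, 1e-8); w <- w / sum(w)
  pK <- pmax(params$pK, 1e-8); pK <- pK / sum(pK)
  c(params$mu_t0,
    log(params$sigma_t0),
    log(params$C),
    if (fit_alpha) log(max(params$alpha, 1e-6)),
    log(w[2:6] / w[1]),
    log(pK[2:6] / pK[1]),
    qlogis(min(max(params$p_lapse, 1e-4), 0.5)))
}

unpack_theta <- function(theta, fit_alpha) {
  i <- 3L
  alpha <- 1
  if (fit_alpha) { i <- i + 1L; alpha <- exp(theta[4]) }
  list(mu_t0 = theta[1],
       sigma_t0 = exp(theta[2]),
       C = exp(theta[3]),
       alpha = alpha,
       w = softmax(c(0, theta[(i + 1):(i + 5)])),
       pK = softmax(c(0, theta[(i + 6):(i + 10)])),
       p_lapse = plogis(theta[i + 11]))
}

# Collapse a trial table to unique (layout, exposure, report) combinations
# with counts; reported identities are matched to displayed targets by
# identity (position-free). Unmatched reports (intrusions) are dropped from
# the likelihood and counted.
prepare_trials <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  roles_list <- strsplit(trials$location_roles, "")
  rep_chr <- trials$reported
  rep_chr[is.na(rep_chr)] <- ""
  n <- nrow(trials)
  repmask <- integer(n)
  intrusions <- 0L
  for (r in seq_len(n)) {
    tl <- which(roles_list[[r]] == "T")
    tchars <- strsplit(trials$displayed_targets[r], "")[[1]]
    rchars <- strsplit(rep_chr[r], "")[[1]]
    hit <- match(rchars, tchars)
    intrusions <- intrusions + sum(is.na(hit))
    locs <- tl[hit[!is.na(hit)]]
    repmask[r] <- sum(2L^(locs - 1L))
  }
  key <- paste(trials$location_roles, trials$exposure_ms, repmask)
  grp <- !duplicated(key)
  counts <- as.integer(table(factor(key, levels = key[grp])))
  rolesmat <- do.call(rbind, lapply(roles_list[grp], function(ch) {
    unname(c(E = 0L, T = 1L, D = 2L)[ch])
  }))
  list(rolesmat = rolesmat,
       exposure_ms = trials$exposure_ms[grp],
       repmask = as.integer(repmask[grp]),
       counts = counts,
       n_trials = n,
       n_intrusions = intrusions,
       has_distractors = any(rolesmat == 2L))
}

nll_prepared <- function(par, prep, quad_nodes, lik_floor) {
  quad <- t0_quadrature(par$mu_t0, par$sigma_t0, quad_nodes)
  g <- nrow(prep$rolesmat)
  wmat <- matrix(par$w, g, 6, byrow = TRUE)
  umat <- wmat * (prep$rolesmat == 1L) + par$alpha * wmat * (prep$rolesmat == 2L)
  vmat <- par$C * umat / rowSums(umat)
  taumat <- pmax(outer(prep$exposure_ms, quad$t0, "-"), 0) / 1000
  cpp_nll(vmat, prep$rolesmat, prep$repmask, taumat, quad$w, par$pK,
          par$p_lapse, lik_floor, prep$counts)
}

#' Negative log-likelihood of a trial table
#'
#' Sum over trials of minus the log probability of the observed report under
#' the race model. Per-trial likelihoods are floored at `lik_floor` to keep
#' the objective finite; floored trials are counted in the `n_floored`
#' attribute. Reported graphemes absent from the display (intrusions) are
#' excluded and counted in `n_intrusions`.
#'
#' @param params A [tva_params()] object.
#' @param trials A trial table (see [read_trial_table()]) from a single
#'   observer and condition.
#' @param quad_nodes Quadrature nodes for the threshold integral.
#' @param lik_floor Per-trial likelihood floor.
#' @return Scalar negative log-likelihood with attributes `n_floored` and
#'   `n_intrusions`.
#' @export
negative_log_likelihood <- function(params, trials, quad_nodes = 24,
                                    lik_floor = 1e-12) {
  if (nrow(trials) == 0) stop("empty trial list", call. = FALSE)
  prep <- prepare_trials(trials)
  par <- params
  res <- nll_prepared(par, prep, quad_nodes, lik_floor)
  structure(res$nll, n_floored = res$n_floored,
            n_intrusions = prep$n_intrusions)
}

#' Fitting configuration
#'
#' @param seed Seed for the restart generator (fits are deterministic given
#'   the seed).
#' @param restarts Number of simplex starts (first start is the data-driven
#'   initial point; further starts are random perturbations of it).
#' @param quad_nodes Quadrature nodes for the threshold integral.
#' @param maxit Simplex iterations per start.
#' @param polish_maxit Iterations for the re-fired simplex polish rounds.
#' @param lik_floor Per-trial likelihood floor.
#' @return A list of class `tva_fit_config`.
#' @export
fit_config <- function(seed = 1, restarts = 8, quad_nodes = 24,
                       maxit = 600, polish_maxit = 1000, lik_floor = 1e-12) {
  structure(list(seed = seed, restarts = restarts, quad_nodes = quad_nodes,
                 maxit = maxit, polish_maxit = polish_maxit,
                 lik_floor = lik_floor),
            class = "tva_fit_config")
}

start_values <- function(trials, prep) {
  # crude capacity guess: mean number of reported targets at the longest
  # exposure; everything else starts at field-typical values
  sizes <- vapply(prep$repmask, function(m) sum(bitwAnd(m, 2L^(0:5)) > 0L),
                  numeric(1))
  long <- prep$exposure_ms >= max(prep$exposure_ms)
  K0 <- sum(sizes[long] * prep$counts[long]) / sum(prep$counts[long])
  K0 <- min(max(K0, 1.5), 5.5)
  pK0 <- dnorm(1:6, K0, 0.9) + 0.02
  tva_params(mu_t0 = 10, sigma_t0 = 3, C = 80, alpha = 0.5,
             w = rep(1 / 6, 6), pK = pK0 / sum(pK0), p_lapse = 0.02)
}

#' Maximum-likelihood fit for one observer and condition
#'
#' Fits all 15 free parameters (14 when the condition contains no distractor
#' trials, in which case `alpha` is fixed at 1) by minimizing the negative
#' log-likelihood on an unconstrained scale: identity for `mu_t0`, log for
#' `sigma_t0`, `C` and `alpha`, softmax for `w` and `pK`, logit for the lapse
#' probability. The search is a seeded multi-start Nelder-Mead simplex; the
#' best start is polished by re-firing the simplex until the objective stops
#' improving. Deterministic for a fixed config seed.
#'
#' @param trials Trial table from a single observer and condition.
#' @param config A [fit_config()].
#' @return An object of class `tva_fit`: fitted [tva_params()], the final
#'   negative log-likelihood, optimizer status, derived summaries
#'   (`t0` = mu_t0 in ms, `C` in elements/s, `K` = E over the fitted capacity
#'   distribution, `alpha`) and bookkeeping counts.
#' @export
fit_observer <- function(trials, config = fit_config()) {
  if (nrow(trials) == 0) stop("empty trial list", call. = FALSE)
  if (length(unique(trials$observer)) > 1L ||
      length(unique(trials$condition)) > 1L)
    stop("`trials` must come from a single observer and condition",
         call. = FALSE)
  if (nrow(trials) < 200)
    warning("fewer than 200 trials; parameter estimates will be unstable",
            call. = FALSE)
  prep <- prepare_trials(trials)
  fit_alpha <- prep$has_distractors
  start <- start_values(trials, prep)
  theta0 <- pack_theta(start, fit_alpha)
  objective <- function(theta) {
    par <- unpack_theta(theta, fit_alpha)
    if (!is.finite(par$C) || !is.finite(par$sigma_t0) || par$sigma_t0 <= 0)
      return(1e10)
    res <- try(nll_prepared(par, prep, config$quad_nodes, config$lik_floor),
               silent = TRUE)
    if (inherits(res, "try-error") || !is.finite(res$nll)) return(1e10)
    res$nll
  }
  scale <- c(4, 0.3, 0.25, if (fit_alpha) 0.4, rep(0.2, 5), rep(0.5, 5), 1)
  best <- NULL
  conv <- 1L
  local_seed(config$seed, {
    for (i in seq_len(max(1L, config$restarts))) {
      th <- if (i == 1L) theta0 else theta0 + rnorm(length(theta0)) * scale
      o <- optim(th, objective, method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # re-fire the simplex from the incumbent until no real improvement;
    # convergence means the objective has stopped moving, not that the last
    # simplex happened to collapse within its iteration budget
    for (round in 1:6) {
      o <- optim(best$par, objective, method = "Nelder-Mead",
                 control = list(maxit = config$polish_maxit, reltol = 1e-9))
      improved <- best$value - o$value
      if (o$value < best$value) best <- o
      conv <- if (improved < 0.05) 0L else 1L
      if (improved < 0.05) break
    }
  })
  par <- unpack_theta(best$par, fit_alpha)
  params <- tva_params(par$mu_t0, par$sigma_t0, par$C, par$alpha, par$w,
                       par$pK, par$p_lapse)
  boundary <- par$p_lapse > 0.45 || par$p_lapse < 1e-4 ||
    par$sigma_t0 < 0.05 || par$C > 2000
  status <- if (conv != 0L) "maxit"
            else if (boundary) "boundary"
            else "converged"
  chk <- nll_prepared(par, prep, config$quad_nodes, config$lik_floor)
  structure(
    list(params = params,
         nll = best$value,
         convergence = conv,
         status = status,
         n_restarts = config$restarts,
         n_trials = prep$n_trials,
         n_floored = chk$n_floored,
         n_intrusions = prep$n_intrusions,
         alpha_fixed = !fit_alpha,
         summaries = derive_summaries_params(params),
         config = config),
    class = "tva_fit")
}

derive_summaries_params <- function(params) {
  list(t0 = params$mu_t0, C = params$C,
       K = sum(1:6 * params$pK), alpha = params$alpha)
}

#' Derived summary parameters of a fit
#'
#' The four headline quantities of the analysis: `t0` (perceptual threshold,
#' ms; the mean of the fitted threshold distribution), `C` (processing speed,
#' elements/s), `K` (expected VSTM capacity, the mean of the fitted capacity
#' distribution) and `alpha` (distractor:target weight ratio).
#'
#' @param fit A `tva_fit` object (or a [tva_params()] object).
#' @return Named list with `t0`, `C`, `K`, `alpha`.
#' @export
derive_summaries <- function(fit) {
  if (inherits(fit, "tva_params")) return(derive_summaries_params(fit))
  stopifnot(inherits(fit, "tva_fit"))
  fit$summaries
}

#' @export
print.tva_fit <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("TVA fit (%d trials, nll = %.2f, %s)\n",
              x$n_trials, x$nll, x$status))
  cat(sprintf("  t0 = %.2f ms  C = %.1f /s  K = %.2f  alpha = %.3f  lapse = %.3f\n",
              s$t0, s$C, s$K, s$alpha, x$params$p_lapse))
  invisible(x)
}

#' Fit every observer and condition in a trial table
#'
#' @param trials Trial table covering one or more observers; one fit is run
#'   per observer-condition cell.
#' @param config A [fit_config()]; each fit derives its seed from the config
#'   seed and the cell, so results do not depend on fit order.
#' @return Tibble with one row per observer and condition: identifiers, the
#'   four summary parameters, lapse, the negative log-likelihood and the
#'   optimizer status.
#' @export
fit_cohort <- function(trials, config = fit_config()) {
  cells <- unique(trials[, intersect(c("observer", "group", "pair", "condition"),
                                     names(trials))])
  cells <- cells[order(cells$observer, cells$condition), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$observer == cells$observer[i] &
                  trials$condition == cells$condition[i], ]
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    fit <- fit_observer(sub, cfg)
    s <- fit$summaries
    dplyr::bind_cols(
      tibble::as_tibble(cells[i, ]),
      tibble::tibble(t0 = s$t0, C = s$C, K = s$K, alpha = s$alpha,
                     p_lapse = fit$params$p_lapse, nll = fit$nll,
                     status = fit$status))
  })
  dplyr::bind_rows(out)
}
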