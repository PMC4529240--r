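RATIOS <- data.frame(ratio = c("6T0D", "4T2D", "3T3D"),
                     n_targets = c(6L, 4L, 3L),
                     n_distractors = c(0L, 2L, 3L))
EXPOSURES <- c(10, 20, 30, 50, 80, 150)

#' Build a balanced 1080-trial schedule
#'
#' The study design: 4 blocks of 270 trials crossing congruence (2) x
#' target/distractor ratio (6T0D, 4T2D, 3T3D) x exposure duration (10, 20,
#' 30, 50, 80, 150 ms), 30 trials per cell overall. 270 is not divisible by
#' the 36 cells, so the full crossing is balanced over pairs of blocks
#' (15 per cell per 540 trials) while every single-factor margin is balanced
#' exactly within each block (135 per congruence, 90 per ratio, 45 per
#' exposure) via a seeded 7/8-copy assignment. Target and distractor
#' locations are drawn uniformly per trial.
#'
#' @param seed Integer seed; schedules are a pure function of it.
#' @return Tibble with columns `block`, `trial_index`, `condition`, `ratio`,
#'   `n_targets`, `n_distractors`, `exposure_ms`, `location_roles`.
#' @export
build_trial_schedule <- function(seed) {
  local_seed(seed, {
    halves <- lapply(1:2, function(h) {
      # choose, per exposure, which 3 of the 6 (congruence x ratio) cells get
      # 8 copies in the first block of the pair; margins come out exact
      ratio_perm <- sample(RATIOS$ratio)
      cond_perm <- sample(c("congruent", "incongruent"))
      expo_perm <- sample(EXPOSURES)
      rows <- list()
      for (ei in seq_along(expo_perm)) {
        if (ei %% 2 == 1) {
          eight <- rbind(c(cond_perm[1], ratio_perm[1]),
                         c(cond_perm[1], ratio_perm[2]),
                         c(cond_perm[2], ratio_perm[3]))
        } else {
          eight <- rbind(c(cond_perm[2], ratio_perm[1]),
                         c(cond_perm[2], ratio_perm[2]),
                         c(cond_perm[1], ratio_perm[3]))
        }
        for (cond in c("congruent", "incongruent"))
          for (rt in RATIOS$ratio) {
            n8 <- any(eight[, 1] == cond & eight[, 2] == rt)
            rows[[length(rows) + 1L]] <- data.frame(
              condition = cond, ratio = rt, exposure_ms = expo_perm[ei],
              nA = if (n8) 8L else 7L)
          }
      }
      cells <- do.call(rbind, rows)
      blockA <- cells[rep(seq_len(nrow(cells)), cells$nA), 1:3]
      blockB <- cells[rep(seq_len(nrow(cells)), 15L - cells$nA), 1:3]
      blockA <- blockA[sample(nrow(blockA)), ]
      blockB <- blockB[sample(nrow(blockB)), ]
      blockA$block <- 2L * (h - 1L) + 1L
      blockB$block <- 2L * (h - 1L) + 2L
      rbind(blockA, blockB)
    })
    sched <- do.call(rbind, halves)
    sched <- merge(sched, RATIOS, by = "ratio", sort = FALSE)
    sched <- sched[order(sched$block), ]
    sched$trial_index <- seq_len(nrow(sched))
    sched$location_roles <- vapply(seq_len(nrow(sched)), function(i) {
      roles <- rep("E", 6)
      occ <- sample(6, sched$n_targets[i] + sched$n_distractors[i])
      roles[occ[seq_len(sched$n_targets[i])]] <- "T"
      if (sched$n_distractors[i] > 0)
        roles[occ[sched$n_targets[i] + seq_len(sched$n_distractors[i])]] <- "D"
      paste(roles, collapse = "")
    }, character(1))
    tibble::as_tibble(sched[, c("block", "trial_index", "condition", "ratio",
                                "n_targets", "n_distractors", "exposure_ms",
                                "location_roles")])
  })
}

# assign grapheme identities to a schedule from an observer's stimulus set
# (12 letters, 6 digits), sampled without replacement within each trial
assign_graphemes <- function(schedule, letters_set, digits_set, seed) {
  stopifnot(length(letters_set) == 12, length(digits_set) == 6)
  local_seed(seed, {
    schedule$displayed_targets <- vapply(schedule$n_targets, function(nt) {
      paste(sample(letters_set, nt), collapse = "")
    }, character(1))
    schedule$displayed_distractors <- vapply(schedule$n_distractors, function(nd) {
      if (nd == 0) "" else paste(sample(digits_set, nd), collapse = "")
    }, character(1))
  })
  schedule
}

#' Simulate one trial's report
#'
#' Draws the generative race: a lapse check, a normal threshold draw, a
#' capacity draw from `pK`, then independent exponential finish times; the
#' targets among the first K finishers within the effective exposure are
#' reported.
#'
#' @param params A [tva_params()] object.
#' @param display A [display_config()] object.
#' @return Integer vector of reported target locations (possibly empty).
#'   Uses R's RNG stream (seed with [set.seed()]).
#' @export
simulate_trial <- function(params, display) {
  v <- element_rates(params, display)
  mask <- cpp_simulate_reports(matrix(v, 1), matrix(role_codes(display$roles), 1),
                               display$exposure_ms, params$mu_t0,
                               params$sigma_t0, params$pK, params$p_lapse)
  which(bitwAnd(mask, 2L^(0:5)) > 0L)
}

# simulate all trials of one observer; schedule must carry graphemes
simulate_observer_trials <- function(params_by_condition, schedule, seed) {
  n <- nrow(schedule)
  roles_list <- strsplit(schedule$location_roles, "")
  rolesmat <- do.call(rbind, lapply(roles_list, function(ch) {
    unname(c(E = 0L, T = 1L, D = 2L)[ch])
  }))
  reported <- character(n)
  local_seed(seed, {
    for (cond in c("congruent", "incongruent")) {
      idx <- which(schedule$condition == cond)
      if (!length(idx)) next
      p <- params_by_condition[[cond]]
      wmat <- matrix(p$w, length(idx), 6, byrow = TRUE)
      rsub <- rolesmat[idx, , drop = FALSE]
      umat <- wmat * (rsub == 1L) + p$alpha * wmat * (rsub == 2L)
      vmat <- p$C * umat / rowSums(umat)
      masks <- cpp_simulate_reports(vmat, rsub, schedule$exposure_ms[idx],
                                    p$mu_t0, p$sigma_t0, p$pK, p$p_lapse)
      reported[idx] <- vapply(seq_along(idx), function(j) {
        r <- idx[j]
        tl <- which(roles_list[[r]] == "T")
        hits <- which(bitwAnd(masks[j], 2L^(tl - 1L)) > 0L)
        tchars <- strsplit(schedule$displayed_targets[r], "")[[1]]
        paste(tchars[hits], collapse = "")
      }, character(1))
    }
  })
  schedule$reported <- reported
  schedule
}

#' Simulate many reports of a single display
#'
#' Runs the generative race `n` times for one fixed display and tallies the
#' reported target sets, aligned with the outcome space of
#' [report_distribution()]. This is the workhorse of the
#' simulator-vs-likelihood consistency checks.
#'
#' @param params A [tva_params()] object.
#' @param display A [display_config()] object.
#' @param n Number of simulated trials.
#' @return Named integer vector of counts over reported target subsets
#'   (names as in [report_distribution()]); sums to `n`. Uses R's RNG
#'   stream.
#' @export
simulate_display_reports <- function(params, display, n) {
  v <- element_rates(params, display)
  rc <- role_codes(display$roles)
  masks <- cpp_simulate_reports(matrix(v, n, 6, byrow = TRUE),
                                matrix(rc, n, 6, byrow = TRUE),
                                rep(display$exposure_ms, n),
                                params$mu_t0, params$sigma_t0, params$pK,
                                params$p_lapse)
  tl <- which(display$roles == "target")
  nT <- length(tl)
  amasks <- 0:(2^nT - 1L)
  lv <- vapply(amasks, function(mask) {
    subset_label(tl[which(bitwAnd(mask, 2^(seq_len(nT) - 1L)) > 0L)])
  }, character(1))
  # location-mask value of each target subset
  locmask <- vapply(amasks, function(mask) {
    sum(2L^(tl[which(bitwAnd(mask, 2^(seq_len(nT) - 1L)) > 0L)] - 1L))
  }, numeric(1))
  tab <- tabulate(masks + 1L, nbins = 64L)
  setNames(tab[locmask + 1L], lv)
}

#' Specification of a synthetic synesthete/control cohort
#'
#' Defines the ground-truth generative conditions for a simulated cohort
#' mirroring the study: `n_pairs` synesthete/control pairs, each control
#' "shadowing" its synesthete with a byte-identical schedule and stimulus
#' set. Base parameters are drawn uniformly from plausible ranges; the
#' congruence effects `delta_C` (elements/s) and `delta_K` (items) are added
#' to the synesthete's congruent condition (defaults match the observed
#' group effects: +20 graphemes/s and +0.23 items), with separate (default
#' null) effects for controls.
#'
#' @param n_pairs Number of synesthete/control pairs.
#' @param delta_C,delta_K Congruent-condition effects for synesthetes.
#' @param control_delta_C,control_delta_K Effects for controls (default 0).
#' @param C_range,mu_t0_range,sigma_t0_range,K_range,alpha_range,lapse_range
#'   Uniform sampling ranges for base parameters.
#' @param w_jitter SD of the log-scale jitter on spatial weights.
#' @param seed Master seed; everything downstream is a function of it.
#' @return A list of class `tva_group_spec`.
#' @export
group_spec <- function(n_pairs = 9, delta_C = 20, delta_K = 0.23,
                       control_delta_C = 0, control_delta_K = 0,
                       C_range = c(60, 120), mu_t0_range = c(5, 20),
                       sigma_t0_range = c(2, 6), K_range = c(3, 4),
                       alpha_range = c(0.4, 0.6), lapse_range = c(0.01, 0.05),
                       w_jitter = 0.1, seed = 1) {
  structure(as.list(environment()), class = "tva_group_spec")
}

# two-point capacity distribution with the requested mean
pk_from_mean <- function(K_mean) {
  K_mean <- min(max(K_mean, 1), 6)
  k0 <- min(floor(K_mean), 5)
  pK <- numeric(6)
  pK[k0] <- k0 + 1 - K_mean
  pK[k0 + 1] <- K_mean - k0
  pK
}

runif1 <- function(range) runif(1, range[1], range[2])

sample_base_params <- function(spec) {
  list(C = runif1(spec$C_range),
       mu_t0 = runif1(spec$mu_t0_range),
       sigma_t0 = runif1(spec$sigma_t0_range),
       K_mean = runif1(spec$K_range),
       alpha = runif1(spec$alpha_range),
       p_lapse = runif1(spec$lapse_range),
       w = softmax(rnorm(6, 0, spec$w_jitter)))
}

params_for_condition <- function(base, condition, dC, dK) {
  C <- base$C + if (condition == "congruent") dC else 0
  Km <- base$K_mean + if (condition == "congruent") dK else 0
  tva_params(base$mu_t0, base$sigma_t0, C, base$alpha, base$w,
             pk_from_mean(Km), base$p_lapse)
}

#' Simulate a full synesthete/control cohort
#'
#' Produces one 1080-trial table per observer. Each pair shares a schedule
#' and stimulus assignment (the control shadows the synesthete); responses
#' are generated from each observer's own parameters, with the spec's
#' congruence effects applied to the congruent condition.
#'
#' @param spec A [group_spec()].
#' @return A list with `trials` (one combined tibble in the trial-table
#'   dialect), `truth` (per observer x condition generative summaries
#'   `t0`, `C`, `K`, `alpha`, plus `sigma_t0` and `p_lapse`) and `spec`.
#' @export
simulate_group <- function(spec) {
  stopifnot(inherits(spec, "tva_group_spec"))
  sub_seeds <- local_seed(spec$seed, matrix(sample.int(2^30, spec$n_pairs * 4),
                                            ncol = 4))
  all_trials <- list()
  truth <- list()
  for (i in seq_len(spec$n_pairs)) {
    sched <- build_trial_schedule(sub_seeds[i, 1])
    stim <- local_seed(sub_seeds[i, 2], list(
      letters_set = sample(LETTERS, 12),
      digits_set = sample(as.character(1:9), 6)))
    sched <- assign_graphemes(sched, stim$letters_set, stim$digits_set,
                              sub_seeds[i, 2])
    bases <- local_seed(sub_seeds[i, 3], list(
      synesthete = sample_base_params(spec),
      control = sample_base_params(spec)))
    deltas <- list(synesthete = c(spec$delta_C, spec$delta_K),
                   control = c(spec$control_delta_C, spec$control_delta_K))
    for (gi in c("synesthete", "control")) {
      obs <- sprintf("%s%02d", if (gi == "synesthete") "S" else "C", i)
      pbc <- list(
        congruent = params_for_condition(bases[[gi]], "congruent",
                                         deltas[[gi]][1], deltas[[gi]][2]),
        incongruent = params_for_condition(bases[[gi]], "incongruent",
                                           deltas[[gi]][1], deltas[[gi]][2]))
      obs_seed <- sub_seeds[i, 4] + if (gi == "control") 7L else 0L
      tr <- simulate_observer_trials(pbc, sched, obs_seed)
      tr$observer <- obs
      tr$group <- gi
      tr$pair <- i
      all_trials[[length(all_trials) + 1L]] <- tr
      for (cond in c("congruent", "incongruent")) {
        p <- pbc[[cond]]
        truth[[length(truth) + 1L]] <- tibble::tibble(
          observer = obs, group = gi, pair = i, condition = cond,
          t0 = p$mu_t0, C = p$C, K = sum(1:6 * p$pK), alpha = p$alpha,
          sigma_t0 = p$sigma_t0, p_lapse = p$p_lapse)
      }
    }
  }
  trials <- dplyr::bind_rows(all_trials)
  cols <- c("observer", "group", "pair", "condition", "block", "trial_index",
            "exposure_ms", "n_targets", "n_distractors", "location_roles",
            "displayed_targets", "displayed_distractors", "reported")
  list(trials = trials[, cols], truth = dplyr::bind_rows(truth), spec = spec)
}
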