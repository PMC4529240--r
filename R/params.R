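#' TVA model parameters for one observer and condition
#'
#' Bundles the 15 free parameters of the fixed-capacity independent race
#' model of whole/partial report: a normally distributed perceptual threshold
#' (`mu_t0`, `sigma_t0`, in ms), the total processing rate `C`
#' (elements/second), the distractor-to-target attentional weight ratio
#' `alpha`, six spatial attentional weights `w` (summing to 1; 5 free), a
#' probability distribution `pK` over visual short-term memory capacities
#' K in 1..6 (5 free), and a lapse probability. Exposure durations are given
#' in milliseconds at the interface; rates are per second.
#'
#' @param mu_t0 Mean of the perceptual threshold, ms.
#' @param sigma_t0 Standard deviation of the threshold, ms (> 0).
#' @param C Total processing rate, elements/s (> 0).
#' @param alpha Distractor:target attentional weight ratio (>= 0).
#' @param w Six non-negative spatial weights; normalized to sum to 1.
#' @param pK Probability mass over capacities K = 1..6; normalized to sum 1.
#' @param p_lapse Probability that a trial yields no encodings at all.
#' @return An object of class `tva_params`.
#' @examples
#' p <- tva_params(mu_t0 = 12, sigma_t0 = 4, C = 80, alpha = 0.5)
#' p$w
#' @export
tva_params <- function(mu_t0, sigma_t0, C, alpha = 1,
                       w = rep(1 / 6, 6),
                       pK = c(0, 0.1, 0.3, 0.4, 0.15, 0.05),
                       p_lapse = 0) {
  stopifnot(is.numeric(mu_t0), length(mu_t0) == 1L, is.finite(mu_t0))
  if (!is.numeric(sigma_t0) || sigma_t0 <= 0)
    stop("`sigma_t0` must be > 0", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (length(w) != 6L || any(w < 0) || sum(w) <= 0)
    stop("`w` must be 6 non-negative weights with positive sum", call. = FALSE)
  if (length(pK) != 6L || any(pK < 0) || sum(pK) <= 0)
    stop("`pK` must be 6 non-negative masses (K = 1..6) with positive sum",
         call. = FALSE)
  if (p_lapse < 0 || p_lapse > 1)
    stop("`p_lapse` must lie in [0, 1]", call. = FALSE)
  structure(
    list(mu_t0 = mu_t0, sigma_t0 = sigma_t0, C = C, alpha = alpha,
         w = w / sum(w), pK = pK / sum(pK), p_lapse = p_lapse),
    class = "tva_params")
}

#' @export
print.tva_params <- function(x, ...) {
  cat("TVA parameters\n")
  cat(sprintf("  t0 ~ N(%.2f, %.2f) ms   C = %.1f /s   alpha = %.3f   lapse = %.3f\n",
              x$mu_t0, x$sigma_t0, x$C, x$alpha, x$p_lapse))
  cat("  w :", paste(sprintf("%.3f", x$w), collapse = " "), "\n")
  cat("  pK:", paste(sprintf("%.3f", x$pK), collapse = " "),
      sprintf("  E[K] = %.2f\n", sum(1:6 * x$pK)))
  invisible(x)
}

#' One trial's display layout
#'
#' Describes which of the six display locations hold targets (letters),
#' distractors (digits) or nothing, together with the exposure duration and
#' the congruence condition of the stimulus set.
#'
#' @param roles Length-6 character vector over `"target"`, `"distractor"`,
#'   `"empty"`, or a 6-character code of `T`/`D`/`E`.
#' @param exposure_ms Exposure duration in ms (> 0). The study design uses
#'   10, 20, 30, 50, 80 or 150 ms; other values are allowed for simulation
#'   studies.
#' @param condition `"congruent"` or `"incongruent"`.
#' @return An object of class `display_config`.
#' @examples
#' display_config("TTDTED", exposure_ms = 80)
#' @export
display_config <- function(roles, exposure_ms, condition = "congruent") {
  if (is.character(roles) && length(roles) == 1L && nchar(roles) == 6L)
    roles <- strsplit(roles, "")[[1]]
  roles <- c(T = "target", D = "distractor", E = "empty")[toupper(substr(roles, 1, 1))]
  if (length(roles) != 6L || anyNA(roles))
    stop("`roles` must describe 6 locations as target/distractor/empty",
         call. = FALSE)
  nT <- sum(roles == "target"); nD <- sum(roles == "distractor")
  if (nT < 1L) stop("display must contain at least one target", call. = FALSE)
  if (!is.numeric(exposure_ms) || exposure_ms <= 0)
    stop("`exposure_ms` must be > 0", call. = FALSE)
  condition <- match.arg(condition, c("congruent", "incongruent"))
  structure(
    list(roles = unname(roles), exposure_ms = exposure_ms,
         condition = condition, n_targets = nT, n_distractors = nD),
    class = "display_config")
}

#' @export
print.display_config <- function(x, ...) {
  code <- paste(c(target = "T", distractor = "D", empty = "E")[x$roles],
                collapse = "")
  cat(sprintf("display %s (%dT%dD), %g ms, %s\n", code,
              x$n_targets, x$n_distractors, x$exposure_ms, x$condition))
  invisible(x)
}

# integer role codes for the C++ kernel: 0 empty, 1 target, 2 distractor
role_codes <- function(roles) {
  unname(c(empty = 0L, target = 1L, distractor = 2L)[roles])
}

roles_string <- function(roles) {
  paste(c(target = "T", distractor = "D", empty = "E")[roles], collapse = "")
}
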