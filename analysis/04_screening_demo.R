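#!/usr/bin/env Rscript

# Screening walk-through on a synthetic observer: consistency scores for
# three color choices per grapheme, the average-score inclusion criterion,
# gray/background exclusion, selection of the 12 letters + 6 digits, and the
# congruent/inverse color pairs for the experimental stimulus set.

library(tvarace)

dir.create("results", showWarnings = FALSE)

# synthetic mapping data: a fairly consistent synesthete; grapheme "G" maps
# to background gray and "Q" has a no-color response
set.seed(42)
graphemes <- c(LETTERS, as.character(1:9))
base <- t(vapply(graphemes, function(g) sample(0:255, 3), numeric(3)))
rows <- list()
for (i in seq_along(graphemes)) {
  for (pres in 1:3) {
    col <- pmin(255, pmax(0, base[i, ] + round(rnorm(3, 0, 24))))
    if (graphemes[i] == "G") col <- c(190, 190, 190) + round(rnorm(3, 0, 2))
    if (graphemes[i] == "Q" && pres == 2) col <- c(NA, NA, NA)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      observer = "synthetic01", grapheme = graphemes[i], presentation = pres,
      r = col[1], g = col[2], b = col[3])
  }
}
maps <- dplyr::bind_rows(rows)
write_result_table(maps, "results/synthetic_mappings.csv")

scored <- grapheme_consistency(maps)
rep <- screening_report(scored)
cat(sprintf("mean consistency score (full set): %.3f -> %s\n", rep$mean_score,
            if (rep$pass) "passes the < 1 criterion" else "fails"))
cat(sprintf("excluded graphemes: %s\n",
            paste(rep$test_set$excluded, collapse = ", ")))
cat(sprintf("test-set mean score: %.3f\n", rep$test_set_mean_score))

sel <- rbind(rep$test_set$letters, rep$test_set$digits)
stim <- tibble::tibble(
  grapheme = sel$grapheme, score = sel$score,
  congruent_r = round(sel$mean_r), congruent_g = round(sel$mean_g),
  congruent_b = round(sel$mean_b))
inv <- t(apply(stim[, c("congruent_r", "congruent_g", "congruent_b")], 1,
               invert_color))
stim$incongruent_r <- inv[, 1]
stim$incongruent_g <- inv[, 2]
stim$incongruent_b <- inv[, 3]
write_result_table(stim, "results/stimulus_set.csv")
cat("selected", nrow(rep$test_set$letters), "letters and",
    nrow(rep$test_set$digits), "digits; wrote results/stimulus_set.csv\n")
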