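#!/usr/bin/env Rscript

# Parameter recovery: simulate observers with known parameters from the
# plausible ranges, refit them, and score the absolute recovery error of the
# four summary parameters (C as a percentage, the rest on their own scales).

library(tvarace)

dir.create("results", showWarnings = FALSE)
sim <- simulate_group(group_spec(n_pairs = 9, delta_C = 0, delta_K = 0,
                                 seed = 20))
syn <- sim$trials[sim$trials$group == "synesthete" &
                    sim$trials$condition == "congruent", ]
cfg <- fit_config(seed = 101, restarts = 3, quad_nodes = 12, maxit = 600,
                  polish_maxit = 1000)
t_start <- Sys.time()
fits <- fit_cohort(syn, cfg)
cat(sprintf("fitted %d observers in %s\n", nrow(fits),
            format(round(Sys.time() - t_start, 1))))

truth <- sim$truth[sim$truth$group == "synesthete" &
                     sim$truth$condition == "congruent", ]
m <- merge(as.data.frame(fits), as.data.frame(truth),
           by = c("observer", "condition"), suffixes = c("_hat", "_true"))
tab <- tibble::tibble(
  observer = m$observer,
  C_true = m$C_true, C_hat = m$C_hat,
  C_err_pct = 100 * abs(m$C_hat - m$C_true) / m$C_true,
  t0_err_ms = abs(m$t0_hat - m$t0_true),
  K_err = abs(m$K_hat - m$K_true),
  alpha_err = abs(m$alpha_hat - m$alpha_true))
print(as.data.frame(tab), digits = 3)
cat(sprintf("medians: C %.1f%%  t0 %.2f ms  K %.3f items  alpha %.3f\n",
            median(tab$C_err_pct), median(tab$t0_err_ms), median(tab$K_err),
            median(tab$alpha_err)))
write_result_table(tab, "results/recovery.csv")
cat("wrote results/recovery.csv\n")
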