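# tvarace

Exact-likelihood modeling of whole and partial report with the fixed-capacity
independent race model of visual attention (TVA), built for accuracy-based
studies of colored-grapheme processing — in particular paired
synesthete/control designs in which each observer is fitted separately on
synesthesia-congruent and incongruent stimulus sets and compared
within-subject.

## The model

An observer briefly views up to six graphemes (letter targets, digit
distractors) followed by a mask, and reports the letters they recognized.
Each displayed element x races toward visual short-term memory (VSTM) with an
exponential processing rate

    v_x = C * u_x / sum_z(u_z),   u_x = w_x (target) | alpha * w_x (distractor)

where `C` is the total processing rate (graphemes/s), `w` the six spatial
attentional weights, and `alpha` the distractor:target weight ratio. An
element is encoded iff it finishes within the effective exposure
`tau = max(0, E - t0)` — with threshold `t0 ~ N(mu_t0, sigma_t0)` per trial —
**and** is among the first `K` finishers, `K` drawn per trial from a free
distribution on {1..6}. With a lapse probability that is 15 free parameters
per observer and condition; the headline summaries are `t0` (ms), `C`
(graphemes/s), `K = E[p_K]` (items) and `alpha`.

The package computes the probability of every possible report set in closed
form (an inclusion–exclusion identity over race order statistics; the
threshold integral is the only quadrature), fits observers by seeded
multi-start Nelder–Mead maximum likelihood, simulates whole cohorts with the
study's balanced 1080-trial design and shadowed controls, scores
grapheme-color consistency for synesthesia screening, and produces the
paired congruence-contrast tables.

## Worked example

The numbered scripts under `analysis/` run the full workflow. A condensed
version:

```r
library(tvarace)

# a cohort of 9 synesthete/control pairs, 1080 trials each; synesthetes get
# +20 graphemes/s and +0.23 items on their congruent condition
sim  <- simulate_group(group_spec(seed = 1))
fits <- fit_cohort(sim$trials, fit_config(seed = 7, restarts = 2,
                                          quad_nodes = 12, maxit = 400,
                                          polish_maxit = 600))
rep  <- congruence_contrast_report(fits, trials = sim$trials)
print(rep$table1)
```

which prints (synesthete rows shown):

```
       group parameter mean_congruent sd_congruent mean_incongruent sd_incongruent      t df        p
  synesthete        t0          9.983       5.2534           10.112         5.1608 -0.346  8 7.38e-01
  synesthete         C        115.277      21.8874           97.447        28.3040  4.660  8 1.62e-03
  synesthete         K          3.578       0.3603            3.338         0.3294 10.202  8 7.31e-06
  synesthete     alpha          0.474       0.0694            0.512         0.0952 -1.241  8 2.50e-01
```

The fitted congruent-minus-incongruent `C` difference (17.8 graphemes/s,
true value 20) is significant for the synthetic synesthetes and absent in
the shadowed controls (t(8) = 0.62, p = .55), while `t0` and `alpha` show no
effect — the selectivity pattern this paired design is built to expose.
Refitting observers simulated with null effects recovers the generating
parameters with median absolute errors of about 6% for `C`, 1.3 ms for
`t0`, 0.03 items for `K` and 0.01 for `alpha`
(`analysis/05_parameter_recovery.R`).

`analysis/04_screening_demo.R` walks the screening stage: consistency
scores (sum of pairwise color distances in unit RGB over three mappings per
grapheme), the average-score < 1 inclusion rule, gray/background exclusion,
selection of the 12 most consistent letters + 6 digits, and the inverse
(255 − channel) incongruent colors.

## Layout

- `R/`, `src/` — the package: exact race probabilities (`tva_core`),
  ML fitting, the cohort simulator, screening and group-contrast statistics,
  trial-table IO.
- `analysis/01_simulate_cohort.R` … `05_parameter_recovery.R` — the
  narrative workflow; outputs land in `results/`.
- `vignettes/tva-race-model.Rmd` — model derivation, numerical choices,
  generator design, and what the checks do and do not show.
- `tests/testthat/` — unit, property and acceptance tests (closed forms,
  ordering-sum and Monte-Carlo oracles, recovery, effect detection).
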