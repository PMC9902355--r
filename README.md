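# vtrial

`vtrial` is a desk-scale R toolkit for running regional crop variety
trials end to end: trait standardization and record storage, automated
randomized complete block (RCBD) design, rules-based data quality
control, multi-environment trial statistics, rule-based and
TOPSIS-based variety evaluation, and GGE biplot analysis. It is aimed
at trial directors, breeders and biometricians who need a reproducible,
scriptable counterpart to the spreadsheet workflows that still dominate
variety testing.

## What it computes

**Observation model.** Every analysis rests on the additive trial
model

    Y_ijk = mu + g_i + e_j + theta_ij + eps_ijk

where `g_i` is the variety (genotype) effect, `e_j` the location
(environment) effect, `theta_ij` their interaction and `eps_ijk` the
plot residual. `anova_two_factor()` decomposes balanced trials by
source; `compute_cv()` (100·SD/mean), `gcv()` (genetic coefficient of
variation from expected mean squares), `lsd_comparisons()`
(t-based least significant difference with letter groupings) and
`rlsd()` (LSD as a percent of the check mean) quantify trial precision
and resolving power; `compare_to_ck()` reports percent yield increases
over the check variety (CK).

**Design.** `group_varieties()` partitions candidates into groups of at
most 16 by seeded random fill, `make_layouts()` lays out every group as
randomized complete blocks (3 replicates by default, CK in every
block), with optional blind codes, and `check_duplicate_applications()`
screens applications that agree on name, pedigree and applicant.

**Quality control.** `validate_all()` applies range, enumeration,
format (calendar date, fixed decimals), consistency (`y = a·x + b`
within tolerance) and statistical (per-location CV inside `[N, M]`,
default 0–10%) rules, flagging records instead of rejecting them.

**Evaluation.** `evaluate_variety()` implements the five-condition
promotion rule (yield, quality, lodging, growth period, one-vote
disease veto) with the shipped maize thresholds; `topsis_rank()` ranks
varieties by relative closeness `C_i = D_i^- / (D_i^+ + D_i^-)` to the
ideal variety, with criterion weights `w_j = alpha_j beta_j / sum
alpha_k beta_k` blending entropy weights and expert scores.

**GGE.** `fit_gge()` performs SVD of the environment-centered
genotype-by-environment matrix; `rank_ideal_genotypes()`,
`rank_ideal_environments()` and `which_won_where()` provide the
ideal-variety, ideal-location and winning-variety readings of the
biplot, and `plot()` draws it.

**Simulation.** `simulate_trial()` generates trials from the
observation model with configurable variance components and a
true-effects ledger; `inject_errors()` corrupts records with classic
abnormal values (malformed dates, double decimals, out-of-range values)
and a corruption ledger, so the QC engine can be scored exactly.

## Worked example

```r
library(vtrial)

trial <- simulate_trial(sim_config(n_varieties = 6, n_locations = 4, seed = 3))
d     <- trial_frame(trial$records, "yield")
an    <- anova_two_factor(d)
an
#> Two-factor ANOVA (6 varieties x 4 environments x 3 replicates; grand mean 604.586)
#>       source df    ss       ms       f          p
#>      variety  5 16994  3398.82  7.3611 3.4437e-05
#>  environment  3 69103 23034.22 49.8873 8.6947e-15
#>  interaction 15 11224   748.29  1.6206 1.0339e-01
#>     residual 48 22163   461.73      NA         NA

means <- variety_means(trial$records, "yield")
lsd   <- lsd_comparisons(an, means)
attr(lsd, "lsd")
#> [1] 17.63801
compare_to_ck(means, trial$ck_code)
#>   variety     mean increase_pct rank
#> 1     V03 621.7792     5.884014    1
#> 2     V06 619.2150     5.447357    2
#> 3     V05 617.2542     5.113443    3
#> 4     V04 597.2125     1.700507    4
#> 5     V01 587.2267     0.000000    5
#> 6     V02 584.8283    -0.408417    6
```

The variety F test is significant (p = 3.4e-05), so the LSD letters in
`lsd` separate the top three varieties from the rest; V03 out-yields
the check (V01) by 5.9%, which clears the 5.0% promotion threshold
checked by `evaluate_variety()`.

A shell workflow is available through the bundled executable
(`inst/exec/vtrial`): `simulate`, `design`, `validate`, `analyze`,
`evaluate`, `topsis`, `gge` and `report` subcommands chain the same
functions, and `analyze` refuses records that never passed `validate`
unless `--force` is given.

## Package layout

- `R/` — implementation (data model, design, qc, stats, evaluate, gge,
  simdata, report, cli)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/variety-trials.Rmd` — methods vignette
- `inst/extdata/maize_traits.json` — example trait/rule/criteria
  configuration
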