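---
title: "Methods: design, quality control and analysis of variety trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, quality control and analysis of variety trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtrial)
```

`vtrial` covers the computational core of a regional variety-testing
workflow: standardized trait records, automated trial design, data
verification, multi-environment statistics, promotion decisions,
comprehensive ranking and GGE biplots. This vignette explains the
models and the choices behind them; it states no result that the test
suite or the acceptance script does not itself compute.

## The observation model

All statistics assume the additive fixed-effects model

$$Y_{ijk} = \mu + g_i + e_j + \theta_{ij} + \epsilon_{ijk},$$

with variety effect $g_i$, environment (location) effect $e_j$,
variety-by-environment interaction $\theta_{ij}$ and plot residual
$\epsilon_{ijk}$. The model's index set deliberately folds *year* into
the environment: a location-year combination is one environment when
`by_year = TRUE` in `trial_frame()`/`pivot_to_matrix()`, and replicates
pool across years otherwise. We chose this resolution because a trial
year behaves statistically like another environment draw — the
simulator mirrors it by re-drawing $e$ and $\theta$ each year — and it
keeps the balanced two-way decomposition exact.

`anova_two_factor()` requires balanced, complete data and rejects
anything else, naming the offending cells. Regional trials are designed
complete; silently approximating an unbalanced decomposition would
change the meaning of every downstream statistic. Mixed/REML models are
out of scope. The variety F statistic is tested against the residual
mean square by default; `error_term = "interaction"` switches the
denominator for users who regard environments as a random sample.
Constant input (all observations equal) reports zero sums of squares
and `NA` F statistics rather than rounding noise; the cutoff treats a
total SS below $10^{-10} \sum y^2$ as zero.

## Trial precision

* **CV** (`compute_cv()`): $100\,s/\bar x$ with the $n-1$ divisor. The
  printed formula in trial-reporting practice is ambiguous about the
  divisor's binding; the sample standard deviation is the standard
  reading and is what we implement. A field trial with CV under 10% is
  conventionally considered well controlled, which is why the QC
  statistic rule defaults to the interval [0, 10].
* **Per-location CV** (`location_cv()`): two flavours are reported and
  labeled. The *error CV* uses the residual mean square of a
  within-location one-way ANOVA (variety effects removed) — the usual
  measure of field control; the *pooled CV* is `compute_cv()` over all
  plot values and also contains genetic spread. The QC rule uses the
  pooled form because it needs no model fit at verification time.
* **LSD** (`lsd_comparisons()`):
  $t_{1-\alpha/2,\,df_{res}}\sqrt{2\,MS_{res}/r}$ with $r$ the
  observations per variety mean. Letters are assigned by the
  sort-descending sequential method: a letter marks each maximal run of
  means whose extremes differ by at most the LSD, so two varieties
  share a letter exactly when some run contains both. LSD is the
  multiple-comparison device used in this workflow; Duncan, SNK and
  similar alternatives are deliberately not implemented.
* **RLSD** (`rlsd()`): the LSD as a percent of a reference mean — the
  smallest varietal difference the trial resolves. The reference is the
  CK mean when a check exists, else the grand mean: percent gains are
  reported against CK, so the detectable difference should be too.
* **GCV** (`gcv()`): $100\sqrt{\hat\sigma^2_g}/\bar Y$ with
  $\hat\sigma^2_g = (MS_g - MS_{err})/k$, $k$ = observations per
  variety mean. Which mean square plays $MS_{err}$ across
  multi-location data is a genuinely open choice; we use the
  interaction MS when more than one environment is present (the
  expected-mean-squares solution under random interaction) and the
  residual MS for single-location data, with an override argument.
  Negative component estimates truncate to zero.

## Trial design

Groups are formed by the sequential fill rule: the group count is fixed
first as $\lceil n/16 \rceil$ (so no group can be empty), then
candidates are drawn in seeded random order and placed in the first
unfilled group. The rule can leave the last group smaller — 60
candidates yield groups of 16, 16, 16 and 12 — which is the documented
behavior of the fill procedure, not a bug. Each (group, location,
replicate) block is an independent random permutation of the group plus
the CK entries; the CK is randomized within blocks like any entry,
since nothing in standard RCBD practice fixes its plot. Tests with very
few varieties use `design_interval_contrast()`: a single unreplicated
sequence with the CK planted first and re-inserted after every `k`
candidates (default 4; the convention is named but not standardized, so
`k` is configurable). Anonymization replaces codes in layouts and task
lists by zero-padded sequential blind codes prefixed with the group
label; the map is kept in the design file for unblinding. Every design
records its seed, and identical seeds reproduce designs byte for byte.
Incomplete-block, alpha-lattice and row-column designs, and any use of
a variety's participation history, are out of scope.

## Data quality control

Records are stored entity-attribute-value style: one row per (variety,
location, replicate, year, trait). Parsing never throws on bad values —
a value that fails its trait's data type gets a `format` flag and stays
in the table. Five rule types mirror the classic verification
taxonomy: range (inclusive bounds), enumeration (trim/case-fold
membership), format (strict `YYYY-MM-DD` calendar dates; digits, a
point and exactly `d` decimals), consistency ($|y - (ax+b)| \le$
tolerance per record key, keys missing either trait reported
unverifiable rather than flagged) and statistic (per-location CV inside
`[N, M]`). Two decisions deserve note:

* The decimal-format convention is read as "digits, decimal point,
  exactly `d` decimals" — the only reading under which a double-pointed
  value like `16.7.8` is the canonical abnormal example.
* Range bounds are inclusive: a plant height of exactly 5 m passes a
  0.5–5 m rule. Boundary observations are legitimate observations.

Precedence: a record with a format flag is never also range- or
consistency-checked — an unparseable value cannot be compared.
`validate_all()` recomputes all flags from scratch on each run
(idempotent), marks records `accepted` or `flagged`, and never deletes
or imputes: flagging is the entire contract, matching a workflow in
which a human director reviews flagged plots. `strict = TRUE` promotes
flags from warnings to errors for pipelines that must block analysis.

## Promotion decisions and TOPSIS

`evaluate_variety()` is a transparent conjunction of five conditions
(yield increases over CK, quality floors, lodging ceilings, growth
period, disease veto) with all comparisons inclusive, returning 0/1
plus the named failed conditions. The shipped thresholds are the maize
profile (mean yield +5.0%, per-year +3.0%, bulk density 720 g/L, starch
69.0%, protein 8.0%, fat 3.0%, lodging 8.0%, lodging-location share
20%, growth period +2.0 days, veto set {Leaf blight, Stem rot, Ear rot,
Head smut, Gray spot}); they are configuration, not constants — other
crops load other profiles. The veto condition is promotion-blocking
whenever the observed highly-infectious set intersects the veto list
("one-vote veto"); `r2` is interpreted as a percent (20 means 20% of
locations). "Highly infectious" is an input label, not computed from a
severity scale.

`topsis_rank()` implements entropy-weighted TOPSIS. The decision matrix
is first direction-adjusted (cost columns reflected as $\max - x$) and
normalized; min–max scaling to [0, 1] is the default, with vector
(unit-norm) normalization as an option. A constant column normalizes to
all ones: it carries no preference information and duly receives zero
entropy weight. Objective weights follow the standard Shannon recipe
($p_{ij}$ column shares, $E_j = -\frac{1}{\ln m}\sum_i p_{ij}\ln
p_{ij}$ with $0\ln 0 = 0$, $\alpha_j \propto 1 - E_j$), blended with
expert scores as $w_j = \alpha_j\beta_j / \sum_k \alpha_k\beta_k$.
Distances to the per-criterion ideal ($S^+$, column maxima of the
weighted matrix) and anti-ideal ($S^-$, minima) are Euclidean, and
closeness $C_i = D_i^-/(D_i^+ + D_i^-)$ ranks the varieties, ties
broken by input order. A single alternative is rejected ($D^+ + D^- =
0$ makes $C$ undefined); if several alternatives are identical on every
criterion their closeness is reported as 0.5. Under min–max
normalization, $C$ is invariant to positive rescaling of any criterion
column — units cannot tip a ranking.

## GGE analysis

The GGE model subtracts each environment's mean from the
genotype-by-environment matrix (removing $e_j$, keeping $g_i +
\theta_{ij}$) and decomposes the rest by SVD. Scores are partitioned as
$U\Lambda^f$ and $V\Lambda^{1-f}$; the default $f = 0.5$ is the
symmetric biplot, chosen because the same fit serves both
ideal-genotype and ideal-environment readings, and $f = 1$
(genotype-focused) provably leaves the genotype projections' order on
the average-environment axis unchanged. Signs are made deterministic by
forcing the largest-magnitude genotype score of each component
positive. The average-environment axis (AEA) is the unit vector along
the mean environment score; the ideal genotype sits at the maximal AEA
projection with zero orthogonal deviation, and genotypes/environments
rank by ascending distance to their ideal point. In the no-interaction
limit the centered matrix has rank one, the fit retains a single
component with a warning, and the ideal-genotype ranking provably
reduces to ranking by genotype mean. `which_won_where()` reduces the
"suitable planting area" view to its computable core: the genotype with
the largest modelled value per environment. Missing cells are never
imputed — the upstream aggregation must produce a complete matrix.
Coordinates, not rendered pixels, are the tested surface; `plot()` is a
convenience.

## The simulator

`simulate_trial()` draws all four effect classes from independent
zero-mean normal distributions — the model states no distributions, and
normality is the conventional reading that makes recovery tests
analytic. Defaults emulate a maize regional yield trial at plot scale:
grand mean 600 with $\sigma_g = 20$, $\sigma_e = 30$, $\sigma_\theta =
10$, $\sigma_\epsilon = 25$, i.e. a residual CV near 4% (a
well-controlled field test) with environment spread exceeding genotype
spread, as is typical for yield. These are the package's study
conditions and are set once, not tuned. The CK is an ordinary simulated
genotype whose true effect the ledger records, so percent-increase
truths are computable. `inject_errors()` produces the classic abnormal
values (scrambled dates, double-decimal numbers, out-of-range values,
out-of-vocabulary labels, one replicate tripled to inflate a location's
CV) with per-class rates and an exact corruption ledger.

What the simulator does *not* emulate: spatial field trend, non-normal
traits (counts, scores), genotype-specific disease pressure, missing
plots. Passing tests therefore demonstrate correctness of the
computations under the stated model, not robustness to field
pathologies outside it.

## Numerical and testing choices

* Sums-of-squares conservation is asserted to $10^{-8}$ relative; GGE
  reconstruction to $10^{-10}$; weight normalization to $10^{-12}$.
* The test suite sizes simulations to seconds, not minutes: the type-I
  error of the variety F test uses 1000 simulated 5×3×3 trials against
  a 3-sigma binomial band around $\alpha = 0.05$; GCV recovery uses 20
  seeds of a 50-variety, 3-location, 3-replicate trial and asks the
  mean estimate to land within 15% of the true $100\sigma_g/\mu$;
  design properties run on 500 random instances. These sizes were
  chosen as the smallest that make the stochastic checks stable across
  seeds.
* All randomness is seeded through a local RNG scope, so package
  functions never disturb the caller's random stream, and equal seeds
  give byte-identical artifacts end to end (designs, record files,
  reports).

## Known limitations

* Only balanced complete trials are analyzed; there is no REML path for
  unbalanced data.
* p-values are reported unadjusted; the LSD is itself the chosen
  multiple-comparison device.
* The consistency rule's linear coefficients ($a$, $b$, tolerance) must
  come from configuration; the package does not estimate them.
* Disease inputs are labels; no severity grading model is included.
* The report module emits Markdown only; conversion to other formats is
  external.
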