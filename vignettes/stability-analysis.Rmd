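---
title: "Yield stability analysis with metstab: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield stability analysis with metstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

# The problem

Variety trials repeated across locations rarely rank genotypes the same
way everywhere: genotype-by-environment interaction (G×E) makes the
"best" variety depend on where it is grown. A breeder choosing material
for wide release wants genotypes that are simultaneously *high
yielding* (large main effect) and *stable* (small interaction), and
wants to know which test locations actually discriminate among
genotypes and which represent the target region. `metstab` implements
the standard desk workflow for a balanced multi-environment trial laid
out in randomized complete blocks (RCBD): combined ANOVA, the AMMI
decomposition with its stability statistics, and GGE biplot geometry.

The package ships the cell-mean yield matrix of a real trial — 12
released bread wheat varieties grown under irrigation at 9 lowland
locations of Oromia, Ethiopia, in the 2021 off-season with 2
replications (`oromia_wheat()`) — and a seeded simulator of the same
design with known effects (`simulate_met()`), so that every stage can
be checked both against published results and against ground truth.

# Models

## Combined ANOVA

For genotype $i$, environment $j$, block $r$, the RCBD combined
analysis partitions

$$SS_{total} = SS_E + SS_{rep(E)} + SS_G + SS_{G\times E} + SS_{err},$$

with the usual degrees of freedom $E-1$, $E(r-1)$, $G-1$,
$(G-1)(E-1)$, $E(G-1)(r-1)$. From a means-only matrix (the common
publication format) only the three treatment strata are estimable;
`partition_ss()` computes them on the replicated scale
($SS_G = Er\sum_i(\bar g_i-\mu)^2$ etc.) and reports each stratum's
share of the *treatment* total $SS_G+SS_E+SS_{G\times E}$, so the three
percentages sum to exactly 100. F tests from means-only input can only
use the interaction mean square as denominator and are flagged as such;
`met_anova()` on replicate-level data adds the replication and pooled
error strata and tests everything against pooled error. Bartlett's
test (`homogeneity_test()`, from per-site error variances and df) is
the default pre-pooling check, with Levene's procedure on absolute
RCBD residuals available for heavier-tailed data.

## AMMI

The Additive Main effects and Multiplicative Interaction model fits

$$Y_{ij} = \mu + g_i + e_j + \sum_{n=1}^{h} \lambda_n \alpha_{ni}
\gamma_{nj} + R_{ij},$$

additive effects by ANOVA, then the double-centred residual
$Z_{ij} = Y_{ij} - \bar g_i - \bar e_j + \mu$ by singular value
decomposition: $\lambda_n$ is the $n$-th singular value of $Z$ and
$\alpha_n, \gamma_n$ its orthonormal genotype and environment vectors
(IPCA axes). Axis $n$ explains $100\,\lambda_n^2/\sum_k\lambda_k^2$
percent of the interaction.

Conventions, chosen once and used everywhere:

* **Symmetric score scaling.** Reported scores are
  $\alpha_{ni}\sqrt{\lambda_n}$ and $\gamma_{nj}\sqrt{\lambda_n}$, so a
  genotype–environment score product reconstructs its interaction term
  and either side's squared scores sum to $\lambda_n$ per axis. The
  published score table of the bundled trial satisfies exactly this
  identity (its per-axis squared-score sums, 2.92 and 2.15, equal the
  fitted $\lambda_1,\lambda_2$), which pins the convention.
* **Sign.** SVD signs are arbitrary; each axis is flipped so the
  largest-magnitude *environment* loading is positive. All derived
  statistics (ASV, explained shares, sectors) are invariant to per-axis
  flips, and comparisons to published scores are made on magnitudes
  and within-axis relative signs.
* **Scale.** All decomposition arithmetic is on the cell-mean scale;
  interaction SS are multiplied by $r$ only at reporting time
  (`ss_ipca`), keeping the singular values consistent with published
  score tables.
* **Axis df.** Axis significance uses the Gollob convention
  $df_n = G + E - 1 - 2n$ (18 for the first axis of a 12×9 table).
  The published ANOVA table of the bundled trial prints a df column
  that is inconsistent with its own design (e.g. 12 df for 12
  genotypes); the design-forced values are used instead.

## ASV and GSI

The AMMI Stability Value measures a genotype's distance from the
origin in the (IPCA1, IPCA2) plane, with the first axis up-weighted by
its share of interaction SS:

$$ASV_i = \sqrt{\left(\frac{SS_{IPCA1}}{SS_{IPCA2}}\,s_{1i}\right)^2 +
s_{2i}^2},$$

small ASV = stable. The weight is taken from the fitted decomposition,
$w = \lambda_1^2/\lambda_2^2$ (1.85 for the bundled trial). Back-solving
the trial's published ASVs from its published scores requires exactly
this $w$; the alternative of using its published per-axis SS (ratio
1.67) is inconsistent with its own ASV column, so the fitted-weight
convention is used and the discrepancy simply noted.

The Genotype Selection Index adds the ASV rank (ascending, rank 1 =
most stable) to the mean-yield rank (descending, rank 1 = highest
yielding): $GSI = rASV + rYSI$, lower = better on both axes at once.
Ties take average ranks. `stability_table()` reports all of this
sorted by GSI.

## GGE

For genotype evaluation the environment main effect is irrelevant, so
the GGE decomposition centres columns only, $Y_{ij} - \bar e_j$, and
decomposes the remainder (genotype main effect + interaction) by SVD.
`gge()` supports symmetric (default), genotype-metric and
environment-metric singular-value partitioning; no division by
environment standard deviations is applied by default (`scale_env`
enables it), since the bundled trial's source gives no indication of
standardization.

Two geometric summaries are built on the first two components:

* `environment_diagnostics()` — the Average-Environment Axis (AEA) is
  the direction of the mean environment score vector; an environment's
  vector length measures discriminating ability and its angle to the
  AEA measures representativeness.
* `which_won_where()` — the convex hull of genotype markers, with rays
  from the origin perpendicular to each hull edge, partitions the
  plane into sectors; each environment falls in one sector and the
  sector's vertex genotype is its winner. This construction is
  mathematically equivalent to taking, per environment, the genotype
  maximizing the rank-2 reconstruction $\hat G_{ij}$ (the normal-cone
  argument: the maximizer of a linear functional over a point set is
  the hull vertex whose normal cone contains the direction), and the
  tests verify both routes against each other. Because the argmax of
  $\sum_n u_{in}\lambda_n v_{jn}$ does not depend on how $\lambda$ is
  split between the sides, sector membership is invariant to the
  scaling mode. An environment exactly on a ray is assigned to the
  counterclockwise sector (a measure-zero tie-break, stated for
  determinism).

# The bundled trial, reproduced

```{r fixture}
trial <- oromia_wheat()
round(mean(trial$means), 2)                       # grand mean, t/ha
partition_ss(trial$means, trial$reps)
```

```{r ammi}
fit <- ammi(trial$means, trial$reps)
round(fit$pct[1:2], 1)                            # IPCA1, IPCA2 share of GxE
stability_table(fit)
```

```{r gge}
g <- gge(trial$means)
environment_diagnostics(g)[, c("environment", "vector_length",
                               "angle_aea", "rank_representative")]
which_won_where(g)
```

## Documented discrepancies with the published analysis

Recomputation from the published 12×9 means matrix reproduces the
published environment SS to four digits, the axis shares to 0.1 of a
percentage point, and ten of twelve published ASVs and IPCA scores to
about $10^{-4}$. Three items do not reproduce, and the package reports
its computed values rather than arbitrating:

1. **The two Fentale varieties are transposed in the published
   stability table.** The recomputed scores assign ASV 0.4103 (scores
   −0.2182, −0.0765) to Fentale 2 and ASV 0.4113 (scores 0.1433,
   −0.3148) to Fentale 1; the source prints the opposite assignment
   while its own yield column matches the means matrix. The two ASVs
   differ by 0.3%, so a near-tie was evidently swapped in production.
   Consequently the recomputed GSI of Fentale 1 is 5 (= 4 + 1), not
   the printed 4, and Fentale 2's is 7, not 8. The headline
   conclusion — the lowest-GSI quartet {Fentale 1, Fentale 2,
   Pavon 76, ETBW 9578} — is unaffected.
2. **Representativeness.** The trial's report names Sewena the most
   representative environment, but under every scaling mode the
   smallest AEA angle belongs to Girja, which lies almost exactly on
   the AEA; Sewena sits nearest the origin (an *average-responding*,
   weakly discriminating site — nearly zero vector length), which is a
   different property. The report's discrimination narrative is also
   internally contradictory (it names both Daro Labu/Bedeno and Girja
   as most discriminating); the computed vector-length ranking puts
   Daro Lebu first.
3. **Sector count.** The report groups the nine environments into four
   sectors, pairing Sewena with Delo Mena. The computed partition
   occupies five sectors: Sewena's winner is ETBW 9578 and
   Delo Mena's is Amibara 2, by margins of about 0.01–0.004 t/ha in
   the rank-2 reconstruction — well inside the wobble of a
   two-decimal means matrix. Because sector membership is
   scaling-invariant (above), no convention choice recovers the
   printed grouping.

# The synthetic generator

`simulate_met()` draws
$Y_{ijr} = \mu + g_i + e_j + \sum_n \lambda_n u_{ni} v_{nj} + b_{jr} +
\varepsilon_{ijr}$ with:

* $g, e$: normal draws re-centred to sum *exactly* to zero, so the
  additive strata contain no leaked interaction;
* $u_n, v_n$: standard-normal draws QR-orthogonalized against the ones
  vector and each other — the interaction term is then *exactly* the
  object AMMI estimates, with known singular values, and
  `ground_truth_ss()` gives closed-form stratum SS
  ($SS_{G\times E} = r\sum\lambda_n^2$);
* $b_{jr}$: block effects centred within each environment, so cell
  means and the treatment strata are untouched and the zero-noise
  ANOVA identity is exact;
* $\varepsilon$: homoscedastic by default; an optional per-environment
  multiplier list provides mild heteroscedasticity for exercising the
  homogeneity tests.

One seed feeds a single generator stream, making whole datasets
byte-reproducible.

Defaults mirror the bundled trial's fitted magnitudes, chosen once
from that fit: $G=12$, $E=9$, $r=2$, $\mu = 3.14$ t/ha,
$\sigma_g = 0.25$ and $\sigma_e = 0.95$ (the spread of the observed
genotype and environment means), $\lambda = (2.9, 2.1, 1.6)$ (the
leading fitted singular values), $\sigma_{err} = 0.5$ (error MS
$\approx 0.24$), $\sigma_{block} = 0.05$ (the replication stratum is
negligible in the trial).

What the generator does *not* emulate: field spatial trend, missing
plots, genotype-specific error variances, multi-season structure, or
non-Gaussian error. Passing parameter-recovery tests therefore shows
the estimators are correct for the stated model, not that real trials
satisfy it.

# Numerical choices and problem sizes

* Degenerate inputs: missing cells, unbalanced replication, duplicate
  plot records, non-positive variances, collinear genotype markers and
  a zero-length AEA are hard errors with a dedicated condition class —
  no silent imputation.
* Collinearity/degeneracy thresholds are relative ($10^{-9}$ of the
  leading singular value); structural identities (zero margins,
  orthogonality, SS additivity, reconstruction) are tested at
  $10^{-9}$ absolute or relative.
* ASV rank ties use average ranks; GSI ties are ordered by mean yield
  descending in the report.
* The parameter-recovery check runs 50 seeded replicates of the
  12×9×2 design at plot noise $\sigma_{err} = 0.05$, chosen a priori
  so that the $O(\sigma_z^2 (G+E)/\lambda)$ upward bias of noisy
  singular values stays inside the three-standard-error band of the
  50-replicate mean; the pure-noise null check compares the
  generator's IPCA1 share against a direct Monte-Carlo SVD null over
  50 seeds. Both finish in seconds.

# Limitations

Fixed-effects decomposition only (no REML/mixed-model stage), complete
balanced tables only, no cross-validation-based axis retention, no
additional stability indices (Eberhart–Russell, Shukla, Wricke), and
no "ideal genotype" concentric view — the implemented surface covers
environment evaluation and which-won-where. LSD and CV require
replicate-level data; for the bundled means-only trial they are
exercised on simulated data instead.
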