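# metstab

Yield stability analysis for balanced multi-environment crop trials:
combined RCBD ANOVA, the AMMI model, ASV/GSI stability statistics, and
GGE biplot geometry.

Plant breeders test candidate varieties across many locations, and
genotype-by-environment interaction (G×E) makes rankings change from
site to site. `metstab` implements the standard toolkit for deciding
which genotypes are simultaneously high-yielding and stable, and which
test environments are informative:

* **Combined ANOVA** — partition of the treatment sum of squares into
  genotype, environment and G×E components with their percentage
  shares (`partition_ss()`), the full replicated decomposition with
  pooled error and F tests (`met_anova()`), per-environment LSD/CV
  (`lsd_cv()`), and Bartlett/Levene homogeneity checks.
* **AMMI** — *Y<sub>ij</sub> = μ + g<sub>i</sub> + e<sub>j</sub> +
  Σ<sub>n</sub> λ<sub>n</sub> α<sub>ni</sub> γ<sub>nj</sub> +
  R<sub>ij</sub>*: additive main effects by ANOVA, the double-centred
  interaction by SVD (`ammi()`), symmetric-scaled IPCA scores, Gollob
  axis df, and AMMI1 biplot coordinates.
* **Stability** — AMMI Stability Value
  *ASV = √[(w·IPCA1)² + IPCA2²]* with *w = SS₁/SS₂*, yield and
  stability ranks, and the Genotype Selection Index
  *GSI = rASV + rYSI* (`stability_table()`).
* **GGE** — environment-centred decomposition (`gge()`),
  discrimination/representativeness diagnostics against the
  average-environment axis (`environment_diagnostics()`), and the
  which-won-where convex-hull sector partition with per-sector winning
  genotypes (`which_won_where()`).
* **Validation tools** — a seeded simulator of replicated RCBD trials
  with an exactly low-rank G×E term and closed-form ground-truth sums
  of squares (`simulate_met()`, `ground_truth_ss()`).

The package ships the cell-mean yield matrix of a 12-variety × 9-location
irrigated lowland bread wheat trial (Oromia, Ethiopia, 2021; 2
replicates) as `oromia_wheat()`, used throughout the examples and
tests.

## Worked example

```r
library(metstab)
trial <- oromia_wheat()

partition_ss(trial$means, trial$reps)
#> Combined multi-environment trial ANOVA (r = 2 )
#>                  Source Df      SS     MS     F   Pr(>F)  SS%
#>               Genotypes 11  10.222  0.929  2.19 2.20e-02  4.9
#>            Environments  8 161.291 20.161 47.44 1.07e-28 77.2
#>  Genotype x Environment 88  37.399  0.425    NA       NA 17.9
#> F denominator: interaction mean square (no error stratum)
```

Environments dominate (77% of the treatment SS): the nine sites differ
far more in mean yield (1.95 t/ha at Girja to 4.81 at Daro Lebu) than
the varieties do. The G×E share (18%) is ~3.7× the genotype share, so
stability matters for selection.

```r
fit <- ammi(trial$means, trial$reps)
round(fit$pct[1:2], 1)
#> [1] 45.5 24.7        # IPCA1 + IPCA2 carry 70.2% of GxE

stability_table(fit)
#> Genotype stability (ASV weight w = 1.847 ; low GSI = stable & high-yielding)
#>   Genotype Mean    ASV rASV rYSI GSI   IPCA1   IPCA2
#>  Fentale 1 3.62 0.4113    4    1   5  0.1433 -0.3148
#>  Fentale 2 3.24 0.4103    3    4   7 -0.2182 -0.0765
#>   Pavon 76 3.11 0.3418    1    7   8  0.0851  0.3036
#>  ETBW 9578 3.37 0.7457    8    2  10 -0.0652 -0.7359
#>  ...
#>    Ogolcho 3.01 1.2989   11    9  20 -0.6105  0.6449
```

Fentale 1 combines the top mean yield (3.62 t/ha, rYSI 1) with a small
ASV, giving the best (lowest) selection index; Ardi has the largest
ASV (2.51 — high-yielding but erratic), and Ogolcho the worst GSI.

```r
g <- gge(trial$means)
which_won_where(g)
#> Which-won-where partition
#> Hull vertices (CCW): Fentale 1, ETBW 9578, Amibara 2, Ogolcho, Ga'ambo 2, Ardi
#>   sector 1 (winner Fentale 1): Abaya, Agawayu, Girja, Yabello
#>   sector 2 (winner ETBW 9578): Sewena
#>   sector 3 (winner Amibara 2): Delo Mena
#>   sector 4 (winner Ogolcho): Bako
#>   sector 6 (winner Ardi): Bedeno, Daro Lebu
```

Ardi wins the high-yield mega-environment (Daro Lebu, Bedeno) while
Fentale 1 wins the largest group of sites. `environment_diagnostics(g)`
ranks Daro Lebu as most discriminating (longest vector) and places
Girja on the average-environment axis; `plot(fit)` and
`plot(g, type = "which-won-where")` draw the corresponding biplots.

An end-to-end run writing every table and figure to disk:

```r
run_met_pipeline("out/", fixture = TRUE)          # or input = "plots.csv"
```

A thin command-line wrapper with `analyze`, `analyze-means`,
`simulate` and `fixture` subcommands is installed at
`system.file("scripts", "metstab-cli.R", package = "metstab")`.

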