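# floodr

Tools for studying the systemic neutrophil compartment in repeated-measures
flow cytometry cohorts — for immunologists and exercise physiologists who
track neutrophil numbers and phenotype over multi-day interventions (e.g. an
eight-day endurance event with morning/evening blood draws), and for
methodologists who want a fully synthetic, seeded test bed for single-cell
cytometry pipelines.

The package covers the complete chain:

1. **Synthetic cohort generation** — a seeded generator of event-level
   cytometry data (12-channel neutrophil panel) whose defaults are
   calibrated to published cohort tables: per-day concentrations of the
   three CD16/CD62L neutrophil subsets
   (CD16^bright^CD62L^bright^ "normal", CD16^bright^CD62L^dim^
   hypersegmented-associated, CD16^dim^CD62L^bright^ banded/immature),
   evening totals, and the morning time courses of six phenotype markers
   (CD35, CD66b, CD11b, CBRM1/5, CD49d, LAIR-1). A separate configuration
   emulates the acute post-endotoxin (LPS) phenotype.
2. **I/O** — FCS 3.0 (list mode, 32-bit float) and delimited text, plus
   cohort metadata tables.
3. **Gating** — scatter + CD66b⁺CD16⁺ neutrophil identification, CD16/CD62L
   quadrant subsets, and conversion of gated fractions to blood
   concentrations via the automated-counter count.
4. **Cohort statistics** — one- and two-way repeated-measures ANOVA with
   Tukey contrasts on the within-subject error term and fold-change 95% CIs.
5. **Control-anchored response model** — a PCA-based single-cell model that
   separates control variation from response-specific variation, with 80%
   benchmark ellipses, overlap statistics and loading biplots.

## The model

For cell *i* with marker vector *x<sub>i</sub>* (a.u., possibly negative
after background subtraction), preprocessing is a single fixed map

> *z<sub>i</sub>* = ( log₁₀(*x<sub>i</sub>* − (min − 1)) − *μ̂*<sub>c</sub> ) / *σ̂*<sub>c</sub>

where min is the global minimum of the analysis pool and *μ̂*<sub>c</sub>,
*σ̂*<sub>c</sub> are per-marker mean and SD of the pooled **control** cells
(all morning day 1 samples), so controls sit at mean 0, SD 1 per marker.

The response model first takes the top *k<sub>c</sub>* principal directions
**P**<sub>c</sub> of the control pool, deflates every cell by projecting that
subspace out, *z̃* = *z*(I − **P**<sub>c</sub>**P**<sub>c</sub>ᵀ), and then
extracts the top *k<sub>r</sub>* principal directions **P**<sub>r</sub> of
the deflated **response** pool. Scores *t* = *z̃* **P**<sub>r</sub> describe
variation specific to the response group and exactly orthogonal to the
control subspace; the explained response-specific variance fractions are the
eigenvalue shares of the deflated response covariance. The control benchmark
is the Mahalanobis ellipse of the control scores whose squared radius is the
empirical 80% quantile of the control squared distances; a sample "overlaps
the control state" to the extent its cells fall inside.

Repeated-measures inference uses the balanced within-subject decomposition
(subject as blocking factor); pairwise time contrasts use the RM error mean
square with Tukey's studentised-range adjustment, and a fold change between
time points is the ratio of the time-point means with CI
((baseline + difference CI) / baseline).

## Worked example

```r
library(floodr)

cohort <- simulate_cohort(
  cohort_config(n_subjects = 28, sessions = "morning",
                events_per_sample = 2000),
  seed = 1
)

tab <- gate_cohort(cohort, subset_gates())   # one row per sample
fit <- rm_anova_oneway(tab, total, subject, day)
glance(fit)
#>   statistic    df df_error p_value n_subjects n_times n_excluded
#> 1      6.77     2       54 0.00238         28       3          0
tidy(fit)[, c("baseline", "follow_up", "fold", "fold_low", "fold_high", "p_adj")]
#>   baseline follow_up  fold fold_low fold_high   p_adj
#> 1 1        5          1.15    0.974      1.32 0.110
#> 2 1        8          1.26    1.09       1.44 0.00158
#> 3 5        8          1.10    0.951      1.25 0.246
```

The total neutrophil concentration does not recover overnight by day 8: a
1.26-fold increase over the day-1 morning baseline (Tukey-adjusted
p ≈ 0.002 in this synthetic cohort), while day 5 is statistically
indistinguishable from baseline — the pattern the generator is calibrated
to.

```r
fa <- flood_analysis(cohort, subset_gates(), k_c = 1)
fa
#> Control-anchored response model: 10 markers, k_c = 1, k_r = 2
#> Response-specific variance explained: 16.6%, 14.7%
#> Samples: 84 | mean fraction inside control benchmark: 0.537
autoplot(fa$model, fa$sample_scores[["S01_d8_morning"]])
```

Control samples sit ~80% inside the cyan benchmark by construction; the
response samples drift out of it as cells shift towards the CBRM1/5, CD49d
and LAIR-1 loading vectors and away from CD62L.

A command-line pipeline wraps the same functions:

```sh
Rscript scripts/pipeline.R all --config run.yaml --seed 1 --out flood_run
```

with subcommands `simulate`, `gate`, `stats`, `flood`, `all`; every stage
writes a manifest (config echo, seed, file hashes).

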