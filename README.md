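# gllrm — polytomous Rasch models and graphical log-linear extensions

`gllrm` implements the complete item-analysis workflow used to validate
short patient-reported outcome scales — the motivating case is a 15-item,
two-subscale questionnaire (perceived burdensomeness / thwarted
belongingness, seven ordered response options, six reverse-keyed items) —
under the Rasch model (RM) and the graphical log-linear Rasch model
(GLLRM), for psychometricians and epidemiologists who need more than a
fit index: interval-level person estimates with score-specific standard
errors, tests of every RM requirement, and honest handling of local
dependence (LD) and differential item functioning (DIF).

## The models

For item *i* with ordered categories *x* = 0..*m<sub>i</sub>* the
partial-credit parameterisation is

P(X<sub>i</sub> = x | θ) ∝ exp( xθ − Σ<sub>k≤x</sub> τ<sub>ik</sub> ),

estimated by **conditional maximum likelihood**: persons with extreme
scores drop out, and the total score is conditioned away via elementary
symmetric functions.  The GLLRM adds uniform LD terms
λ<sub>ij</sub>(x<sub>i</sub>, x<sub>j</sub>) over item pairs and uniform
DIF offsets δ added to an item's thresholds per covariate group, while the
sum score remains sufficient.  Around the fitting engine sit Andersen
conditional likelihood-ratio tests (homogeneity and no-DIF),
item-restscore fit statistics with a conditional parametric bootstrap,
model-based partial Goodman–Kruskal gamma screens for LD and DIF,
Kelderman confirmatory tests, a Monte-Carlo unidimensionality test,
Benjamini–Hochberg adjustment, Monte-Carlo reliability, targeting
indices, DIF-equated scores, an iterative model-search strategy
(`model_search()`), a full multi-sample study driver (`run_study()`) and
an exact synthetic-data generator (`simulate_responses()`,
`inq_fixture()`).

## Worked example

A general-population-like sample from the synthetic fixture, analysed the
way a real validation would proceed:

```r
library(gllrm)
fx  <- inq_fixture(seed = 42)                 # two-sample synthetic bundle
pb  <- apply_coding(fx$gp$responses, fx$scales$pb)  # reverse + 7->4 recode
rm_fit <- rasch_cml(pb)
rm_fit
#> Polytomous Rasch model (CML)
#> items: INQ1, INQ2, INQ3, INQ4, INQ5, INQ6
#> persons: 2508 ( 757 non-extreme used, 1751 extreme )
#> conditional logLik: -1646.919  free parameters: 16

andersen_clr(rm_fit, "score")                 # global homogeneity
#> Andersen CLR (score)
#>   statistic = 14.319, df = 16, p = 0.575

head(scan_ld(rm_fit)[order(scan_ld(rm_fit)$p), c(1:3, 6:8)], 1)
#>   item1 item2 obs_gamma    z    p_adj
#> 1  INQ1  INQ2     0.593 5.31 1.60e-06     # conditional LD flagged

fit <- gllrm(pb, gllrm_spec(ld = list(c("INQ1","INQ2"), c("INQ4","INQ5"))))
andersen_clr(fit, "score")                    # GLLRM passes
#> Andersen CLR (score)
#>   statistic = 1.7138, df = 34, p = 1
kelderman_lr(fit, "INQ1~INQ2")                # and the edge is needed
#> Kelderman LR (INQ1~INQ2)
#>   statistic = 174.73, df = 9, p = <2e-16

mc_reliability(fit, M = 1000, seed = 1)$reliability
#> [1] 0.5146
targeting(fit)$indices[2, c("info_target_index", "floor_pct")]
#>   info_target_index floor_pct
#> 2             0.156      69.8
```

The numbers tell the substantive story: the global homogeneity test is
insensitive here, but the conditional association screen exposes strong
LD between the "better off without me" / "happier without me" item pair,
confirmed overwhelmingly by the Kelderman test; a GLLRM carrying the
planted edges fits; and the scale is badly targeted to
a general population — 70% of respondents sit on the floor, the scale
delivers about 16% of its maximum information where the people actually
are, and the sum-score reliability is correspondingly poor.  The same
functions drive the full seven-line study (`run_study()`), which also
handles the unidimensionality preliminary, item exclusions, matched mixed
samples and DIF-equated scores; `write_report()` emits deterministic,
replayable result tables.

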