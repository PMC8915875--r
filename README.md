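# scirapr

Structured, transparent appraisal of in vitro toxicity studies for chemical
hazard and risk assessment, implemented as an offline R package around the
SciRAP (Science in Risk Assessment and Policy) in vitro instrument,
version 2.0.

Regulatory risk assessors increasingly have to weigh non-guideline in vitro
evidence. SciRAP separates the **reliability** of a study — split into
*reporting quality* (RQ, 24 criteria) and *methodological quality* (MQ, 16
criteria) — from its **relevance** to the assessment question (4 items).
Each reliability criterion is judged **F**ulfilled, **P**artially
**F**ulfilled, **N**ot **F**ulfilled or **N**ot **D**etermined; each
relevance item **D**irectly **R**elevant, **I**ndirectly **R**elevant,
**N**ot **R**elevant or **N**ot **D**etermined. Criteria deemed critical may
be up-weighted (weight *w* ∈ [1, 1.5]); criteria deemed not applicable may
be removed; relevance items can be neither weighed nor removed.

Each reliability section is summarised by the SciRAP score over retained
(non-removed) criteria,

```
score = (F + 0.5 · PF) / T × 100,    F = Σ wᵢ over fulfilled criteria,
                                     PF = Σ wᵢ over partially fulfilled,
                                     T = Σ wᵢ over all retained criteria,
```

which runs from 0 (all not fulfilled) to 100 (all fulfilled); NF and ND have
identical impact on the score. The qualitative companion is the colour
profile: per-domain weighted category fractions (bars for RQ/MQ, a pie for
relevance).

For panels of raters, the package consolidates evaluations into
rater-by-criterion matrices, summarises per-criterion agreement (categories
observed *k*, largest category share *p_max*), classifies variability —
**consensus** (*p_max* = 1), **low** (0.8 ≤ *p_max* < 1), **high**
(*p_max* < 0.6, or *k* ≥ 3 and *p_max* < 0.8), **moderate** otherwise, all
thresholds configurable via `decision_rules()` — and flags criteria for
refinement when they are high-variability in at least one study. A seeded
synthetic generator produces panels with controlled agreement.

## Worked example

Evaluate one study:

```r
library(scirapr)
ev <- new_evaluation("scirap-invitro-2.0", study_label = "Study 1",
                     evaluator = "expert-01")
for (id in sprintf("RQ%02d", 1:24)) ev <- set_rating(ev, id, "F")
ev <- set_rating(ev, "RQ08", "ND")   # metabolic competence not reported
ev <- set_rating(ev, "RQ12", "NF")   # no contamination screening described
ev <- set_rating(ev, "RQ21", "PF")
ev <- remove_criterion(ev, "RQ09", "study used primary cells, not a cell line")
compute_score(ev, "RQ")
#> SciRAP RQ score: 89.1  (F = 20, PF = 1, T = 23)
```

With RQ09 removed, 23 criteria remain; 20 fulfilled and one partially
fulfilled give (20 + 0.5)/23 × 100 = 89.1. The colour profile for the same
evaluation prints one line per evaluation domain:

```r
compute_colour_profile(ev, "RQ")
#> SciRAP colour profile (RQ)
#>   test compound and controls         F 100%  PF   0%  NF   0%  ND   0%
#>   test system                        F  67%  PF   0%  NF  17%  ND  17%
#>   administration of test compound    F 100%  PF   0%  NF   0%  ND   0%
#>   data collection and analysis       F  80%  PF  20%  NF   0%  ND   0%
#>   funding and competing interests    F 100%  PF   0%  NF   0%  ND   0%
#>   other                              F 100%  PF   0%  NF   0%  ND   0%
#>   overall                            F  87%  PF   4%  NF   4%  ND   4%
```

Multi-rater variability on a synthetic 31-expert panel:

```r
sp  <- panel_spec(n_raters = 31, c(F = .85, PF = .1, NF = .05, ND = 0), seed = 7)
mat <- generate_panel("scirap-invitro-2.0", "MQ", sp, study_label = "Study 1")
cl  <- classify_matrix(mat)
head(cl[, c("criterion_id", "n_retained", "k_observed", "p_max", "class")], 4)
#>  criterion_id n_retained k_observed     p_max class
#>          MQ01         31          3 0.7741935  high
#>          MQ02         31          3 0.9032258   low
#>          MQ03         31          2 0.8709677   low
#>          MQ04         31          2 0.9677419   low
prioritize(list(`Study 1` = cl))
```

Here MQ01 (24 of 31 raters agreeing, three categories observed) falls under
the high-variability rule and is prioritized for refinement; the
low-variability criteria are not.

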