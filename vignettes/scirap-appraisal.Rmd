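---
title: "Appraising in vitro toxicity studies with scirapr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising in vitro toxicity studies with scirapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scirapr)
```

## The appraisal model

Evidence appraisal for chemical risk assessment needs to answer two distinct
questions about a study: *can I trust it* (reliability) and *does it bear on
my assessment question* (relevance). The SciRAP approach keeps these
strictly apart, and further splits reliability into **reporting quality**
(RQ) — whether design, conduct and results are reported well enough to be
judged — and **methodological quality** (MQ) — whether the design and
methods are scientifically sound and sensitive. Reliability is judged
against *criteria* that reflect intrinsic properties of the study;
relevance against *items* that only make sense relative to a problem
formulation.

The bundled version 2.0 instrument carries 24 RQ criteria, 16 MQ criteria
and 4 relevance items, grouped into evaluation domains (test compound and
controls; test system; administration of test compound; data collection and
analysis; for RQ additionally funding and competing interests; plus an
open-ended "other" slot per reliability section). Two RQ criteria (cell
passage number, cell density) carry a conditional-applicability note: they
are meant to be removed when the study was not conducted in a cell line.

Each reliability criterion is rated F / PF / NF / ND. The distinction
between ND and a missing rating is deliberate: ND is a *judgment* — the
evaluator looked and found the information insufficient — whereas an
unrated criterion is simply unfinished work. `compute_score()` therefore
refuses incomplete evaluations instead of silently treating gaps as ND.

## The score and its weighted generalisation

For one section, with per-criterion weights $w_i \in [1, 1.5]$ over the
retained (non-removed) criteria,

$$\mathrm{score} \;=\; \frac{\sum_{i \in F} w_i \;+\; 0.5 \sum_{i \in PF} w_i}
{\sum_{i\ \mathrm{retained}} w_i} \times 100 .$$

The unweighted formula on counts is the special case $w_i \equiv 1$. The
weighted form enters the numerator and the denominator symmetrically; this
is the only reading under which an all-fulfilled evaluation scores exactly
100 whatever the weights, which the instrument states as the top of the
score range. Consequences worth knowing:

* NF and ND contribute zero to the numerator and full weight to the
  denominator — they are exchangeable as far as the score is concerned
  (they differ in the colour profile only).
* Upgrading one criterion NF→PF or PF→F raises the score by exactly
  $50\,w_i / \sum w$; the score is monotone in every rating.
* Removing a criterion rescales the denominator: an all-F evaluation stays
  at 100 and an all-NF evaluation stays at 0 under any removals.

Weights are accepted anywhere in the continuous interval $[1, 1.5]$; the
instrument states the range but no step, and nothing in the formula needs
one.

The open-ended "other" entries (RQ24, MQ16) are counted among the 24/16
criteria of the instrument, so they are score-eligible by default. Because
they are phrased as questions rather than statements, their F/NF semantics
is debatable; `compute_score(..., include_open_questions = FALSE)` excludes
them, and the choice is recorded in the result's `T`.

The colour profile reports, per domain, the weighted fraction of retained
criteria in each category; an up-weighted criterion occupies a
proportionally larger area, and removed criteria vanish from the
denominator (a domain whose criteria are all removed is omitted with a
notice). The overall profile and the score are consistent by construction:
$100\,(p_F + 0.5\,p_{PF})$ equals the score to floating-point accuracy,
and the test suite asserts this at $10^{-9}$. Relevance has no numeric
score — the instrument defines scores for RQ and MQ only — so its readout
is the equal-weight four-item pie.

## Multi-rater agreement and variability classes

When several experts evaluate the same study, their evaluations are
consolidated into a rater-by-criterion matrix; a criterion removed by a
rater becomes NA ("not applicable") and leaves the denominator of every
summary. Per criterion we compute the category proportions over retained
ratings, the number of distinct categories observed $k$, and the largest
proportion $p_{\max}$. ND is an ordinary category here: two raters agreeing
on ND agree. Modal ties are broken by the fixed category order F, PF, NF,
ND (DR, IR, NR, ND for relevance); the tie-break affects the modal label
only, never $p_{\max}$ or the class.

Variability is classified semi-quantitatively from $(p_{\max}, k)$:

| class      | default rule                                          |
|------------|-------------------------------------------------------|
| consensus  | $p_{\max} = 1$ (no variability among retained raters) |
| low        | $0.8 \le p_{\max} < 1$                                |
| high       | $p_{\max} < 0.6$, **or** $k \ge 3$ and $p_{\max} < 0.8$ |
| moderate   | anything else ($0.6 \le p_{\max} < 0.8$ with $k \le 2$) |

The consensus and low bands are the instrument's published rules. The
high-variability branch of the original decision tree was never published
with its cut-offs; the defaults above are this package's reconstruction
from the two stated signals (category count and category percentages) and
the stated low band, and every threshold is a parameter of
`decision_rules()` and is embedded in classification output for audit. The
"moderate" class is this package's addition: the published consensus, low
and high rules do not partition the agreement space, and silently lumping
the gap into either neighbour would misreport it. Criteria with fewer than
`min_raters` (default 2) retained ratings are reported as unclassifiable
rather than forced into a class.

Consensus is judged over *retained* raters: if some raters removed a
criterion and all remaining ones agree, that is consensus of the panel that
actually judged it. Chance-corrected agreement statistics (Fleiss' kappa,
Krippendorff's alpha) are intentionally out of scope — the appraisal is
semi-quantitative by design.

Cross-study prioritization follows the published rule: a criterion or item
is flagged for potential refinement when it is classified high in at least
one study; criteria at consensus or low variability everywhere are not
prioritized.

Survey-style summaries use `percent_summary()`, integer arithmetic with
halves rounded away from zero — the convention that reproduces the usual
"n (xx%)" reporting of panel feedback.

## The synthetic generator

`generate_panel()` emulates the *structure* of an expert test round: a
panel of raters, each independently rating each criterion, with an optional
per-cell removal probability (reliability sections only — relevance items
cannot be removed). Cells are drawn i.i.d. from per-criterion category
distributions; identical seeds give identical matrices, and generation is
isolated from the caller's RNG state. Independence across raters and
criteria is an assumption, not an observation: real expert panels show
correlated severity, shared blind spots and experience effects. A per-rater
leniency hook (an exponential tilt on the category credit, off by default)
lets users break rater exchangeability, but no attempt is made to model
real expert behaviour. Passing tests on synthetic panels therefore
demonstrates the correctness of the bookkeeping and the decision rules
under known agreement structure — not that the instrument tames real-world
inter-expert variability.

`generate_evaluation()` draws single complete evaluations under three
presets chosen once as plausible study profiles: `well_reported`
(F/PF/NF/ND = 0.75/0.15/0.05/0.05, expected score ≈ 82), `poorly_reported`
(0.05/0.15/0.40/0.40, expected score ≈ 13) and `mixed`
(0.35/0.30/0.20/0.15, expected score ≈ 50), mirroring a test set that
contains at least one well-reported and one less well-reported study.

## Numerical and interface choices

* Scores are exact rational arithmetic in doubles; human-readable output
  rounds to one decimal, machine formats keep full precision.
* Profile fractions must sum to 1 within $10^{-9}$ per domain; the embedded
  scores of imported reports are recomputed and compared at $10^{-6}$, with
  a tamper warning on mismatch.
* Degenerate inputs fail loudly: scoring with all criteria removed, empty
  profiles, zero denominators and unknown ids raise typed conditions
  (`scirap_*_error`) rather than returning NA.
* JSON is the canonical machine format for catalogs, evaluations and
  reports; CSV is provided for flat interchange (fixed token set, `NA` for
  removed cells) and YAML accepted for catalogs and rule files. Report
  export to spreadsheet formats is out of scope; the CSV report carries the
  same content.
* Rendering uses base graphics onto vector devices (PDF/SVG) with the fixed
  colour mapping green `#2ca02c`, yellow `#ffd92f`, red `#d62728`, grey
  `#bfbfbf`. ND appears as a grey sector in the relevance pie for
  consistency with the reliability bars.

## Verification problem sizes

The test suite verifies the scoring arithmetic against an independent
brute-force oracle on randomised evaluations; the agreement and
classification pipeline against exhaustive enumeration of all 125
three-rater single-criterion matrices plus seeded random 8×5 matrices; the
ND/NF exchangeability on 1,000 random weighted evaluations; and parameter
recovery on synthetic panels of 500 raters × 200 replicates per agreement
level (modal probability 1.0 → consensus, 0.9 → low, 1/3 → high). These
sizes were chosen so the whole suite runs in well under a minute while
leaving the binomial fluctuations of the recovery checks negligible
(at $n = 500$, the probability that a 0.9-modal panel leaves the low band
is below $10^{-11}$ per criterion).

## Known limitations

* The bundled instrument is the version 2.0 in vitro tool only; the in
  vivo, ecotoxicity and nanomaterial variants are out of scope, as is any
  risk-of-bias crosswalk.
* The high-variability thresholds are a documented reconstruction, not the
  original decision tree; analyses intended to match other work should
  state the thresholds used (they are embedded in every output).
* Relevance appraisal is context-dependent by definition; the package
  records judgments but cannot supply the problem formulation that makes
  them meaningful.
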