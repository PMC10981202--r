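---
title: "Methods: an additive MCDA value model for orphan drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an additive MCDA value model for orphan drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanmcda)
```

## The problem and the model

Reimbursement committees appraising orphan drugs face a mismatch: classical
cost-per-QALY appraisal compares a therapy against a single willingness-to-pay
threshold, which systematically disadvantages treatments for very small
populations. Multi-criteria decision analysis (MCDA) broadens the appraisal:
each drug is scored on several explicit criteria, and a weighted sum gives a
single comparable score.

`orphanmcda` implements a linear additive value model. A criteria set holds
$m$ criteria; criterion $i$ has a categorical scoring function mapping each
outcome level to a fraction $x_i \in [0,1]$, and a normalized weight $w_i$
with $\sum_i w_i = 1$. A drug profile selects one level per criterion and
scores

$$ S = 100 \sum_{i=1}^{m} w_i\, x_i \in [0, 100]. $$

The additive form assumes preferential independence between criteria: the
value of a better outcome on one criterion does not depend on the levels
selected elsewhere. That assumption is imperfect here — cost enters both the
cost-effectiveness and budget-impact criteria, and effectiveness enters both
cost-effectiveness and magnitude of health gain — but it is the standard
trade-off of practical value frameworks, and the double counting is visible
to the panel when it votes the weights.

## Weight elicitation: SMART & Swing

Weights are elicited, not asserted. The panel first **ranks** the criteria
from most to least important (ties allowed), then votes, for each criterion,
the percentage **increase** $d$ of its importance over the next-ranked
criterion. All votes are aggregated by the plain arithmetic mean; rank ties
arise when mean ranks coincide exactly (tolerance $10^{-9}$, since votes are
small integers).

Unnormalized weights follow a multiplicative chain upward from an arbitrary
base $b > 0$ at the lowest rank group:

$$ \tilde w_{\text{lowest}} = b, \qquad
   \tilde w_{g} = \tilde w_{g+1}\,\bigl(1 + d_g/100\bigr), $$

with all members of a tied group receiving identical weight. Normalization
$w_i = \tilde w_i / \sum_j \tilde w_j$ removes $b$, which is why the base is
arbitrary (`swing_weights()` defaults to 1; a property test asserts base
invariance).

Two conventions deserve note, both adopted because they are the only reading
under which the embedded default reproduces its published weight table
exactly (verified numerically in the test suite):

* **Tied groups.** A tied group carries one step increase over the group
  below — the maximum of its members' entries — while a `0` entry marks a
  within-tie position. In the default set, rank 6 holds disease rarity
  (entry 0, within-tie) and clinical evidence (entry 25, the group's step).
* **The lowest rank's entry.** The least important criterion also carries a
  printed increase entry (25 for patient age). It has no next-ranked
  criterion to be compared against, so it is stored but never enters the
  chain.

The elicitation layer also covers the session's other votes: the criteria
**count** vote uses plurality with ties broken toward keeping more criteria,
and `truncate_to_count()` then drops whole bottom rank groups — refusing to
split a tied group, since that would require information the votes do not
contain.

## The embedded default criteria set

`emirates_default()` returns the ten-criterion Emirates framework: three
disease-related criteria (therapeutic alternative/unmet need, disease
severity, burden on households — plus disease rarity), two economics-related
(cost-effectiveness as a GDP-per-capita multiple of the ICER, budget impact
as a share of the annual drug budget) and treatment-related criteria
(magnitude of health gain, clinical evidence, indication uniqueness, patient
age). Every scoring function spans 100% to 0%, with between three and six
levels; the burden-on-households criterion has exactly three levels (100, 75,
0) with no intermediate steps. Rarity classes follow the NICE convention
(rare: fewer than 5 per 10,000; ultrarare: about 1 per 50,000); the
thresholds are documentation — the assessor selects the class. Disease
severity is likewise a purely categorical selection; its "expected QALYs
without therapy" gloss is not a quantitative input.

```{r weights}
round(criteria_weights(emirates_default(), percent = TRUE), 1)
```

The three orphan-specific criteria (rarity, indication uniqueness,
therapeutic alternative) jointly hold 23.1% of the weight — the margin by
which this framework deliberately advantages rare-disease therapies over a
conventional appraisal.

## Numeric classifiers and boundary conventions

The scorer itself consumes categorical selections only. Two optional helpers
map numbers onto the economic criteria: `classify_budget_share()` (percent
of the annual drug budget) and `classify_icer_multiple()` (ICER / GDP per
capita). The printed category bounds overlap at their edges
("0.01–0.05" followed by "0.05–0.10"), so both classifiers use half-open
intervals with each boundary belonging to the range that starts there —
a total, deterministic rule, property-tested for no gaps and no overlaps.

Scores are computed in full double precision and summed without intermediate
rounding; one-decimal rounding is applied only at the reporting boundary.
The concordance checks run on the rounded totals, because the procedure's
reference comparison (a 39.7-point spread against a 40-point threshold) is
defined at reported precision. An exact 50.0 is flagged indeterminate and
fails both an "above 50" and a "below 50" expectation, since the criterion
is strictly more-than / less-than. Observed rank ties fail the rank check
unless the expectation declares the tie explicitly.

## Synthetic vote panels and archetype fixtures

`synthetic_votes()` emulates a consensus session: `n_participants` members
each submit a full ranking, one increase vote per criterion, and a desired
criteria count, centred on the consensus encoded in the criteria set. With
`dispersion = 0` all participants vote the consensus exactly — including
tied ranks, which a participant may express directly — so the aggregation
pipeline recovers the set's own ranking and weights; this panel of 11
participants is the default study condition, matching the size of the
original session. With `dispersion > 0`, rank votes become strict
permutations of noisily perturbed consensus positions and increase votes get
truncated Gaussian noise (s.d. = 10 × dispersion percentage points). The
generator emulates vote structure, not voter psychology: real panels show
correlated blocks of opinion, anchoring and discussion effects that i.i.d.
noise does not capture, so passing tests demonstrate the pipeline's
correctness on well-formed panels, not robustness to real committee
dynamics.

`archetype_profiles()` provides four complete drug profiles mirroring the
four therapy archetypes used to validate the original tool: a genetic
curative therapy for an ultrarare disease, a highly effective chronic
therapy for a rare disease, and higher- and lower-quality symptomatic
chronic therapies. The original per-criterion selections were never
published, so these are labelled synthetic reconstructions, constructed to
satisfy the qualitative expectations only (two above 50 points, two below,
the stated rank order). Their exact totals (74.3, 63.0, 40.0, 12.9) are a
property of the reconstruction and are deliberately never asserted against
the originally reported totals (69.2, 59.9, 42.0, 29.5); those published
totals are used as fixed inputs when testing the concordance logic itself.
A robustness test perturbs each weight by ±1 percentage point (renormalizing)
and checks the archetype ordering is unchanged.

## Design choices made where the design was open

* **Rank-vote aggregation rule.** The session's blanket rule is averaging,
  so mean rank is used; alternatives (Borda variants, median rank) were not
  specified and are out of scope.
* **Ties within a participant's ranking.** Permitted (one rank per
  criterion, the same rank usable twice). This keeps dispersion-0 panels
  able to carry a tied consensus; strict permutations remain the noisy
  default.
* **Per-criterion contribution rounding.** Contributions are summed at full
  precision; whether the original spreadsheet rounded before summing is
  unknown, and full precision is the conservative choice.
* **Number of drugs per comparison.** Unlimited. The original spreadsheet
  compared at most four at a time; the limit was an artifact of its layout.
* **Config dialect.** YAML canonical (diff-friendly for committee use), JSON
  accepted as an alternate encoding of the same schema. The embedded default
  set exports byte-stably via `write_criteria_set()` and round-trips
  unchanged.

## Problem sizes

All computations here are small and deterministic: ten criteria, panels of
11 voters, comparisons of four drugs. Property-style tests use a few dozen
randomized instances of up to eight criteria under fixed seeds, and the full
suite runs in seconds.

## Limitations

The engine reproduces a committee's value framework; it does not validate
one. No reimbursement cutoff is defined on the 0–100 scale. Uncertainty in
the categorical selections is not propagated. Weights reflect one panel's
votes, with known double counting between cost- and effectiveness-bearing
criteria; re-elicitation with a different panel yields a different, equally
valid instrument.
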