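---
title: "Preference-sensitive MCDA for treatment choices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preference-sensitive MCDA for treatment choices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdaid)
```

## The model

`mcdaid` implements value-based compensatory multi-criteria decision
analysis. A decision model is a set of options, a set of criteria, and a
complete ratings matrix r_ok on [0, 1] ("how well does option o perform
on criterion k", larger always better). The person supplies nonnegative
importance weights, normalized internally to w_k summing to 1, and each
option is scored by expected value:

$$S_o = \sum_k w_k \, r_{ok}.$$

The method is *compensatory* by construction: a poor rating on one
criterion can be offset by good ratings elsewhere, in proportion to the
weights. Non-compensatory approaches (lexicographic rules, outranking)
are deliberately out of scope. Two structural assumptions matter and are
worth making explicit: criteria are treated as preferentially independent
(the weight on bleeding does not depend on the mortality rating), and
ratings are point values — uncertainty about the evidence enters only
through the certainty multipliers described next, never as distributions
on r.

## Certainty adjustment

GRADE grades the certainty of evidence per *outcome* on four verbal
levels. Verbal levels cannot enter an expected-value calculation, so they
are mapped to multipliers: very low = 0.1, low = 0.4, moderate = 0.7,
high = 1.0. The numbers are a convention — reasonable people can debate
them — so they are configuration (`certainty_mapping()`), not constants,
subject only to being in [0, 1] and strictly increasing with level.
Because GRADE grades evidence per outcome, the multiplier c_k attaches to
the criterion and is shared by every option on it.

How the multiplier should enter the score is genuinely open; the package
offers two modes and always reports which produced the numbers:

* **multiplicative** (default): $S'_o = \sum_k w_k c_k r_{ok}$. The most
  literal reading of "mapping certainty onto the ratings scale".
  Multiplying each rating by c_k and multiplying each criterion's score
  term by c_k are algebraically identical for per-criterion multipliers,
  so there is nothing to choose between those two phrasings.
* **shrink** (shrink-to-neutral): $S'_o = \sum_k w_k (c_k r_{ok} +
  (1-c_k)\,0.5)$. Offered because plain multiplication asymmetrically
  penalises high ratings (it drags everything towards 0, so an uncertain
  *good* outcome is punished while an uncertain *bad* one is flattered);
  shrinking towards the neutral midpoint 0.5 treats the two symmetrically.

Adjusted scores are reported alongside unadjusted ones and are *not*
renormalized so that the best option reaches 1.0 — the whole point of the
pairing is that the effect of the adjustment stays visible. With every
criterion at high certainty the two columns coincide in both modes, which
the tests assert.

User-sourced practical criteria default to high certainty: the person is
the authority on their own practical considerations. This too is
overridable.

## Deriving ratings from published effect differences

Meta-analyses publish effect *differences*, not absolute performances,
so turning them into ratings needs an anchoring rule. The package's
`value_function()` kinds cover the standard cases (identity,
1 − risk, linear rescaling between a worst and best anchor); the bundled
model uses the `reference_anchored` rule: the established comparator
(SAVR) is pinned at 0.5 on every criterion, and the newer option's rating
is 0.5 + scale × benefit, where benefit is the signed risk difference as
a proportion (effects in days are first divided by a horizon, default 30
days — a conventional recovery window that keeps a 3-day admission
difference on the same footing as a 3-point risk difference). The default
scale of 0.5 per unit proportion maps the largest published effect
(bleeding, 24 percentage points) to a rating gap of 0.12, keeping every
rating comfortably inside [0, 1]; any scale up to 2 stays in range, and
clipping beyond that warns. The anchoring is a display convention, not a
claim about absolute risks: expected-value *differences* between the two
options, which is all that drives preference, depend only on the rating
gaps, not on the 0.5 anchor.

## The bundled TAVI/SAVR model

`tavi_savr_model()` builds a two-option, ten-criterion model: seven
locked evidence criteria (mortality, stroke, bleeding, new-onset atrial
fibrillation, heart-failure symptoms, permanent pacemaker insertion,
short-term reintervention) and three unlocked practical considerations
("avoiding open-heart surgery", "recovery burden", "concern about
long-term valve durability") initialised to a neutral 0.5 for both
options until the person rates them. Locking matters: evidence-derived
cells refuse editing (`set_user_rating()` raises a locked-rating error),
so a session cannot misrepresent the evidence, while the three practical
cells are rated per option — a per-cell design chosen over a single
differential judgement because it keeps the ratings matrix uniform and
lets each option be assessed on its own terms.

Three defaults in the bundle are documented stand-ins rather than
published facts, and each is overridable and flagged in the model's
notes: the selection of *which* seven of the nine published effects are
featured (acute kidney injury and admission duration are dropped by
default but re-addable via `overrides$criteria`); the per-criterion
certainty levels (moderate for evidence criteria, high for user
criteria); and the labels of the three practical considerations.
Age-specific mortality and stroke effects are known to exist but are not
published as numbers, so the age group is carried as metadata and
age-specific effects enter only through explicit `overrides$effects` —
nothing is fabricated. Effects are stored TAVI-minus-SAVR on the harm
scale with the `favours` column *derived* from the sign, so a data-entry
sign error is mechanically detectable.

## Sensitivity analyses

**Flip thresholds.** One-way analysis varies a single criterion's
normalized weight t over [0, 1], rescaling the remaining weights
proportionally to sum to 1 − t (the standard scheme; co-variation
alternatives are out of scope). The two-option score difference is linear
in t, so the flip point is closed-form; a grid-scan oracle at 0.001
resolution confirms it in the tests. Ties at the baseline are reported as
ties, never silently ordered; a criterion on which both options are rated
equally can never flip the result and reports no threshold.

**Preference heterogeneity.** Individual weights are the point of the
tool, so the simulator does not estimate any real population's
preferences; it characterises how preference-dependent the *decision* is.
Weights are drawn from a Dirichlet distribution on the simplex via the
gamma representation; the default symmetric concentration 1 is uniform on
the simplex — the maximally agnostic choice — and larger concentrations
encode tighter consensus around equal weights. Each draw scores the
model; exact score ties split the win equally, so shares are unbiased
under perfect symmetry. With n = 10,000 draws the binomial standard error
of a share near 0.5 is 0.005, ample for the one-decimal statements the
report makes; the same n keeps the whole simulation under a second.

**Classification.** GRADE's strong/weak language ("most informed patients
would choose the same option" vs "choices vary with values and
preferences") is verbal; the package operationalises it with explicit
share thresholds, default strong ≥ 0.9 and weak ≥ 0.6, below which the
pattern is equipoise. The defaults are conventions with no published
quantitative anchor, which is why they appear in every output that uses
them.

## Numerical choices

* Normalized weights sum to 1 within 1e-9; normalization is invariant to
  positive rescaling within 1e-12.
* Scores within 1e-9 of each other are reported as ties.
* All simulation output is bit-reproducible given (n, concentration,
  seed); the sampler restores the ambient RNG state afterwards.
* Model documents are JSON with an explicit schema version; unknown
  fields are rejected rather than ignored (silent misconfiguration is
  unacceptable in a clinical-facing tool), and numbers are written with
  17 significant digits so a write/read round trip reproduces ratings
  bit-identically.
* Reports contain no timestamps, so regenerating one from the same inputs
  is byte-identical; run metadata goes to the log stream instead. A score
  object carries an MD5 fingerprint of the model it was computed from,
  and rendering a report against an edited model is an error.

## What the tests do and do not show

The property suite checks the engine against independent naive
implementations (double-loop summation, grid scans, per-draw recounts) on
randomly generated models, and the bundled model against the published
effect constants and structural counts. Passing these shows the
arithmetic and the bundled encoding are right. It does not validate the
tool clinically: ratings derived by the reference-anchored convention are
not absolute risks, the certainty mapping and classification thresholds
are conventions, and the Dirichlet population is a modelling device, not
a measured preference distribution. Every emitted document and report
therefore carries a disclaimer that this is not a validated clinical
decision aid.

## A complete session

```{r example}
m <- tavi_savr_model("65_under_75")
m <- set_user_rating(m, "avoid_open_heart", "TAVI", 0.9)
m <- set_user_rating(m, "avoid_open_heart", "SAVR", 0.2)
w <- elicit_weights(m, c(80, 60, 50, 40, 50, 40, 30, 70, 50, 60))
s <- mcda_score(m, w)
summary(s)
flip_thresholds(m, w)
sh <- preference_share(m, sample_weight_vectors(5000, 10, 1, seed = 42),
                       adjusted = TRUE)
classify_recommendation(sh)
render_decisiographic(m, w, s, flips = flip_thresholds(m, w), shares = sh,
                      classification = classify_recommendation(sh))
```
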