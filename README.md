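# mcdaid — preference-sensitive MCDA decision support

Clinical guidelines grade evidence and issue strong or weak
recommendations, but a recommendation is a population-level judgement: it
bakes in someone else's view of how much a stroke matters relative to
open-heart surgery. `mcdaid` is for people building patient decision
support who want the opposite workflow: present the evidence, elicit the
*individual's* importance weights at the point of decision, and compute a
personalised, preference-sensitive opinion — transparently, with the
arithmetic on show.

The engine is value-based compensatory multi-criteria decision analysis
(MCDA). Each option *o* carries a rating r_ok ∈ [0, 1] on each criterion
*k*; the person supplies nonnegative importance weights, normalized to
w_k with Σ w_k = 1; the option's expected-value score is

    S_o = Σ_k  w_k · r_ok

Evidence quality enters through the GRADE certainty levels, mapped to
multipliers c_k (very low = 0.1, low = 0.4, moderate = 0.7, high = 1.0),
giving a certainty-adjusted score reported *alongside* the unadjusted one:

    S'_o = Σ_k  w_k · c_k · r_ok              (multiplicative mode)
    S'_o = Σ_k  w_k · (c_k r_ok + (1−c_k)/2)  (shrink-to-neutral mode)

Preference sensitivity is quantified two ways: closed-form one-way flip
thresholds (the normalized weight at which the preferred option changes,
the other weights rescaled proportionally), and Dirichlet simulation of a
heterogeneous preference population, summarised as the share of simulated
weightings preferring each option and classified as
`strong_for_X` / `weak_for_X` / `equipoise` against explicit share
thresholds (defaults 0.9 / 0.6).

The bundled worked example is the choice between transfemoral TAVI
(transcatheter aortic valve implantation) and SAVR (surgical aortic valve
replacement) for severe symptomatic aortic stenosis, built from the nine
published randomized-trial effect differences (mortality, stroke, acute
kidney injury, bleeding, new-onset atrial fibrillation and admission
duration favouring TAVI; heart-failure symptoms, permanent pacemaker
insertion and short-term reintervention favouring SAVR). Neither option
dominates: that is exactly why weights matter.

## Worked example

```r
library(mcdaid)

m <- tavi_savr_model("65_under_75")    # 2 options, 10 criteria, 7 locked
w <- elicit_weights(m, rep(100, 10))   # equal importance on 0-100 sliders
s <- mcda_score(m, w)                  # multiplicative certainty adjustment
s
#> MCDA expected-value scores (2 options, 10 criteria)
#>      unadjusted adjusted
#> TAVI     0.5125   0.4038
#> SAVR     0.5000   0.3950
#> certainty adjustment: multiplicative mode, mapping very_low=0.1 low=0.4 moderate=0.7 high=1
```

Under equal weights TAVI edges ahead (0.5125 vs 0.5000): its large
bleeding and atrial-fibrillation advantages outweigh the pacemaker and
heart-failure penalties. The adjusted pair shrinks both scores (all
evidence criteria default to moderate certainty, c = 0.7) but preserves
the ordering — showing both pairs makes the effect of certainty visible
rather than hiding it.

How preference-dependent is that? The pacemaker criterion flips the
result once it gets ~23% of the total weight:

```r
one_way_flip_threshold(m, w, "pacemaker")
#> criterion pacemaker: preference flips to SAVR once its weight exceeds 0.2286
```

and across a maximally agnostic preference population (uniform on the
weight simplex), choices split rather than agree — a weak, not strong,
pattern:

```r
sh <- preference_share(m, sample_weight_vectors(10000, 10, 1, seed = 7),
                       adjusted = TRUE)
classify_recommendation(sh)
#> preference pattern: weak_for_TAVI (strong >= 0.90, weak >= 0.60)
#>   TAVI   SAVR
#> 0.7874 0.2126
```

`render_decisiographic(m, w, s, ...)` assembles everything — ratings with
locked cells marked, weights, both score pairs, flip thresholds, shares
and the disclaimer — into one deterministic plain-text screen.

A command-line front end covering the same pipeline (`fixture`,
`validate`, `score`, `sensitivity`, `simulate`) is installed at
`system.file("cli/mcdaid", package = "mcdaid")`.

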