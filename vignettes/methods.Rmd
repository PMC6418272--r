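---
title: "Global lexical activity: model, stimulus construction, and region-level trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global lexical activity: model, stimulus construction, and region-level trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mromgla)
```

`mromgla` implements a complete computational chain used in
model-based studies of visual word recognition: an interactive-activation
network over a lexicon with the multiple read-out model's (MROM) three
lexical-decision criteria, global lexical activity (GLA) as a scalar
familiarity estimate for any letter string, a constrained stimulus-selection
pipeline that turns GLA into a factor with low/medium/high levels, and the
repeated-measures trend analysis that links those levels to per-region brain
signal change. This vignette explains each stage, the assumptions behind it,
and the design decisions taken where the literature leaves the choice open.

## The network and its dynamics

The network has position-specific letter units (one per position x letter)
and one unit per lexicon word. A word of length L connects to positions
1..L: it is excited by its own letter at each position
(`excite_letter_word`, default 0.07 per sender) and inhibited by every
other letter at those positions (`inhibit_letter_word`, 0.04). Words
inhibit each other laterally (`inhibit_word_word`, 0.21) and feed
activation back to their own letters (`feedback_word_letter`, 0.30). There
is no visual-feature layer: stimuli are presented as clean letter evidence,
a constant `input_clamp` (1.0) added to the net input of the stimulus
letter at each position. Mixed word lengths coexist; a shorter word simply
ignores the positions beyond its length.

Updates are synchronous. Only units with positive activation transmit, and
each unit follows the shunting rule: with net input $n > 0$ the change is
$n\,(a_{max} - a)$, otherwise $n\,(a - a_{min})$, minus decay
$\theta\,(a - r)$ toward the resting level, with hard clipping to
$[a_{min}, a_{max}]$. An isolated unit under constant positive input $n$
therefore converges to $a^\* = (n\,a_{max} + \theta r)/(n + \theta)$,
which the test suite verifies to $10^{-8}$ against long simulated runs.

Letter units rest at 0. Word resting levels encode frequency: $\log_{10}$
frequency (+1 offset, so zero-frequency entries stay finite) is mapped
linearly onto `rest_range` (default $-0.92$ to $0$), the most frequent
word resting at the top. With all-equal frequencies (including a
single-word lexicon) every word rests at 0. The activation floor `a_min`
is $-1.0$ so that the whole resting range lies strictly inside the
activation bounds — a resting state outside the bounds would not be a
fixed point of the dynamics, which the test suite checks exactly.

## Global lexical activity

GLA is the mean, over processing cycles 1 to `gla_cycles` (default 7;
cycle 0 is the resting state and is excluded), of the summed positive
activation of all word units. It is a word-likeness/familiarity estimate:
a string with many orthographic neighbors partially activates all of them
and yields high GLA whether or not it is itself a word. For selection and
leveling, raw GLA is z-scored with the sample (n−1) standard deviation over
the *joint* candidate pool of words and nonwords; a per-lexicality
standardisation is available (`z_by_lexicality = TRUE`) but not the
default, since a single standardisation preserves the word/nonword mean
difference the selection stage must test.

## The three read-out criteria

A lexical decision is read out from three criteria, checked in this order
at every cycle:

* **M** — identification: any word unit reaches `m_criterion` → YES.
* **S** — fast guess: the instantaneous summed positive word activity
  reaches an adjusted threshold → YES.
* **T** — deadline: the adjusted temporal deadline expires → NO.

At `adjust_cycle` the early global activity $g$ is read once; the deadline
becomes `round(t_base + t_gain * g)` and the fast-guess threshold
`max(s_min, s_base - s_gain * g)`. High familiarity thus delays the NO
deadline and makes the fast YES easier — the mechanism by which
high-neighborhood words are answered faster while high-neighborhood
nonwords are rejected more slowly.

The literature specifies the direction of these adjustments but not their
scale, and the original model's parameter values are not recoverable from
the descriptions this package works from. The defaults were fixed once
from the activity scales of the default network on synthetic lexicons:
word-layer sums for words reach roughly 0.5–0.9 by cycle 7–10 and for
nonwords 0–0.5, so `m_criterion = 0.55` is reachable for most words under
lateral inhibition, `s_base = 1.5` with `s_gain = 1.5` puts the adjusted
threshold just inside the trajectory of high-GLA items and out of reach of
low-GLA items, and `t_base = 18` with `t_gain = 15` spreads deadlines over
roughly 18–29 cycles. `adjust_cycle` defaults to 7, the end of the GLA
window: with clean clamped input, word-layer activity for nonwords is
exactly zero until about cycle 4–6, so an earlier read (e.g. cycle 3)
would return $g = 0$ for nearly all nonwords and the adjustment mechanism
would never engage for exactly the items it exists for. All of these are
ordinary `model_params()` arguments.

## Synthetic lexicons

Real studies of this kind draw their lexicon from a frequency-normed
database; such data cannot be redistributed here, so
`generate_synthetic_lexicon()` emulates the relevant statistics: unique
consonant/vowel-skeleton strings (CVC; CVCC/CCVC; CCVCC/CVCCC/CCCVC) of
lengths 3–5, with rank-weighted letter draws so that words concentrate in
a small orthographic space and show the neighborhood overlap monosyllabic
lexicons have. Frequencies per million follow a Zipf law
(rank$^{-1.05}$, rank-1 frequency `freq_max` = 2000). The default size is
1025 words with length proportions 0.18/0.62/0.20, which yields a
four-letter candidate pool of ~600 words, the order of magnitude a
four-letter selection stage needs. A generated lexicon is regenerated with
sharper letter weights if fewer than 10% of its four-letter words have at
least one neighbor; in practice the default settings give a mean
four-letter neighborhood around 4–5 with ~90% of words having neighbors.

The generator emulates *orthographic* structure only: there is no
phonotactic grammar, no syllable structure, no morphology, and letter
frequencies are an idealised power law. Consequently, passing tests show
that the pipeline behaves correctly on lexicons with realistic
neighborhood statistics — not that any quantity matches a specific
natural-language database.

## Stimulus construction

`build_stimuli()` reproduces the construction chain end to end:

1. the lexicon's four-letter words form the word candidate pool;
2. a nonword pool (default 2000) is generated by substituting 1–4
   uniformly chosen positions of uniformly chosen source words with
   different letters, rejecting strings that are lexicon words or
   duplicates (substitution only — no transpositions, insertions or
   deletions);
3. GLA is computed for every candidate and z-scored over the joint pool;
4. `select_stimuli()` picks `n` words and `n` nonwords whose z-GLA samples
   each pass Shapiro–Wilk normality (p > 0.10), differ in mean (Welch t,
   p < 0.01) and pass a median-centred Levene test of equal variances
   (p > 0.10);
5. tertile GLA levels (low/medium/high) are assigned within each
   lexicality by stable sorting, with level sizes differing by at most 1;
6. the orthographic descriptors (Coltheart's N, neighbor frequencies,
   bigram counts) are attached.

Selection is seeded quantile matching with a trimming heuristic: each
class is matched, item by item, to the theoretical quantiles of a target
normal distribution whose mean and spread are fit to that class's pool,
with the ±3σ window kept inside the pool's central support. Failed audits
narrow the failing class's target (normality), rebalance the two spreads
(variance equality) or push the class means apart (mean difference), up to
`max_iterations`. The procedure is deterministic given the seed and always
re-audits the sets it returns.

Two facts about this stage are worth stating plainly. First, the word and
nonword z-GLA distributions separate strongly (words contain their own
unit's activation), so the mean-difference constraint is easy; the binding
constraints are normality and variance equality against skewed pools with
a point mass of zero-GLA nonwords, which is why the achievable common
spread is a fraction of the pool spread. Second, because selection
conditions on GLA, correlations between GLA and the orthographic measures
computed *on the selected sets* are attenuated by range restriction; the
unrestricted candidate pools are the right place to measure that coupling
(on default synthetic lexicons, r(GLA, N) ≈ 0.5–0.6 for words and ≈ 0.78
for nonwords).

## Orthographic measures

For a target string against a lexicon: `N` counts same-length words at
Hamming distance exactly 1 (substitution neighbors); `FN` sums their
frequencies; `NHF`/`FHN` restrict to neighbors with strictly higher
frequency than the target (a nonword's implicit frequency is 0, so every
positive-frequency neighbor counts). Bigrams are the adjacent ordered
letter pairs of the target, position-independent by default (a
position-specific variant is a switch); `BiC` counts their occurrences in
other lexicon words with multiplicity (token counting — a `type` option
counts each shared bigram once per word), `BiN` counts the words sharing
at least one bigram, and `BiF` sums those words' frequencies. The target
itself is never its own neighbor or bigram sharer. All measures are
checked against a naive enumeration oracle.

## Region-level trend analysis

`rm_anova_2x3()` implements the balanced 2 (lexicality) × 3 (GLA level)
fully within-subject ANOVA with subject as random blocking factor. Every
effect is tested against its own subject-by-effect interaction; no
sphericity correction is applied by default (a Greenhouse–Geisser option
exists), so with $n$ subjects the GLA main effect has dfs
$(2,\,2(n-1))$ and single-df contrasts $(1,\,n-1)$ — with 20 subjects,
(2, 38) and (1, 19). Polynomial contrasts use weights $(-1, 0, +1)$
(linear) and $(+1, -2, +1)$ (quadratic) on the level means, tested against
the subject-by-contrast error; their sums of squares decompose the GLA
effect exactly, which the tests verify to $10^{-8}$ on random tables
together with a brute-force sums-of-squares oracle and `aov()` error
strata. Simple GLA effects are computed within each lexicality slice with
slice-wise error terms (a pooled-error option is exposed; slice-wise is
the convention consistent with reporting per-lexicality F tests).

`classify_region_profile()` turns a result into a label by a fixed
decision tree: a significant interaction is named after whichever
lexicality carries a significant linear contrast (`word-specific-linear`,
`nonword-specific-linear`, `shared-linear` if both,
`interaction-nonlinear` if neither); without an interaction, a significant
GLA main effect with a significant pooled linear contrast is
`shared-linear`; anything else is `null`. The sign of the relevant linear
trend is attached as a `direction` attribute.

`generate_region_signals()` provides the matching generator:
`grand_mean + subject effect + slope_lexicality * level + noise`, with
Gaussian homoscedastic noise (the ANOVA's own assumption) and levels coded
0, 1, 2 so the programmed slope is exactly the per-level increment the
linear contrast estimates. Under zero slopes the pooled linear contrast
rejects at the nominal rate (measured 0.05 over 1000 seeded tables); with
a word slope of half a residual sd at n = 20 the word linear contrast has
~83% power. The full `word-specific-linear` classification is a harder
event: it additionally requires the 2-df interaction to be significant,
and at that effect size the interaction's noncentrality is
$\lambda = n \sum (\alpha\beta)_{lj}^2/\sigma^2 = 5$, i.e. ~47% power, so
the classifier returns the word-specific label in only ~40% of such
replicates. Recovering the classification reliably needs roughly a
full-residual-sd slope (interaction power ≈ 0.93). This is a property of
the design, not of the implementation.

## Numerical and degenerate-input conventions

* F ratios with exactly zero error SS are 0 when the effect SS is also 0
  (constant data) and `Inf` otherwise (perfect effect), with p-values 1
  and 0.
* z-transforms of constant vectors, empty lexicons, stimuli containing
  letters outside the network alphabet, windows longer than a trace,
  unbalanced signal tables and missing cells are errors, never silent
  repairs.
* Tertile splits with $n \equiv 1 \pmod 3$ give the extra item to the low
  level (sizes differ by at most 1); boundary ties keep input order.
* All generators and the selection procedure save and restore the global
  RNG state: identical specs (seed included) give identical output, and
  library calls never perturb a caller's random stream.
* Simulation sizes in the test suite (micro-lexicons of 5–20 words for
  the dynamics oracle, 1000/200 replicates for calibration/recovery, 50
  lexicons for the latency benchmark, one full 600/2000-candidate
  selection run) were chosen to make the checked quantities stable at
  desk scale.

## Known limitations

* GLA magnitudes depend on the whole parameter vector; only their ordering
  and coupling to neighborhood structure are asserted, not absolute
  values from any published study.
* The clean-clamp input makes early word-layer dynamics faster than in a
  feature-level model; the `adjust_cycle` default compensates, but
  latency distributions should be read qualitatively (cycles, not ms).
* The selected stimulus sets are range-restricted in GLA by construction;
  correlation analyses on them underestimate the pool-level coupling.
* The synthetic lexicon is orthography-only; any phonological,
  morphological or semantic covariate of real lexicons is out of scope.
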