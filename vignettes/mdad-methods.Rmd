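---
title: "Screening mental-disorder risk from short-text sentiment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mental-disorder risk from short-text sentiment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mdad)
```

## The problem

Clinical descriptions of depressive, anxiety, obsessive-compulsive,
bipolar and panic disorders involve far more emotional nuance than a
positive/negative dichotomy: grief differs from sadness, terror from fear,
loathing from disgust. Coarse two-class sentiment analysis therefore blurs
the boundary between conditions. `mdad` screens short social-media texts by
(i) scoring them against a fine-grained, 11-category affect-intensity
lexicon, (ii) summarizing each user as an 11-dimensional sentiment
distribution, and (iii) comparing that distribution to per-condition
prototype vectors. It is a screening aid — a way to rank risk from
emotional expression — not a diagnostic instrument.

## The 11-category lexicon

The source is an 8-emotion affect-intensity lexicon (anger, disgust,
sadness, surprise, fear, trust, joy, anticipation; one real-valued
intensity per word). People with the five target conditions predominantly
express the negative emotions, so those need finer resolution: disgust,
sadness and fear are each split into a high-arousal and a low-arousal
sub-category — loathing/disgust, grief/sadness, terror/fear — giving the
11 categories of `msai_categories()`. The split treats each word's
intensity as a sample point on the line and runs 2-means clustering
(`kmeans_1d()`, Lloyd's algorithm with seeded random restarts; the
within-cluster sum of squares is the loss). Which cluster gets the
stronger label is not determined by the clustering itself; we assign the
larger-center cluster to the high-arousal name, since loathing, grief and
terror denote the higher-intensity variants on the Plutchik wheel. Anger,
surprise, trust, joy and anticipation pass through unchanged (clustering
anger yields no useful boundary — its words are not bimodal in practice —
and we never split it).

Synonym expansion (`expand_synonyms()`) adds words whose sense similarity
to a seed word is *strictly* greater than 0.7; an added word inherits the
seed's category and intensity, because the expansion step contributes
vocabulary coverage, not new intensity evidence. We expand before
normalizing, so inherited intensities participate in the per-category
rescaling. The package does not bundle a sense-similarity resource; any
(word, synonym, similarity) table can be supplied, and the synthetic
module generates one for testing.

Finally each category is min-max rescaled to [0, 1]
(`normalize_lexicon()`). Min-max is the natural choice here: it preserves
the within-category ranking that the clustering relied on and gives every
category the same dynamic range. A category whose intensities are all
equal is mapped to 1.0 — the words still carry the category's full, if
undifferentiated, signal; mapping them to 0 would silently delete the
category.

## Scoring a text

Per sentence, each sentiment word `w` matched in the lexicon contributes

    Int(w) * prod(alpha_k) * beta * eta + gamma + tau

to its category, where `alpha_k` are the degree-adverb weights attached to
it (range [0, 2]; "very" = 1.5 and "little" = 0.5 anchor the scale; the
empty product is 1), `beta` = 1.5 if the word follows an adversative
("but", ...) in its sentence and 1 otherwise, `eta` = -1 when a negation
attaches and +1 otherwise, and `gamma`/`tau` are the weights of the
nearest emoticon and sentiment-punctuation token (range [0, 1], 0 when
absent) — weaker, additive signals. Qualifiers attach by proximity: each
degree adverb or negation goes to its nearest sentiment word within a
3-token window (ties to the following word; the window guards against
cross-clause capture), each emoticon/punctuation token to its nearest
sentiment word in the sentence, and no qualifier is counted twice.

Sentence vectors are summed over a user's texts within an observation
window (default 14 days, matching a two-week collection period) and
normalized to the sentiment distribution `Ds`: negative components are
clamped to zero, then the vector is divided by its sum. Negation can
legitimately produce negative components ("not happy!" scores
0.8 × (−1) + 0.3 = −0.5 on joy); we clamp at normalization time rather
than at scoring time so that opposite contributions within the window can
cancel first. A text with no net-positive sentiment yields an explicitly
flagged empty distribution instead of a silent zero vector. Only "very"
and "little" have externally anchored weights; all other table entries
(degree adverbs, emoticons, punctuation) are package defaults, shipped as
editable TSV so deployments can re-weight them.

Tokenization lowercases, strips URLs and @-mentions, and keeps hashtag
bodies as plain words. Unicode input is handled as UTF-8 but not
canonically normalized (no NFC pass); texts that rely on combining
characters for emoticons may tokenize differently across platforms.

## Diagnosis

Each condition is represented by a prototype sentiment distribution
`Vs(c)`, initially derived from a screening-scale text: every scale item
is scored with the degree factor of every matched word forced to the
maximum configured degree weight, because scale items describe the most
severe presentation and the prototype is anchored at that severity
reference. The probability of condition `c` for a user is the cosine
similarity between `Vs(c)` and the user's `Ds` — in [0, 1] for
non-negative vectors, symmetric, and invariant to rescaling of either
side. Conditions are scored independently (no argmax suppression): users
can and do present several disorders at once.

Risk levels: severe (SMU) above 0.8, moderate (MMU) from 0.6 to 0.8
inclusive, no-or-mild (NMU) below 0.6; a positive screening result is MMU
or above. The boundary values land in MMU because the severe and
no-or-mild definitions are strict inequalities; both thresholds are
arguments. The published scale texts themselves are not redistributed:
the package generates synthetic stand-in scale texts
(`generate_scale_text()`) and accepts user-supplied scale files.

## Training by stochastic error feedback

Scale language differs from social-media language, so scale-derived
prototypes are corrected against real data. Per condition, each iteration
(1) samples a batch (default 1000 users, with replacement when the corpus
is smaller) from an unlabeled public corpus and computes its average
sentiment distribution, (2) splits the 11 categories into positive
(joy, trust, anticipation, surprise) and negative (the rest) — surprise is
grouped positive so that the top-positive candidate pool is non-trivial;
the partition is overridable — (3) picks uniformly one of the top-2
positive and one of the top-3 negative categories by crowd share,
(4) increments the prototype on each picked dimension by that category's
sentiment increment and renormalizes, and (5) accepts the update only if
the diagnostic error rate on a labeled cohort *strictly* decreases, where
a user counts as positive when their cosine probability reaches 0.6. The
error rate is computed on the full labeled training set each iteration
(stabler than per-batch error, at modest extra cost). The accepted-update
error sequence is non-increasing by construction.

The sentiment increment is the category's crowd share expressed as a
fraction — a share printed as 40% contributes 0.40 — scaled by
`learning_scale` (default 1). We considered the literal reading in which
the share *fraction* is further divided by 100 (increments ~0.004,
available as `learning_scale = 0.01`): with a strict-decrease acceptance
gate, steps that small essentially never change any user's
0.6-threshold decision, so no update is ever accepted and training cannot
reduce error at any realistic cohort size — which would contradict the
premise that iterative error feedback improves the model. The share-scale
increment makes the accept/reject loop productive while renormalization
keeps steps bounded.

Two caveats are inherent to the procedure and worth knowing. First, it is
a rejection-only random walk over at most top_pos × top_neg = 6 proposal
directions whose magnitudes vary only with batch composition; when no
direction can flip any cohort user across the threshold, training stalls
at the current error (runs on some seeds accept only a handful of
updates). Second, the update direction follows crowd sentiment, not the
per-condition gradient, so conditions whose signature categories the
crowd rarely expresses (e.g. the loathing/disgust signature) improve more
slowly.

Evaluation uses per-condition confusion counts at the positive threshold,
precision/recall/F1, and the average diagnostic precision — the mean over
conditions of per-condition accuracy. Cohorts are split 70/30 by
stratified sampling (condition vs. none), rounding the training size half
up per stratum, which reproduces the reference 277/119 and 280/120
split arithmetic exactly.

## The synthetic-data generator

All inputs can be generated (`make_fixture_lexicon()`,
`generate_cohort()`, `generate_scale_text()`, `generate_synonym_table()`),
so the full pipeline runs without downloads. The generator emulates the
*statistical* structure the method relies on — nothing more:

* the source lexicon's split categories are given bimodal intensities
  (modes near 0.2 and 0.8) so the 2-means boundary is real;
* each condition has a ground-truth target distribution concentrated on a
  distinct negative-sentiment signature; controls sit mostly on the four
  positive categories with light negative mass;
* a user's personal distribution is a Dirichlet draw centered on their
  target (concentration 50 by default — Dirichlet noise is the natural
  simplex-valued perturbation), and their tweets sample sentiment words
  category-first from it, with degree adverbs or sentiment punctuation
  injected at rate 0.2;
* cohort sizes default to 20 users per condition plus 100 controls, with
  Poisson tweet counts around 14 per user over a 14-day window,
  echoing the reference cohort's per-condition medians of 10-18.

Texts are word salads with controlled statistics, not natural language:
passing tests demonstrate that the pipeline recovers planted sentiment
structure, not that it parses real tweets, sarcasm, or hashtag slang. In
particular the generator never injects negations, so the clamping path is
exercised by hand-written fixtures instead.

## Numerical and design choices

* `kmeans_1d` uses 10 random restarts by default (seeded, restart stream
  drawn from one seed); the exhaustive 2-partition optimum is verified in
  tests for up to 12 points.
* Duplicate (word, category) lexicon rows keep the maximum intensity, and
  synonym collisions resolve the same way — expansion never lowers an
  intensity.
* Malformed lexicon rows are skipped with a warning; more than 10%
  malformed rows aborts the read.
* Probabilities are clipped into [0, 1] against floating-point drift
  before threshold comparison.
* All vectors share the fixed category order of `msai_categories()`;
  every container validates against it at construction.

Problem sizes in the shipped tests and the acceptance script — a
200-user labeled cohort, a 200-user unlabeled corpus, 100 training
iterations per condition, 100 random clustering fixtures — are chosen so
the full suite completes in well under a minute of compute while keeping
every statistical check comfortably powered.

## Limitations

English-only tokenization; no part-of-speech tagging, dependency parsing,
spelling correction, sarcasm or irony handling; no neutral/objective
class; no per-tweet time-series modeling; independent per-condition
scores with no differential-diagnosis logic; and no claim of clinical
validity — thresholds were set on self-reported social-media cohorts, not
against clinical assessment.
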