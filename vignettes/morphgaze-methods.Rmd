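---
title: "Statistical morphology models and eye-tracking measures: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical morphology models and eye-tracking measures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Readers of a morphologically rich language such as Finnish face a storage /
computation trade-off: a noun can surface in well over a hundred inflected,
derived and cliticised forms, so storing every form as a whole unit is
expensive, while full decomposition into morphemes makes recognition itself
costly. `morphgaze` implements a family of statistical models of morphology
that occupy different points on this continuum and compares how well each
model's per-word *self-information* — the negative base-2 log of the word's
probability, in bits — predicts early versus late eye-tracking measures of
visual word recognition:

* **FFD** (first fixation duration): an early index of lexical access.
* **GD** (gaze duration): the summed first-pass fixation time, a global
  index. In multi-word displays only the *first run* of consecutive
  fixations counts.
* **GmF** (GD minus FFD): a late index, defined only for words that
  received more than one fixation.

Because the corpus and the human recordings such a study rests on are not
distributable, the package generates both: a synthetic agglutinative
lexicon with known (gold) morph boundaries, and simulated fixation data
whose generative effect structure is known exactly. Every claim the test
suite makes is therefore a claim about recoverable ground truth.

## The model family

Seven models are compared, organised by their representational units
(statistical morphs, linguistic morphs, whole words) and by whether unit
probabilities depend on the preceding context:

| units | context-independent | context-dependent |
|---|---|---|
| statistical morphs | MDL segmentation (alpha 0.01 / 0.8 / 10) | category HMM |
| linguistic morphs | morph unigram | morph bigram |
| surface forms | word unigram | — |

### The MDL segmentation model

The core of the package is an unsupervised segmentation model driven by a
two-part minimum-description-length objective. A state of the model is an
assignment of a morph sequence to every corpus word. Its cost, in bits, is

```
cost = lexicon cost + alpha * corpus cost
lexicon cost = sum over morph *types* m of [ -log2 P(letters of m) - log2 P(end marker) ]
corpus cost  = sum over morph *tokens* of -log2 P(morph)    (ML unigram over current counts)
```

Letter probabilities are maximum-likelihood frequencies over the corpus
word types (each type once), extended with an end-of-morph marker whose
pseudo-count equals the number of types; they are held fixed during
training. The hyperparameter `alpha` weights the corpus part: a small
value makes lexicon storage the binding constraint, favouring a compact
inventory of short, reusable, morph-like units; a large value makes corpus
encoding dominant, favouring whole-word storage (whole forms minimise the
number of encoded tokens). The three values compared throughout — 0.01,
0.8 and 10.0 — span full decomposition, a mixed solution, and full forms.

**Search.** Training is coordinate descent: epochs of per-word exhaustive
re-analysis in a seeded random shuffle order. For words of up to ten
characters every one of the `2^(L-1)` segmentations is evaluated *exactly*
(the word's counts are removed, the candidate's added, and the global cost
read off incrementally); longer words use a memoized split-point dynamic
program as a proposal whose exact cost is then compared against keeping
the current analysis. Accepted moves never increase the total cost.
Because coordinate descent over a shared lexicon has genuine local optima
(e.g. two words that share a prefix can only profit from splitting it
*jointly*), training runs a small set of restarts — whole-word
initialisation, fully-split initialisation, and seeded random splits — and
keeps the lowest-cost solution. On toy corpora small enough for exhaustive
joint enumeration, the test suite checks that this search returns the
global optimum. Cost ties are broken deterministically: fewer morphs
first, then the longer leftmost morph.

The trainer is written in C++ (via Rcpp), as is customary for
segmentation model implementations; the R wrapper maps characters to
single bytes beforehand so that split points always fall on character
boundaries.

**Scoring.** A query word is analysed by Viterbi decoding over the
lexicon (dynamic programming over split points, maximising the product of
morph unigram probabilities); its self-information is the sum of
`-log2 P(morph)` over that analysis. Stimulus words are re-analysed at
scoring time rather than looked up from training state, so the scorer
also covers words never seen in training: morphs absent from the lexicon
fall back to the letter model with escape mass `1/(N+1)` (or, in strict
mode, make the word explicitly unscorable).

### Category HMM

A flat structured variant of the segmentation model: morphs belong to
categories (prefix, stem, suffix, non-morpheme) and categories follow a
first-order Markov chain with word-start and word-end pseudo-states.
Transitions that violate morphotactics (word-start to suffix, prefix to
word-end) are pinned at zero. Categories are initialised heuristically —
the longest morph of a word leans stem, earlier long morphs lean prefix,
later ones suffix, very short strings lean non-morpheme — and refined by
Viterbi-EM over the base model's segmentations. This is a deliberate
simplification of hierarchical-lexicon category models: it retains the
property under study (categorical dependency between units) at a desk
scale, and nothing more. Self-information adds the transition terms,
including both boundary transitions, to the emission terms.

### N-gram models

The word unigram model scores surface forms by maximum-likelihood token
frequency. The morph unigram and bigram models are the supervised
counterparts of the segmentation models: they are trained on the gold
(linguistically) segmented corpus. The bigram model conditions each morph
on its predecessor, with word-start as initial context and word-end as a
terminal event, which is what lets it capture within-word prediction of
upcoming morphs. Smoothing is interpolated absolute discounting with
discount 0.5 against a letter-model base distribution, so every
observed-alphabet morph keeps positive probability; the discount value is
recorded in the model's smoothing descriptor and is exposed as a
parameter. Unsmoothed maximum likelihood is available for exact
small-fixture arithmetic.

## Gaze measures, trimming, exclusion

`compute_measures_exp1()` implements the single-word design: FFD is the
first fixation's duration, GD the sum over all fixations on the word, GmF
their difference, missing on single-fixation trials.
`compute_measures_exp2()` implements the word-row design: measures are
restricted to the first run of consecutive fixations on a target area, so
refixations after the eyes have left the word do not count; the launch
site is the letter distance from the immediately preceding fixation to
the target's left border.

The cleaning rules follow standard practice in this literature and are
applied in this order for the lexical-decision design: error trials are
excluded; then subjects whose error rate strictly exceeds 15% are
excluded entirely; then reaction times beyond 3 sample SDs of the
subject's own mean are trimmed in a single pass (no re-iteration). The
word-row design trims first-run GDs by the same per-subject 3-SD rule and
applies no response-based trial exclusion. Length-split analyses divide
items at eight letters or fewer (short) versus nine or more (long).

## Mixed-model comparison

Each model is evaluated by the decrease in deviance it brings to a
baseline linear mixed regression, fitted by **maximum likelihood** (not
REML — deviances across different fixed-effect structures are otherwise
not comparable). The single-word baseline has presentation order as a
fixed effect and random intercepts for subject and item; the word-row
baseline adds launch site as a fixed effect, a list random intercept, and
an uncorrelated per-subject slope for row position (coded -0.5 / +0.5).
The augmented model adds one column: the model's surprisal. Significance
is the likelihood-ratio chi-square with one degree of freedom; AIC is
reported alongside. Continuous covariates are standardised before
fitting, which stabilises the optimizer and leaves deviance differences
unchanged. Rows with missing GmF are dropped from the GmF baseline *and*
its augmented fits (a shared missing-data mask), never from the FFD or GD
fits. Fits with variance estimates on the boundary are kept, with a
message; fits are deterministic given the data.

Correlation tables aggregate measures to item means over subjects before
computing Pearson correlations, mirroring the item-level descriptive
analyses such studies report.

## The synthetic data generator

The generator defines the study conditions; its defaults were chosen once,
on the following grounds, and are not tuned to test outcomes.

* **Grammar.** 420 stems (random consonant-vowel syllable strings over an
  ASCII alphabet) with Zipf(1.0) frequencies; four ordered suffix slots —
  derivational, inflectional, possessive, clitic — with fixed short
  Finnish-flavoured inventories, attachment probabilities 0.22 / 0.55 /
  0.12 / 0.15 and Zipf(0.8) within-slot frequencies. Words therefore
  carry 1-5 morphs, with bimorphemic forms most common, and a broad
  length range (roughly 4-14 letters).
* **Paradigm cap.** Each stem attests at most 8 suffix combinations. Real
  paradigms are used sparsely; without the cap the combinatorial space
  floods the vocabulary with singleton types and the token/type ratio
  collapses to ~3, two orders of magnitude thinner than a real corpus.
  With it the default corpus has roughly 3,000 types.
* **Corpus size: 600,000 tokens.** The granularity that minimises the
  two-part cost at a given alpha depends on corpus scale: with too few
  tokens the lexicon term dominates at every alpha and even alpha = 0.01
  collapses to single letters; with vastly many, every alpha stores full
  forms. 600k tokens puts the three study values of alpha on the intended
  regimes at desk scale — alpha 0.01 recovers gold morph boundaries
  (boundary F1 around 0.85-0.9 across seeds), alpha 0.8 yields a mixed
  segmentation, and alpha 10 stores full forms (mean 1.00 morphs per
  stimulus word).
* **Stimuli.** 300 uniform vocabulary draws plus 60 draws from the top
  frequency quartile (the uniform sample over-represents rare words), no
  two targets sharing a stem; 360 pseudowords generated from a letter
  trigram model (additive 0.1 smoothing) with lengths matched exactly to
  the targets and membership in the vocabulary rejected.
* **Measures.** The generative model for the simulated measures is
  linear-Gaussian on the bit scale, matching the analysis model by
  design: FFD carries the early predictor's effect (default 8 ms/bit),
  GmF the late predictor's (default 25 ms/bit), GD = FFD + GmF, and
  durations are rounded to whole milliseconds. Intercepts (244/537 ms
  single-word; 306/484 ms word-row) follow the descriptive means of the
  emulated design. GmF is set missing with probability 0.02 (single-word)
  or 0.37 (word-row), the complements of the 98% / 63% multi-fixation
  rates of the emulated experiments. Reaction times equal GD plus an
  offset and Gaussian noise scaled so that corr(RT, GD) >= 0.98, which is
  why RTs are not analysed separately. Per-subject error rates follow a
  Beta(2, 38) distribution (mean 5%). Word-row trials draw launch sites
  from a Gamma(2, 1.5) distribution at quarter-letter resolution and add
  a per-subject position slope (SD 10 ms).
* **Fixation emission.** Two fixations per multi-fixation trial (FFD,
  then GD - FFD); since the measures are sums, richer sequences would add
  realism but no information. Word-row trials walk the seven areas left
  to right, with the fixation before each target placed so that the
  computed launch site reproduces the drawn one exactly. The round trip
  simulator -> fixation report -> measure computation is exact by
  construction, and the test suite asserts it.

What passing tests on these data do **not** show: that the models'
ranking on real Finnish eye-tracking data would be reproduced. The
synthetic lexicon has no homography beyond accidental collisions, no
orthographic neighbourhood structure, no semantics, and its measure
generator contains exactly the effects the analysis looks for. The tests
show that the machinery — cost function, search, scoring, measure
computation, exclusion rules, model comparison — recovers known structure
at realistic sizes, which is the precondition for the scientific claims,
not the claims themselves.

## Numerical choices

* Logarithms are base 2 throughout; all information quantities are bits.
* Cost ties in training and the brute-force oracle are resolved at
  tolerance 1e-6 bits by preferring fewer morphs, then the longer
  leftmost morph.
* Token counts (not type counts) weight the corpus term by default, so
  surprisal is frequency-sensitive; `use_type_counts` switches this.
* Trainer state is rebuilt from scratch at every epoch boundary to cancel
  floating-point drift in the incremental cost bookkeeping.
* The per-word exact-enumeration threshold is ten characters (1,024
  candidates); beyond it the DP proposal is used. Convergence is declared
  when the relative per-epoch cost decrease falls below 1e-4 (default),
  with a warning flag — never an error — if the epoch budget runs out.
* Mixed models use `lme4::lmer` defaults with derivative checks off;
  singular fits are tolerated (they are the expected outcome of the
  OLS-limit tests).
* Problem sizes in the test suite: toy corpora for the oracle comparison
  stay within ~200k joint segmentations; calibration checks use 500
  replicates (null distribution) and 100 replicates (recovery) at 15-20
  subjects and 20-30 items; end-to-end dissociation uses 20 replicates at
  the design's own 24 subjects and 360 items.

## Design choices where the design was open

* **Exclusion order** (errors -> subject exclusion -> trimming) follows
  the narrative order such studies report; the rules themselves, not
  their order, are what the literature states.
* **15% criterion** is a strict inequality ("exceeded").
* **Launch-site units** are letters, positive for launches from the left;
  and are computed from the immediately preceding fixation under an
  adjacency assumption.
* **LRT for the delta-deviance p value** with df = 1 per added surprisal
  column; the comparison framework (deviance decrease + AIC) does not
  itself prescribe a test.
* **Re-analysis at scoring time** (Viterbi) rather than reusing
  training-time segmentations for stimulus words: it is the only option
  for out-of-corpus queries and coincides with the training segmentation
  in the common case.
* **Smoothing** of the supervised n-gram models is interpolated absolute
  discounting with discount 0.5; any value in (0, 1) may be supplied, and
  a held-out split can be used to choose it when that matters.
* **The category HMM is flat**: a hierarchical-lexicon variant would
  change the lexicon prior, not the property under test here.

## Known limitations

* The brute-force oracle equivalence is only verifiable for tiny corpora;
  at scale, the restart set bounds but does not eliminate the risk of
  local optima.
* Launch sites require the fixation immediately before first target entry
  to lie in the adjacent area; skipped intervening areas would bias the
  computed distance.
* Exp2 skipping ("skipped" rows) is only computable when the target map
  is supplied explicitly, since skipped targets leave no trace in a
  fixation report.
* The letter-byte mapping caps the alphabet at 94 distinct characters.
* Type-level letter probabilities are held fixed during training; a fully
  adaptive lexicon prior would couple the letter distribution to the
  current lexicon.
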