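---
title: "Modeling spoken-word recognition in noise with a bilingual autoencoder"
author: "noisylex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spoken-word recognition in noise with a bilingual autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When listeners recognize a spoken word, phonologically similar words are
co-activated and compete for recognition.  Background noise is known to
enlarge this *competitor space*: listeners produce more distinct
misperception errors in offline identification tasks, and eye-tracking
studies show that looks to onset competitors persist longer when noise is
added.  Non-native listeners show the same effects, amplified.  `noisylex`
implements a neural-network model of this process, together with the
simulated experiments and the analyses of the network's internal states
that make the competition mechanism inspectable.

## The model

The core is a deep autoencoder with two input/output pathways that meet in
a shared bottleneck:

```
phonology (292) -> P0 (200) -> P1 (120) \
                                         >-> PS2 (80)
semantics (300) -> S1 (120)             /
PS2 -> P3 (200) -> phonology out (292)
PS2 -> S3 (120) -> S4 (200) -> semantics out (300)
```

All units are logistic.  Training presents three kinds of mapping in
interleaved minibatches: phonology alone (reconstruct phonology),
semantics alone (reconstruct semantics), and both presented simultaneously
(reconstruct both).  The network is **never given a supervised
phonology-to-semantics mapping**; the ability to produce a word's meaning
from its sound alone emerges because both modalities are forced through
the same bottleneck.  Spoken-word recognition is tested by presenting a
phonological form with the semantic input at zero and decoding the
semantic output with a nearest-neighbour rule (Euclidean distance over the
vocabulary's semantic vectors).

Two *versions* of the model differ only in their linguistic environment:
during fine-tuning, words are drawn from the two languages in a 3:1 or 1:3
ratio.  The majority language of a version is its "native" language.  Both
versions see exactly the same total number of training presentations, so
any performance asymmetry is an exposure effect, not a training-amount
effect.

### Representations

*Phonology.*  Words (mono- or disyllabic) are phoneme sequences fitted
into a 13-slot template `CCCVVCCCVVCCC` with left-alignment inside each
syllable; e.g. a disyllable like *carrot* (`kh {` + `r @ t`) aligns to
`kh _ _ { _ r _ _ @ _ t _ _`.  Each occupied slot carries a 22-bit
articulatory feature row from a fixed inventory shipped as
`inst/extdata/phoneme_features.tsv` (consonant place 6, manner 7, voicing
1, vowel height 4, backness 3, length 1).  Two thermometer-coded length
bits (`01` monosyllabic, `11` disyllabic), two one-hot stress bits and two
one-hot language bits complete the 292-bit vector.  Left alignment encodes
"time into space": the leftmost slots are populated by every word, the
rightmost only by disyllables, which makes onsets more informative than
offsets — the asymmetry that drives onset-competitor effects.

Design choices worth flagging: the published account of this scheme left
the per-slot feature inventory and the placement of syllable-2 onsets
under-determined.  We fix 22 features as above (preserving the 292-bit
total and the onset-similarity structure) and place syllable-2 onset
consonants in the shared consonant band (slots 6–8), left-aligned after
syllable 1's coda; a word whose coda plus following onset overflow the
band is rejected.  This rule is deterministic and testable, and it
reproduces the worked alignment above exactly.

*Semantics.*  Meanings are 300-bit sparse binary vectors; translation
equivalents share one identical vector.  Real-valued embeddings can be
imported and binarized with the strict threshold rule `bit = 1 iff value <
-0.175` (`binarize_embedding()`); by default the synthetic generator is
used instead (below).

### Training

Training couples two standard techniques: greedy layerwise pretraining of
the encoder stack (50 epochs per layer, throwaway decoders) and denoising
fine-tuning.  Every fine-tuning presentation corrupts the presented inputs
with Gaussian noise (SD 0.1) and, in the joint mapping type, masking
noise: with probability 0.5 one modality's input is zeroed while both
targets stay clean.  This masking corruption is the ingredient that makes
the cross-modal mapping emerge; with Gaussian corruption alone the
phonology-only semantic readout stays far from ceiling.  Optimization is
minibatch gradient descent with classical momentum 0.9 (one step per
mapping type per epoch); defaults are learning rate 0.05, batch 128, 5000
epochs, chosen as the smallest budget at which the native-language clean
identification accuracy reaches ceiling (>= 0.9, in practice 1.0) on the
default 121-pair lexicon.  All of these are arguments of `finetune()`.

## The synthetic lexicon

`generate_synthetic_lexicon()` is first-class, tested code, not a test
hack: it emulates the statistics of the bilingual training vocabulary the
simulations assume — 121 translation pairs, 39 disyllabic words in
language A and 45 in language B (the rest monosyllabic), phonotactically
valid forms sampled from the fixed ~40-symbol inventory, and sparse binary
semantics with an expected 52.7 ones over 300 bits.  Semantic structure is
cluster-based: 12 cluster prototypes are drawn with independent
Bernoulli(52.7/300) bits and each pair resamples 10% of its prototype's
bits, which leaves the expected popcount unchanged while giving the
semantic space the neighbourhood structure that makes nearest-neighbour
decoding non-trivial.  Words have at least two phonemes (the masking and
incremental regimes need a word-initial/word-final split).

What the generator does *not* emulate: real lexical statistics (frequency,
phonotactic probability, morphology), graded within-pair semantic
differences between translations, and the particular neighbourhood
densities of English/Dutch.  Passing tests on this lexicon therefore show
that the mechanisms behave as designed under controlled conditions, not
that the model quantitatively fits any particular human dataset.

## The simulated experiments

*Offline identification* (`run_offline_experiment()`): full factorial over
model version, noise SD (0, 0.30, 0.60, 0.90), and noise position.  Noise
is Gaussian, added only to the feature bits of occupied slots; the
word-initial set is the first ⌈k/2⌉ phonemes and the word-final set the
rest — a deterministic stand-in for per-word masking inventories, which can
be overridden.  Offline inputs carry the target language's unit and no
prosody.  Responses are scored by the nearest-neighbour rule; the
`unique_misperceptions()` measure counts distinct wrong responses per
incorrectly identified word.

*Online visual-world* (`run_online_experiment()`): words are presented
incrementally (phonemes 1..t at timestep t, all-zero input at t = 0), with
no language unit and no prosody.  Each display holds a critical item (the
target, or its onset competitor — the same-language word sharing the
longest phoneme prefix) and three distractors chosen to be jointly far
from target and competitor in both phonology and semantics.  At each
timestep the model "looks" at the display item whose semantics is closest
to the semantic output.  The looking preference is `log((looks_critical +
0.5) / (mean distractor looks + 0.5))` minus its value at t = 0.  The 0.5
smoothing guards the ratio against zero counts, and the baseline is
subtracted *after* the log so that the correction is well-defined for any
counts; L(0) = 0 holds exactly by construction.  Because the distractors
are chosen adversarially far from the target, late looks in the
competitor condition drift toward the competitor; we therefore summarize
the competition phase as the mean baseline-corrected competitor
preference over timesteps 2–4, which noise reliably raises (prolonged
competition) while it lowers the target preference at full presentation.

*Input-based baseline* (`input_based_identify()`): no network, no
training — the response is simply the vocabulary word with the closest
phonological form to the input.  Its native/non-native outputs are
*identical by construction*, which is the mechanism behind its inability
to capture group effects.

## Mechanistic analyses

`run_mechanistic()` presents all target-language words incrementally
(clean vs. SD 0.75) and computes, per layer (input, PS2, S4, output):

- *online accuracy*: fraction of words whose semantic output is rank-1;
- *cumulative unique misperception errors*, frozen once a word is first
  recognized;
- *rank-order closeness to the target*: the position of the target's
  reference pattern among all words' references sorted by Euclidean
  distance to the current activation (rank r means r−1 spurious words
  outperform the target).  References are the semantic vectors (output
  layer), the full phonological encodings (input layer), and the
  activations elicited by the clean full form presented together with its
  semantics (hidden layers);
- *interlingual variants*: the rank of the best nontarget-language word,
  indexing cross-language competition;
- *RSA*: per layer and timestep, a cosine-distance RDM over words,
  correlated (Pearson, strict upper triangle) with the RDMs of the
  training set's phonological and semantic representations.  The upper
  triangle avoids double-counting the symmetric entries and excludes the
  zero diagonal.

## Numerical choices and degenerate inputs

- Euclidean nearest-neighbour ties break by lexicon order, recorded and
  deterministic.
- Zero-norm activations in an RDM are defined as maximally dissimilar
  (distance 1); a constant RDM yields a missing RSA correlation rather
  than an error.
- Noisified inputs are not clipped to [0, 1]; the network consumes real
  inputs.
- `t` beyond a word's length clamps to the full form, so short words hold
  their final state over the analysis horizon (t = 0..5).
- Zero-variance bins in the binwise one-tailed t-tests report t = 0,
  p = 0.5 when all items equal the baseline, and a missing p otherwise.
- The effect model replaces the original random-effects structure with a
  fixed-effects binomial GLM plus cluster-robust standard errors (one
  cluster per trained network); noise intensity enters scaled to [0, 1].
  Under this coding the noise, position and group effects on accuracy are
  all expected negative.

## Problem sizes

The test suite exercises the full pipeline at a reduced scale chosen to
keep the default run fast: a 20-pair lexicon with 5 trained replications
per version (1000 epochs, batch 64), which reaches the same ceiling
property as the full configuration.  `scripts/acceptance.R` recomputes the
headline quantities at the full lexicon size (121 pairs) with 2
replications per version.  Both scales are the package's own choices; all
parameters scale up via `experiment_config()`.

## Known limitations

- The phoneme feature table is a plausible articulatory inventory, not a
  published standard; only its structural properties (injectivity,
  22 bits, C/V typing) are load-bearing.
- Binary slot phonology plus additive Gaussian noise abstracts away from
  real speech acoustics; speech-shaped noise, coarticulation and duration
  are out of scope.
- Exposure ratio is the only proficiency parameter; there is no age of
  acquisition, no frequency weighting, no cross-language phonetic
  interference.
- The architecture is feed-forward; incremental presentation is simulated
  by re-presenting growing prefixes, not by recurrent dynamics.
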