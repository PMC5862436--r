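---
title: "Decoding sensory event properties from the phonology of onomatopoeia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sensory event properties from the phonology of onomatopoeia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The scientific problem

When people improvise a word for a noisy physical event — a ball bouncing,
an object sliding, a bell ringing — the sounds they choose are not
arbitrary. Across a cohort of speakers responding to audio (A), visual (V)
and audiovisual (AV) renditions of such events, two regularities dominate:

* **Movement type** (hit / slide / ring) is carried by the *manner of
  articulation* of the consonants: hits attract plosives, slides
  fricatives, rings liquids and nasals.
* **Object shape** (in V) and **sound frequency** (in A and AV) are
  carried by the vowels: spiky shapes and high-pitched sounds attract
  front unrounded vowels, rounded shapes and low-pitched sounds back
  rounded vowels — the vowel side of the bouba/kiki effect.

`onophon` implements the complete quantitative chain needed to establish,
decode and transfer these codes, together with a synthetic corpus
generator that plants them at tunable strength so that every stage can be
validated end to end without access to any particular set of recordings.

## Phonological representation

Words are IPA strings. Each inventory symbol maps to a binary 12-vector
of distinctive features, in the fixed order *(sonorant, syllabic,
consonantal, continuant, nasal, high, low, back, round, anterior,
coronal, voiced)*; e.g. /f/ = `001100000100`. The same symbols are also
classified by 14 IPA chart flags: four consonant places (radical,
dorsal, coronal, labial), four manners (plosive, fricative, liquid,
nasal), voicing, three vowel heights (open, mid, close), vowel roundness
and backness. The two systems are linked by wildcard patterns (a labial
is `+anterior −coronal`, a fricative `−sonorant +continuant`, and so
on); `derive_ipa_from_distinctive()` implements the mapping and the test
suite checks it exhaustively against the shipped chart.

A word becomes a phoneme × feature binary matrix and is then collapsed
to its column means — the *feature profile*, a vector in $[0,1]^d$ whose
entries are the relative weights of each feature in the word. Averaging
deliberately discards temporal structure (reduplication, segment
length); nothing downstream sees phoneme order.

```{r encode}
library(onophon)
tab <- load_feature_table()
p <- encode_record(tab, "fuŋ", system = "distinctive")
round(unclass(p), 2)
```

The shipped chart (`inst/extdata/feature_chart_synthetic.csv`) is a
reconstruction compiled from standard distinctive-feature analyses of
the IPA, not a copy of any study's deposited decomposition; it covers 35
canonical symbols, including all 26 basic Latin letters so that
orthographic forms can be treated as IPA homographs. Chart cells holding
two symbols are handled by an *absorption map* shipped inside the file
(ɪ→i, ɛ→e, θ→s, …): every symbol resolves to a unique point in
feature space. Input is normalized to Unicode NFC; under the `skip`
tokenization policy an unknown character is first stripped of combining
diacritics and retried before being dropped.

### Machine-learning feature subsets

The classifier operates on 13 of the 14 IPA flags (voicing excluded):
all 13, the 8 consonant features, or the 5 vowel features. Subsetting is
a *column selection* of the all-phoneme average, so a vowel-only word
has a legitimate all-zero consonant profile rather than missing values.
The alternative reading — re-averaging over only the phonemes of the
relevant class — is available as `subset_method = "reaverage"`; the two
differ by a factor equal to the class's share of phonemes, and column
selection is the default because the projection-then-selection order
matches the stated analysis.

## The synthetic corpus generator

`generate_corpus()` emulates the study design exactly: 19 speakers ×
(6 A + 12 V + 24 AV) stimuli = 798 words, where A crosses 3 movements ×
2 sound frequencies, V crosses 2 shapes × 2 sizes × 3 movements, and AV
crosses all four factors. Words are built from CV skeletons (CV, CVC,
CVCV, CVCVC, CVCVCV with probabilities 0.15/0.30/0.25/0.20/0.10 —
chosen once as a plausible word-length law, since no empirical
distribution is published, and documented as arbitrary). Templates
guarantee that every word carries both consonant and vowel features.

Consonant slots draw a manner class from
$(1-\beta_m)\,\text{uniform} + \beta_m\,\text{code}(movement)$,
then a phoneme uniformly within the class; vowel slots draw a
front/back class likewise with strength $\beta_v$ from the shape code
(V) or the sound-frequency code (A, AV). Speaker idiosyncrasy adds one
normal offset per speaker and class on the log-probability scale
(scale $\sigma$), drawn once per speaker, so generated words always
remain valid inventory phonemes. Two switches control the multisensory
structure: `av_coupling` (default on) makes AV vowels depend on sound
frequency plus a movement bias while suppressing the shape effect —
the multisensory finding — and `v_movement_channel = "place"` moves the
visual movement code from manner to place of articulation, which is the
construction used to study transfer failure.

**Defaults.** The design counts, factor levels and cohort size are fixed
by the study being emulated. The effect strengths are the generator's
own emulation targets: $\beta_m = 0.65$, $\beta_v = 0.75$,
$\sigma = 0.5$ were selected during generator design by a coarse grid
scan so that the emulated corpus carries planted effects of the
magnitude the study reports (movement decoding from consonants
$\varphi \approx 0.68$, shape/sound decoding from vowels
$\varphi \approx 0.5$), and then frozen. They are conditions of the
simulation, not fitting parameters; all validation below treats them as
given.

What the generator does *not* emulate: temporal/reduplicative structure
(excluded from the representation anyway), object size effects (the
study found none), transcription noise, and cross-speaker phonotactic
preferences beyond class-level logit offsets. Tests passing on this
corpus therefore show that the pipeline recovers what was planted, not
that any particular natural corpus carries such structure.

## Feature screening

`run_anova_screen()` runs one ANOVA per feature (12 distinctive + 14
IPA = 26), factor and modality, with subjects as random factor. The
default is the classical repeated-measures reading: a one-way ANOVA on
per-speaker condition means with speaker as the error stratum. A mixed
model with random speaker intercepts on per-trial profiles
(`method = "mixed"`, via lmerTest) is provided as an alternative since
the exact model behind "subjects as random factor" is underdetermined;
the two agree on planted effects. Significance uses the Bonferroni
threshold $\alpha/26$ jointly across features — for $\alpha = 0.01$,
$p < 0.01/26 \approx 0.00038$.

`deviation_patterns()` reproduces the ±3 s.d. deviation maps: for each
condition level and IPA feature, the level mean is standardized against
the modality-wide mean. The standardizing unit matters. Dividing by the
s.d. over all per-speaker condition-level means (or over trials) bounds
$|z|$ near $\sqrt{2}$ on a three-level factor *however strong the
effect*, because the between-level variance sits in the denominator —
under that unit a ±3 s.d. rule can never fire. The default unit is
therefore the standard error of the level mean across speakers, under
which strong planted codes produce the expected `+`/`−` patterns (hit
`+` on plosive, slide `+` on fricative, ring `+` on liquid/nasal);
`unit = "speaker"` and `unit = "trial"` remain available for
small-threshold exploration. A zero-s.d. cell is labelled `0` with a
warning, and `k_sd = 0` degenerates to sign-of-deviation labels.

`feature_correlations()` gives the Pearson matrix over profile columns
(with pairwise p-values); anatomically coupled features correlate by
construction — nasals are voiced, so *nasal* and *voiced* are positively
correlated on any inventory-faithful corpus.

## Decoding

`fit_lda()` is a pooled-covariance linear discriminant with class priors
equal to training frequencies. Averaged binary profiles make collinear
and zero-variance columns routine, so the pooled covariance is shrunk
toward its diagonal with a small fixed coefficient ($10^{-4}$, plus an
absolute ridge of $10^{-8}$): deterministic, minimal distortion, and
sufficient for duplicated columns. On well-conditioned data its
predictions match the classical discriminant (cross-checked against
`MASS::lda` in the tests, which is never used as the implementation).

Cross-validation is *speaker-grouped*: `speaker_grouped_folds()`
partitions speakers (not items) into k groups differing in size by at
most one — 19 speakers in 10 folds give nine groups of two and one
singleton — so no speaker ever contributes to both training and test,
and the suite asserts this in every fold. `decode_within()` repeats the
whole k-fold procedure (default k = 10, 1000 repetitions; analyses here
use 100 or fewer to keep runs desk-scale, which leaves the medians
essentially unchanged since the repetition spread is a few hundredths)
with fresh folds per repetition, each repetition producing a
row-normalized confusion matrix and a macro-averaged Matthews
coefficient $\varphi$ (the unweighted mean of one-vs-rest binary
$\varphi$; degenerate margins score 0 by convention). Repetitions are
summarized by median and IQR; the mean is also logged. If a repetition's
random folds leave some class with fewer than two training items, folds
are re-drawn with a warning.

`decode_cross()` trains the k fold-classifiers in one modality exactly
as in the within-modality analysis and lets each predict the full
record set of another modality; the k confusion matrices and
coefficients are averaged within a repetition, then median/IQR taken
across repetitions. Results carry a manifest (target, subset, seed,
folds, repetitions, class levels), and every randomized stage derives
per-repetition seeds from one master seed, so identical calls replay
byte-identically.

```{r decode, eval = FALSE}
corp <- generate_corpus(synth_config(seed = 1))
decode_within(tab, corp$records, "movement", modality = "AV",
              subset = "consonant", reps = 100, seed = 1)
```

The shape/sound problem in AV is decoded as the 4-class
shape × frequency task, from which the 2-class marginals are derivable;
A and V use the 2-class sound and shape tasks respectively.

## Cross-linguistic application

`ingest_wordlist()` reads an action/language/form table, treats
orthography as IPA (tokenization policy `skip`), drops forms losing more
than half their characters, resolves duplicate (action, language) rows
last-wins, and enforces a 10-language floor per action.
`classify_actions()` applies a trained AV all-features movement
classifier to each form and tabulates per-action proportions of
languages assigned to hit/slide/ring; `compare_to_ratings()` correlates
these with human percentage ratings (renormalized per rater and action,
then averaged; the average-then-normalize order is also reported, and a
zero-variance side yields r = 0 by convention). `generate_wordlist()`
plants known movement mixtures and noisy ratings so this stage is
testable; on such lists the correlation is high by construction.

## Numerical and design choices

* Feature order and naming are fixed package-wide; serialization is
  UTF-8, tab-delimited, NFC-normalized (IPA breaks naive CSV quoting).
* Profiles are exact rational means: value × phoneme count is an
  integer, asserted in the tests.
* $\varphi$ computations are done in double precision from counts;
  macro-averaging over a 2-class problem provably equals the binary
  coefficient, and the binary coefficient is cross-checked against the
  Pearson correlation of the underlying binary assignment vectors.
* Degenerate inputs fail loudly and early: empty words, unknown
  symbols under `strict`, constant factors in the screen, k exceeding
  the speaker count, classes absent from a test modality.
* The repository-level analysis surface is functional (a fitting
  function returning a classed `ono_lda` object with `print`/`coef`/
  `predict` methods, decoding runs returning classed summaries with
  `print`/`summary`) rather than a single monolithic model object — the
  chain has several distinct stages and this keeps each reusable.
* No shell entry point is shipped: the exported functions, this
  vignette and `scripts/acceptance.R` are the interface for
  reproducible runs.

## Known limitations

* Orthography-as-IPA is a rough approximation (digraphs like English
  *sh* segment as two phonemes) and cross-linguistic lists carry
  historical relatedness (the Galton problem); neither is corrected.
* Exact ANOVA p-values depend on the unit of analysis
  (per-trial vs per-speaker means), which is underdetermined; only the
  significance pattern is treated as reproducible.
* The generator plants class-level codes with logit-normal speaker
  noise; it does not model phonotactics, transcription disagreement or
  word-length dependence on condition, so absolute decoding levels on
  real corpora may differ from the emulation.
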