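---
title: "Scoring divergent semantic integration: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring divergent semantic integration: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsitext)
```

## The construct and the statistic

Divergent semantic integration (DSI) quantifies one component of creativity
in a narrative: the extent to which the text connects ideas from divergent
semantic contexts. Under a distributional-semantics representation each word
(or word piece) of a story is a vector $\omega \in \mathbb{R}^d$, and DSI is
the mean cosine distance over all unordered pairs of the story's $n$
embeddings:

$$\mathrm{DSI} = \binom{n}{2}^{-1} \sum_{i<j} D_{\cos}(\omega_i, \omega_j),
\qquad D_{\cos}(\omega, \kappa) = 1 - \frac{\omega \cdot \kappa}
{\lVert\omega\rVert\,\lVert\kappa\rVert}.$$

A story that stays in one topical neighbourhood scores near 0; a story whose
words come from mutually unrelated contexts scores near 1 (random directions
in high dimension are nearly orthogonal); 2 is the antipodal bound.

**Denominator.** Some presentations print the divisor as $n$ while describing
the statistic as an average over "all word pairs". We divide by the pair
count $\binom{n}{2}$: only that reading yields a mean with the documented
$[0, 2]$ range, and it is what the package's oracle tests assert.

`dsi()` evaluates the mean through the identity
$\sum_{i<j} u_i\!\cdot\!u_j = (\lVert\sum_i u_i\rVert^2 - n)/2$ for
unit-normalized rows, which is $O(nd)$; the $O(n^2 d)$ brute-force double
loop lives in the test suite as an independent oracle and the two must agree
to $10^{-10}$.

## Preprocessing: two routes

*Static (context-independent) models* score content words only: text is
lowercased and tokenized; stop words (the 174-word English snowball list,
shipped as a data file so other lists can be swapped in), numbers and
punctuation are removed. Words are deliberately **not** stemmed and **not**
spell-corrected; out-of-vocabulary tokens are treated as missing data and
counted in the `dropped` diagnostic. Repeated tokens keep one vector per
occurrence.

*Contextual models* need the full sentence, so nothing is removed except
non-printable/control characters (and the Unicode replacement character).
Sentences are encoded independently; each token piece contributes one vector
per requested hidden layer (default layers 6 and 7 of a 24-block encoder,
1-indexed over the blocks with the input-embedding layer not counted — the
convention is exposed as configuration because published index conventions
are ambiguous). The default pairing pools all vectors from both layers and
takes all pairs, including same-token cross-layer pairs; `within_layer` and
`cross_layer` pairings are provided for sensitivity analysis, as is a flag to
exclude punctuation vectors from scoring (they are included by default, since
the contextual route removes nothing).

Sentence splitting is a deterministic rule: a run of `.`/`!`/`?` followed by
whitespace ends a sentence, unless a lone period follows a known
abbreviation. No published splitter is canonical for this statistic;
contextual scores can shift slightly with splitter choice, which is one
reason the splitter here is small, documented, and deterministic.

## Embedding backends

- `embed_static()` looks tokens up in a `vector_table` loaded from
  word2vec-text or GloVe-text files (`load_vector_file()`, dialect
  auto-detected from the two-integer header line).
- `embed_contextual()` is written against an encoder interface. The package
  ships a deterministic synthetic encoder (`synthetic_encoder()`); real
  transformer weights can back the same interface, but no deep-learning
  runtime is assumed or required by the tests. Sentences beyond the encoder's
  input budget are chunked at the boundary with a warning — a rare fallback
  for short narratives.
- `embed_synthetic()` maps every token to a unit pseudo-random vector keyed
  by `(token, seed)`; in contextual mode each layer returns
  `normalize((1-λ)·v_token + λ·v_sentence)` plus a distinct per-layer
  perturbation. It is bit-reproducible and RNG-isolated (the caller's
  `.Random.seed` is never disturbed).

## The synthetic world and what a green test establishes

`generate_stories()` emits symbolic stories whose tokens come from `c` topic
clusters: token `anchorBxxvCD` decodes (in the synthetic backend only) to a
cluster centroid plus `dispersion`-scaled variant noise. Expected DSI rises
from ≈0 (one cluster, zero dispersion) toward ≈1 as `c` grows, because a
fraction $1 - 1/c$ of pairs crosses near-orthogonal centroids. Defaults
(stories of ~100 words, dispersion 0.3, a 12-anchor pool) were chosen once to
mimic short creative stories — the corpora this statistic is used on average
roughly 40–90 content words — and to keep within-cluster distances clearly
below between-cluster distances without making stories degenerate.

`generate_ratings()` simulates raters as `a·z(score) + ε`,
`ε ~ N(0, noise_sd²)` i.i.d. per rater and story, mapped onto the 1–5 rating
scale by one global linear rescaling (this preserves rank order and Pearson
correlations exactly, unlike clipping). The closed-form attenuation
`cor(score, mean rating) = a / sqrt(a² + noise_sd²/k)` is asserted in tests.

What the synthetic world does **not** contain: real lexical statistics,
syntax, discourse structure, topic drift within a cluster, rater leniency or
fatigue. A green parameter-recovery test therefore establishes that the
pipeline orders topical divergence correctly — not that any particular
correlation with human ratings will be observed on real data.

## Text-length audit

`length_curve()` truncates every story to a common token length `L`, draws
`floor(L/w)` disjoint random subsections of `w` tokens (uniformly, without
replacement; the `L mod w` remainder is discarded, matching the published
designs), scores each, and averages. Positions are re-sorted within a
subsection so that at `w = L` the single "subsection" is the full story in
original order and reproduces the full-story score bit-for-bit. Subsections
destroy sentence integrity, so a subsection is scored as a single
pseudo-sentence; how the original analyses fed non-contiguous word samples to
a sentence-contextual encoder is unstated, and this is our documented choice.
The audit reports per-length distributions and the cross-length correlation
matrix; on the synthetic corpus the `w = 50` means correlate > .9 with
full-length scores and across-seed variability shrinks as `w` grows.

## Covariates

The incremental-validity battery: word count (non-punctuation tokens;
word-internal hyphens/apostrophes keep a word whole), Flesch–Kincaid grade
level (`0.39·w/s + 11.8·syl/w − 15.59`, with a rule-based vowel-group
syllable counter plus a small exception table — absolute values can differ
from other implementations; rank order is the stable quantity), mean
frequency / prevalence / age-of-acquisition over a user-supplied norm table
(license-restricted norms are not bundled; a tiny synthetic table ships for
tests; frequency is conventionally log10 per-million — supply whichever scale
your norms use), and MTLD (threshold 0.72, partial factor
`(1−TTR)/(1−0.72)`, mean of forward and reverse passes; undefined when no
factor completes in either direction).

## Psychometric functions: numerical choices

- Correlation CIs use the Fisher z transform with SE $1/\sqrt{n-3}$.
- The dependent-correlation test is Steiger's $Z_1^*$ (Fisher-z statistic
  with the covariance term evaluated at the back-transformed mean
  correlation); the CI for the difference is Zou's (2007). The difference in
  r is independent of the predictor intercorrelation; the z is not.
- `sr_ave` correlates each rater with the mean **including** themselves (the
  literal consensus mean); a leave-one-out variant is behind a flag.
- Omega comes from a one-factor ML fit (`stats::factanal`) on the
  correlation matrix: $\omega = (\sum\lambda)^2 / ((\sum\lambda)^2 +
  \sum\theta)$. **Caveat:** on data with no common factor, ML estimation can
  terminate at a Heywood boundary (a uniqueness at its floor) and inflate
  omega; such fits are flagged (`heywood = TRUE`) and should not be
  interpreted.
- ICCs are the two-way random-effects absolute-agreement forms ICC(2,1) and
  ICC(2,k) from the mean-squares decomposition, with listwise deletion.
- The hierarchical regression bootstraps the ΔR² CI (percentile, 2000
  seeded resamples — the reference implementations do not document their
  method); standardized coefficients come from refitting on z-scored
  variables.
- Cohen's d uses the pooled SD; its CI inverts the noncentral-t distribution
  (normal approximation as fallback). Welch's t is reported; note the pooled
  (Student) t differs slightly when variances differ.

## Degenerate inputs

Scores for stories with fewer than two scorable vectors are `NA` with
diagnostics, never exceptions, in batch mode; zero-norm vectors error before
scoring; all-stop-word stories warn at preprocessing; zero-variance
variables error in correlation functions and are excluded per-rater in
`sr_ave`; perfect collinearity is reported by name in the regression.

## Known limitations

- No real transformer runtime: contextual extraction is exercised through
  the synthetic encoder only; plugging in genuine weights requires
  implementing the small encoder interface.
- The syllable counter (hence FK readability) is heuristic.
- The sentence splitter's abbreviation list is small and English-centric.
- The synthetic corpus is symbolic; see above for what green tests do and do
  not establish.
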