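---
title: "Affect transitions, silence, and content originality: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affect transitions, silence, and content originality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the sequence
model and its assumptions, the statistical layer, the design decisions
that were genuinely open, the synthetic-cohort generator, and what the
test suite does and does not establish.

```{r setup}
library(affectseq)
```

## Sequence model

A posting history is reduced to symbols over the alphabet `+`
(positive), `-` (negative), `m` (mixed), `0` (neutral), and `S`
(silence day). Affect labels are taken as given input — the package
performs no sentiment inference; in real datasets they come from
manual annotation, and inter-rater agreement can be quantified with
`cohens_kappa()` / `average_pairwise_kappa()`.

Three representations of a user's observation window are supported.
The post-level-with-silence stream keeps all post symbols in
chronological order and inserts exactly **one** `S` token per silent
calendar day. One token per silent day (rather than one per silent
gap) makes runs of silent days visible as `S↔S` transitions, which is
essential if silence is to be treated as a first-class state rather
than missing data. The post-level-without-silence stream simply drops
those tokens. The day-level representation maps each window day to a
single symbol with `day_affect()`.

The day aggregation rule has three stages, applied in this order:

1. a day with no posts is `S`;
2. the two *mixed* rules: equally many `+` and `-` posts (both
   nonzero), or as many `m` posts as all other posts combined, give
   `m`;
3. otherwise the strict-plurality symbol wins, and residual ties
   resolve by the fixed precedence `m > - > + > 0`.

Two points here were open design decisions. First, the order of rules
2 and 3 matters for days like `0 0 0 + -`: with the mixed rules first
(the default, following the natural reading of the rule statement) the
day is `m`; a `plurality_first = TRUE` flag flips the order, making it
`0`. Second, plurality ties not covered by the mixed rules (e.g. `+ 0
+ 0`) need a deterministic resolution; the precedence order prefers
the more informative affective symbols and treats mixed as "no clear
single polarity". Determinism was the overriding goal: re-encoding the
same data must give byte-identical sequences.

A known edge case is the published worked-example week this encoding
is tested against: its Monday (`+ -`) is printed as day-level `-` in
the source table even though the identical Sunday pattern is printed
`±`, and the stated tie rule demands the mixed label. The package
implements the stated rule; the tests assert Tuesday–Sunday and
document the Monday cell as internally inconsistent.

Transitions are *bidirectional*: each adjacent ordered pair is counted
under its unordered key, giving 15 types for the 5-symbol alphabet
(`choose(5,2) + 5`) and 6 for the originality alphabet `O/N/S`. A
sequence of length L contributes exactly L − 1 transitions, a
conservation property the tests check against a brute-force
enumeration oracle.

Per-user features for the correlation screen are transition
**proportions**, not raw counts. Counts scale with posting volume,
which is itself filtered on in cohort selection; proportions remove
that confound. Raw totals are retained in the feature table (`total`
column) and pooled per-type counts are attached as the `n_occ`
attribute, mirroring the convention of reporting pooled occurrence
counts alongside a correlation table.

## Cohort selection

`select_cohort()` applies six ordered filters: posting rate ≥ 0.3/day
(about two posts a week) over the user's full posting span; at least
one post in the 7 calendar days ending at CES-D completion; restriction
to the 60-day window before completion; ≥ 20 posts in the window; age
≥ 18; and ≤ 20% non-English posts in the window. All thresholds are
`cohort_config()` parameters. Boundary conventions that had to be
fixed: the rate threshold is inclusive; the "posting span" is first to
last post, inclusive of both endpoint days; the pre-completion week
includes the completion day itself. Language detection is *not*
performed — the per-post language tag is trusted, since in the intended
workflow that judgement is human. Non-English posts inside the window
are dropped from downstream analysis by default (configurable). The
funnel emits a `filter_report` whose chain arithmetic
(`n_out = n_in − n_removed`, each stage's input equal to the previous
output) is enforced by property tests.

## Originality classification

The classifier is deliberately minimal: cosine similarity of unigram
term-frequency vectors after normalization (lowercasing, URL and
punctuation stripping, whitespace collapse). No IDF weighting and no
character n-grams — TF-cosine is the most parsimonious reading of
"cosine similarity" for near-verbatim duplicate detection, and exact
copies score 1 by construction. Retrieval is an interface: the package
ships a deterministic local-corpus retriever (token-overlap ranking)
so results are reproducible; live web search is out of scope.

Thresholds: best similarity > 0.96 ⇒ non-original; in [0.92, 0.96]
with a source whose url/site name contains "lyrics" or "quote"
(case-insensitive) ⇒ potentially non-original; otherwise original.
Both band boundaries are inside the band ("greater than 0.96" leaves
0.96 itself to the keyword band). Potential cases count as non-original
in binary analyses by default (`potential_as_nonoriginal = FALSE`
reverses this) — how borderline cases are tallied is not determined by
the method itself, so the choice is exposed. A post with no retrieved
candidates is original with similarity 0 and a `no_candidates` flag; a
text that is empty after normalization has undefined similarity,
reported as 0 with a warning.

## Statistical layer

- `perm_corr_test()` reports the exact sample Pearson r and a
  two-sided permutation p with the add-one estimator
  p = (1 + #{|r_b| ≥ |r|})/(n_perm + 1), which is never zero and makes
  the attainable minimum 1/(n_perm + 1). A tolerance of 1e-12 in the
  exceedance comparison prevents floating-point ties from being
  miscounted. Defaults n_perm = 10,000.
- `bootstrap_ci()` is a percentile interval over paired resamples
  (default n_boot = 2,000, level 0.95); degenerate resamples (a
  constant coordinate) are redrawn with a retry cap. The percentile
  method was chosen over BCa for transparency at these sample sizes.
- Tiers: p < 0.01 "significant", p < 0.05 "trend". With around a
  hundred correlations per screen, the stricter tier plays the role of
  an informal multiplicity guard; no formal correction is applied by
  default, but `bh = TRUE` adds a Benjamini–Hochberg column.
- `partial_corr()` uses the closed-form first-order formula with a
  t-approximation on n − 3 degrees of freedom; a permutation variant
  (shuffling one set of control residuals) is available behind
  `method = "permutation"`.
- `mann_whitney()` reports U with a tie-corrected normal
  approximation (no continuity correction); tests cross-check it
  against both a pair-counting oracle and the standard implementation.
- `normality_check()` delegates to the standard Shapiro–Wilk routine.
- `correlation_screen()` derives one seed per scale × feature pair
  deterministically from the base seed, so identical inputs give
  bit-identical tables. Constant feature columns (transition types
  nobody exhibits) produce `NA` rows tiered "ns" rather than errors.

## Synthetic-cohort generator

The generator exists so the full pipeline — reading, filtering,
encoding, classifying, screening — can be validated end to end with
known ground truth. Its structure:

- **Profiles.** (ope, con, ext, agr, neu, swl, cesd) are drawn jointly
  from a correlated multivariate normal and mapped to their scales
  (traits to [1, 5], SWL to [1, 7], CES-D rounded into [0, 60]). The
  default correlation matrix encodes the expected sign structure:
  CES-D rises with neuroticism (r = 0.5) and falls with
  conscientiousness, extroversion and life satisfaction. CES-D is
  generated jointly with the traits rather than as their causal
  response: the mediation claim being modelled is correlational.
- **Posting dynamics.** Each user follows a day-level Markov chain
  over the five states. Trait effects act additively on the *logits*
  of named transitions (per SD of the trait), which keeps rows
  stochastic for any effect size. Defaults: extroversion +0.35 on
  `+→+`, agreeableness −0.35 on `-→-`, neuroticism +0.20 on `+→-` and
  `-→+`. These magnitudes were calibrated once so that the pipeline
  recovers correlations in the weak-to-moderate band (|r| ≈ 0.25–0.35
  at n = 70) typical of trait–behaviour associations, then frozen.
  The base matrix gives each state a persistence bonus over a common
  baseline mix with roughly a third of days silent.
- **Emission.** Active days emit 1 + Poisson(1.2) posts; each matches
  the day state with probability 0.75, else draws from the baseline
  affect mix. This is the day/post duality: posts are noisy readouts
  of an underlying daily mood state.
- **Originality.** Each post is non-original with probability
  plogis(b0 + 0.8·z_neu), intercept set for a ~7% marginal rate;
  non-original posts copy a corpus document verbatim (so the
  classifier's recall on them is 1 by construction), original posts
  get everyday-word token text.

What the generator does *not* emulate: real language (texts are token
salads), circadian or weekday structure, comment/like dynamics,
non-stationarity over the window, annotation noise in affect labels,
and paraphrased (non-verbatim) quoting. Passing tests therefore show
the pipeline's *mechanics* are correct and its statistics are
calibrated — they do not certify performance on real social media
text, where affect labels and near-duplicate detection are much
harder.

One structural subtlety surfaced by testing: because CES-D is bounded
and rounded and the originality link is logistic, the partial
correlation of non-original share and CES-D given neuroticism is not
*exactly* zero in the generated population — both conditional means
are mildly nonlinear in neuroticism, leaving a small (~+0.03)
residual association at the defaults. The mediation check therefore
evaluates the mean partial correlation over several replicate cohorts
rather than one noisy draw.

## Problem sizes in the test suite

The suite exercises: oracle equivalence on 1,000 random sequences (and
exhaustive permutation enumeration at n ≤ 7, 5,040 permutations);
type-I error of the permutation test over 1,000 null replicates at
n = 70 with n_perm = 199 (granularity 1/200 is ample at α = 0.05);
planted-effect recovery over 20 replicate cohorts of 200 users; and
mediation structure over 5 cohorts of 500 users. These sizes were
chosen to give Monte-Carlo error comfortably below the tested margins
while keeping a full run in the minutes range on a single core.

## Limitations

The package analyses labelled data; it contains no NLP beyond
normalization for duplicate detection. The day-level rule discards
within-day ordering. Transition features are first-order only — no
higher-order or continuous-time dynamics. Bootstrap intervals at n ≈ 70
are themselves noisy; they are reported as descriptive companions to
the permutation p, not as the inferential criterion.
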