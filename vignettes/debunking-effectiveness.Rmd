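---
title: "Measuring rumor-debunking effectiveness from comment stances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rumor-debunking effectiveness from comment stances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debunkr)
```

## The measurement problem

When a false rumor spreads on a platform like Sina Weibo or Twitter,
debunking postings counter it in recognizably different ways. This package
encodes a six-way taxonomy: uncited-evidence methods — flat **denial**
(`Den`) and **further fact-checking** (`Fur`) — and cited-evidence methods —
**refutation** by a third party (`Ref`), **person response** (`Per`) and
**organization response** (`Org`) by the slandered party, and
**combinations** (`Com`) of two or three of `{Ref, Per, Org}`
(uncited-evidence methods never participate in a combination). Rumors are
grouped into three categories: *authority* (the rumor slanders an
authoritative person or organization), *society*, and *politics*.

The observable signal of a debunking posting's effect is how users respond
in the replies. Each comment carries one of the four SDQC stances toward
the rumor: **supporting**, **denying**, **querying**, or **commenting**
(no clear stance on veracity). Nested replies are flattened onto their root
posting; comments are the unit, threads are not modeled.

## The indices

For a comment group (all comments under the postings of method $j$ for
rumor $i$, a single posting, or any other grouping):

$$DI = \frac{\#deny - \#support}{\#deny + \#support}, \qquad
  RI = \frac{\#comment}{\#all}, \qquad
  DEI = \frac{DI}{RI}.$$

$DI \in [-1, 1]$ is net denial among the veracity-relevant comments only —
querying and commenting stances are omitted from its numerator and
denominator because they do not contribute to resolving veracity, and the
normalization makes it comparable across rumors of very different comment
volume. $RI \in [0, 1]$ is the share of comments that contribute nothing to
veracity. $DEI$ rewards groups where users clearly deny the rumor *and* do
so without a flood of redundant commentary; it inherits $DI$'s sign and is
unbounded above as $RI \to 0$.

**Degenerate groups.** $DI$ is undefined when a group has neither denying
nor supporting comments; $RI$ is undefined for an empty group; $DEI$ is
undefined when $DI$ is undefined or $RI = 0$. Undefined values are
first-class `NA`s with explicit `*_defined` flags, are excluded from
downstream statistics, and are counted in reports — they are never silently
coerced to zero, because a group of pure querying/commenting traffic carries
no denial information at all.

**Pooled vs per-posting.** Headline per-method tables pool the counts of
all of a method's comments before applying the formulas. Distributional
claims (``does method A beat method B?'') instead use per-posting indices:
each posting's own comment tally yields one $DI$/$RI$/$DEI$ observation,
giving the replication the rank tests need. Both units are exposed
(`effectiveness_table(grouping = ...)`), and `summarize_effectiveness()`
reports mean, normal-theory 95% CI and median over per-posting records.
The pooled value and the mean of per-posting values do not coincide in
general (the pooled ratio weights postings by volume), which is why both
are emitted and neither is presented as the other.

By default the per-method grouping folds all `Com<...>` signatures into a
single `Com` group; `decompose_combinations()` keeps each signature
separate — a triple `Com<a,b,c>` is its own group and is *never* counted
into its constituent pairs, since the indices attached to pair and triple
edges are independent quantities. In graph exports a pair is a solid edge,
and a triple renders as a clique of dotted edges sharing a `triple_id`;
edge weight is the signature's DEI and `n_comments` is its volume.

## Statistical comparisons

`compare_methods()` runs, overall and per rumor:

- a Pearson chi-square test of independence on the method-by-stance
  contingency table (no continuity correction; tables here are large);
- Kruskal–Wallis omnibus tests on per-posting $DI$, $RI$ and $DEI$ across
  methods, with mid-ranks and the standard tie correction; the statistic is
  referred to $\chi^2_{k-1}$;
- Dunn's pairwise $z$ tests on mean-rank differences with tie-corrected
  pooled variance, Bonferroni-multiplied by the number of pairs
  $k(k-1)/2$ and capped at 1. This Dunn–Bonferroni combination is what
  SPSS-style "Adj. Sig." pairwise Kruskal–Wallis output reports, which is
  the convention this package mirrors.

Non-debunking (`Other`) postings get indices for context but are excluded
from method comparisons. Methods contributing fewer than two defined
per-posting values are dropped with a warning; a single-method corpus skips
the omnibus with an explanatory note. P-values are reported as continuous
measures of compatibility with the null model — no star thresholds.

A note on scope: the rank tests assume per-posting indices are exchangeable
within method under the null. Comment volume varies wildly across postings,
so per-posting indices are heteroscedastic estimates; rank tests are used
precisely because they are invariant to monotone distortions and robust to
this, but very-low-volume postings still contribute noisy observations.

## Annotation agreement

`cohens_kappa()` implements unweighted Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, for two annotators over a nominal scheme
(the stance and method taxonomies are nominal, so no weighting is
appropriate). The 95% CI uses the Fleiss–Cohen–Everitt large-sample
standard error under the alternative; the test of $\kappa = 0$ uses the
standard error under the null — a report needs both, and the two SEs
differ. Items either annotator abstained on are dropped and counted. When
both annotators are constant and identical, $p_e = 1$ and kappa is
undefined; this is flagged, not thrown. More than two annotators are out of
scope: a third pass is modeled as pairwise against the consensus.

## The stance-classifier harness

The evaluation harness — `split_train_test()` (7:3 by default, optionally
stratified; the field's corpora are split "randomly", so simple random is
the default and both modes exist), `evaluate_predictions()` (accuracy,
per-class precision/recall/F1, macro averages over the classes present in
gold, $F1 = 0$ by convention when $P + R = 0$) — is classifier-agnostic:
prediction files from any external model can be evaluated.

The built-in baseline is a multinomial token-frequency model with additive
smoothing ($\alpha = 1$), i.e. multinomial naive Bayes, over a tokenizer
that splits on whitespace and breaks CJK codepoints into single characters.
It exists to exercise the pipeline end-to-end and to provide a deterministic
reference point, not to compete with fine-tuned transformers; score ties
break by training-class frequency then lexicographic class name, and an
empty text falls back to the training prior. Class imbalance is why
macro-F1, not accuracy, is the headline metric: the commenting stance
dominates real corpora, and a majority-class predictor would look strong on
accuracy while being useless.

## What the synthetic generator emulates — and what it does not

`generator_config()` describes: rumors with categories; a posting plan per
(rumor, method) including combination signatures and `Other` rows
(non-debunking); a stance probability vector $\pi = (p_S, p_D, p_Q, p_C)$
per (rumor, method) (method-wide rows apply to every rumor; rumor-specific
rows override); negative-binomial comments per posting (reply volumes on
social media are overdispersed — a few postings attract enormous threads);
and the marker-token text model. The analytic ground truth of a group is
the closed form of its $\pi$: $DI = (p_D - p_S)/(p_D + p_S)$, $RI = p_C$,
$DEI$ their ratio (`analytic_indices()`), and the generator also records
the exact drawn tallies, so tests can check both estimator consistency and
exact bookkeeping.

`default_study_config()` fixes the study-like conditions: five rumors
(two authority, two society, one politics); per rumor 76 debunking postings
of which combinations are the majority (46, i.e. 60.5%, split across
`Com<Ref,Per>`, `Com<Ref,Org>`, `Com<Ref,Per,Org>`), followed by refutation
(15.8%) and denial (11.8%), trailing shares for `Per`/`Org`/`Fur`, plus 6
`Other` postings; stance vectors with $p_C > p_D > p_Q > p_S$ for every
debunking method (commenting dominates real threads) and a visibly larger
supporting share under `Other`; comment volumes NegBin(mean 25, size 0.8).
These are desk-scale sizes — a generated corpus has ~10,000 comments,
enough for the rank tests to be well inside their asymptotic regime while
the full test suite runs in seconds — chosen once and documented here, with
the true denial mass set high because retrospectively collected
rumor-debunking threads are truth-driven.

All randomness flows from the single `seed` through one sequentially
consumed RNG stream (plan rows are generated in order: volumes, stances,
texts), so a given configuration is byte-reproducible.

What the generator does **not** emulate: real language (tokens are
synthetic markers, so classifier results on generated corpora say nothing
about Chinese NLP difficulty); repost cascades, user networks, or time
dynamics; correlation of stances within a thread (comments are i.i.d. given
the group's $\pi$, whereas real threads exhibit herding); and annotation
noise (truth labels are exact). Passing tests therefore demonstrate that
the estimators and tests are correct and calibrated under the stated
model — not that any particular platform corpus satisfies that model.

## Numerical and design choices

- **Ids** are opaque strings; platform message ids are not portable.
- **Combination tokens** are canonicalized to the member order
  `Ref, Per, Org` on construction (`Com<Org,Ref>` parses to
  `Com<Ref,Org>`), so signature grouping is order-insensitive; signatures
  containing `Den`/`Fur` or fewer than two members are rejected.
- **Serialization** is JSONL (one object per line) or RFC 4180 CSV, UTF-8,
  `NA` as JSON `null` / empty CSV field; round-trips are lossless and
  tested field-wise.
- **Report rounding** is 3 decimals; ties in DEI rankings at that precision
  are listed together and noted, never broken arbitrarily. Full precision
  is kept internally.
- **Split sizes** use `round(n * fraction)`; stratified splits apply the
  rule per class (singleton classes go to training so the model sees every
  class).
- **De-duplication** of comments across nested threads is left to the
  caller; the corpus model enforces unique ids but does not define content
  equality.
- **Null calibration scale**: the type-I-error check for the
  Kruskal–Wallis route uses 4 methods × 30 postings with NegBin(mean 50,
  size 5) comment volumes and 500 replicates — a desk-scale version of
  ~290 postings per method and ~50 comments per posting, chosen once; at
  this size the $\chi^2$ approximation's empirical rejection rate at
  $\alpha = 0.05$ must land in [0.03, 0.07].

## Known limitations

- DEI compares *methods given exposure*; it says nothing causal about what
  a user would have believed under a different method, and retrospective
  corpora over-represent truth-driven late commentary (one reason observed
  $DI$ values run high).
- The DEI ratio is unstable for groups with tiny $RI$; pooled tables
  mitigate this, per-posting records can be noisy, and the undefined-value
  flags should be inspected rather than discarded.
- Kappa here is strictly two-annotator, unweighted; weighted kappa and
  Krippendorff's alpha are out of scope.
- The baseline classifier ignores word order, negation and sarcasm — all of
  which matter for real stance detection; it is a harness reference, not a
  recommendation.
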