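---
title: "Measuring public discussion of diseases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring public discussion of diseases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasetalk)
```

## The measurement problem

Counting how often disease names appear in a social-media corpus is a cheap
proxy for public interest in those diseases, and is often correlated against
survey prevalence. Two biases dominate the naive count:

1. **Word-sense ambiguity.** Many disease names have frequent non-medical
   senses: "stroke" of genius, astrological "cancer", "heart attack" as
   hyperbole, "CHF" the Swiss franc, abbreviations buried in shortened URLs.
   A raw count therefore overstates discussion for ambiguous lexica, and by
   a factor that varies wildly across diseases.
2. **Platform demographics.** Platform users are not a demographically
   random sample of the population, so even a perfectly disambiguated count
   should not be expected to track general-population prevalence.

diseasetalk implements a correction for each. Ambiguity is corrected by
*sampled human appraisal*: for each disease term, up to $k$ tweets
containing it are sampled, two raters judge each mention Yes/No for the
medical sense, the two per-rater Yes percentages are averaged into a
**correction factor** $c_t$, and the term's **validated count** is

$$\mathrm{vcount}_t = \mathrm{rcount}_t \cdot \frac{c_t}{100},$$

where $\mathrm{rcount}_t$ is the number of distinct filtered tweets
containing $t$. Term-level validated counts are summed over each disease's
lexicon; the lexicon-level percentage is then the term-level factors
weighted by term frequency. The demographic correction is realised entirely
by the choice of prevalence stratum: counts are correlated against
prevalence *among platform users* instead of the general population. No
re-weighting is computed here — the two-stratum prevalence table is a
poststratified survey product consumed as input.

## Pipeline stages

**Lexicon construction.** Disease lexica are built from a thesaurus in the
consumer-health-vocabulary schema: entries `(concept_id, chv_term,
descriptive_phrase, umls_term)` where rows sharing a concept form one
key-value network. Retrieval is deliberately inclusive: if *any* element of
a network contains *any* search string as a case-insensitive substring, the
*entire* network becomes candidate material. Vetting then proceeds in three
passes:

* a **decision file** records the judgments that need a human (is the term a
  noun naming the disease? does it denote this disease at all?) plus any
  plural expansions, making the manual review reproducible;
* **structural reduction** drops compound candidates (a superstring of a
  retained term — "allergic asthma" when "asthma" is retained) and
  reverse-order candidates (token permutations such as "fever hay").

Compound dropping is sound because matching is substring-subsumptive: every
tweet the compound would retrieve is already retrieved by the shorter term.
This equivalence is asserted as a cross-module property test on synthetic
corpora. Reverse-order detection is defined as token-multiset permutation
equality after punctuation is stripped to whitespace (covering thesaurus
constructions like "pain, back, radiating"); within a permutation class the
representative is the `chv_term` surface form when one exists, else the
lexicographically first — a deterministic tie-break.

**Corpus filtering.** A tweet is kept when (a) at least 50% of its
alphabetic tokens are found in an English dictionary (boundary inclusive;
URLs are removed and `#`/`@` sigils stripped before tokenisation) and (b)
its free-text location contains a country alias or one of its
comma/whitespace-delimited segments exactly equals an unambiguous US place
name. Ambiguous names are simply absent from the gazetteer, so "London"
does not pass even though a London, Texas exists. The gazetteer is an input
file; the bundled default is a small city list suitable for tests, not a
complete national gazetteer.

**Counting.** Matching requires the term's token sequence to appear
contiguously at token boundaries after case-folding ("attack" does not
match "attacked"; plural forms are separate lexicon entries). A tweet
counts once per distinct (disease, term) pair it contains — so one tweet
naming two diseases is counted twice, but repeating one term in one tweet
counts once. The tweet, not the occurrence, is the annotation unit, which
keeps counting consistent with appraisal sampling.

**Appraisal and correction.** Samples are uniform without replacement,
capped at $k = 30$ per term (the default balances annotation cost against a
~9-point standard error at $p = 0.5$); when a term matched 30 or fewer
tweets, all of them are taken. The sampler the original workflow used is
not recorded anywhere, so uniform-without-replacement was chosen as the
simplest defensible design. Validated counts are carried as real numbers
through every aggregation and rounded half-up only at report time; this is
the convention most consistent with the published per-disease tables.
Inter-rater reliability is summarised by Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$, with the convention $\kappa = 1$ when
both raters are constant and identical.

**Correlation and projection.** Spearman correlation is computed as the
Pearson correlation of mid-ranks (ties averaged); the implementation is
hand-written and checked exhaustively against an independent
rank-then-Pearson oracle, including planted tie patterns. Inference, when
requested, is a two-sided seeded permutation test — exact small-$n$
inference with no distributional assumptions, since the analysis typically
involves ~22 diseases. Projected prevalence distributes the actual
prevalence total in proportion to validated-count share:

$$\mathrm{projected}(d) = \frac{\mathrm{vcount}_d}{\sum_{d'} \mathrm{vcount}_{d'}}
  \cdot \sum_{d'} \mathrm{prev}_{d'},$$

which conserves the total by construction (asserted to $10^{-9}$ relative).
The representation ratio projected/actual flags over-discussed
(ratio > 1) and under-discussed diseases.

**Merging.** Prevalence surveys sometimes collapse conditions that are
counted separately (congestive heart failure with heart disease; heart
attack with stroke). The merge map sums raw and validated counts into the
analysis rows at which prevalence exists; all correlations and projections
operate on the merged set.

## The bundled reference dataset

`reference_counts()`, `reference_prevalence()` and `reference_merge_map()`
expose a published 2012 measurement: raw and validated tweet counts for 24
diseases from a year of a 1% US Twitter sample, with two-stratum prevalence
from a poststratified national consumer survey, collapsing to 22 analysis
diseases. `reproduce_study()` re-runs the from-counts analysis on it in
well under a second. Two caveats frame the reproduction:

* the printed prevalence is rounded to 0.1&nbsp;million persons, which can flip
  ranks of near-tied diseases; the two platform-stratum correlations
  therefore reproduce to within ±0.02 rather than exactly, and projected
  prevalence to ~2×10⁻⁴ relative;
* the underlying 80-million-tweet corpus and the 2824 human judgments are
  not distributable, so corpus-scale quantities (the raw counts themselves,
  the observed κ = .77) are inputs here, not outputs. The full pipeline is
  instead validated on synthetic corpora where ground truth is planted.

## What the synthetic generator does and does not emulate

`generate_corpus()` plants term mentions by a per-tweet categorical draw
(so empirical mention rates converge exactly to their specification), labels
each mention medical with the term's planted validity $p_t$, and renders
mentions inside fixed template sentences — medical contexts and non-medical
contexts in metaphor, slang, homograph and URL-fragment styles. Non-English
tweets are built from out-of-dictionary tokens; locations are drawn from
bundled unambiguous-US and non-US/ambiguous strings. Each component draws
from its own seed-derived stream, so changing the rater seed never perturbs
the corpus. Raters are simulated by sensitivity/specificity: the
probability of a Yes is `sensitivity` on a medical mention and
`1 - specificity` otherwise.

This emulates the *measurement* structure of real data — planted validity,
filtering attrition, sampling noise, rater error — but none of its language:
there is no topical drift, no user-level clustering (tweets are treated as
exchangeable; real corpora have heavy-tailed per-user activity and
organisational accounts), no misspellings or slang variants ("diabeetus",
"ashtma" are invisible to exact matching, a known recall limitation), and no
retweet duplication. Passing the synthetic battery therefore demonstrates
that the estimator machinery is correct, not that real-corpus counts are
unbiased.

Validation batteries run at deliberately modest sizes chosen to keep the
whole suite fast while leaving comfortable statistical margins: estimator
recovery uses 200 replicates of 20,000-tweet corpora with ten terms spanning
$p_t \in [0.1, 0.95]$ and checks the recovered $c_t/100$ against the exact
(Clopper–Pearson) 99% binomial interval at the realised sample size;
structural-vetting equivalence uses 100 seeded 400-tweet corpora;
convergence checks use 4 binomial standard errors at $n \ge 10{,}000$.

## Numerical conventions and degenerate inputs

* Probabilities are validated to $[0,1]$; mention rates must sum to ≤ 1.
* A term with raw count 0 yields an empty, flagged sample and a validated
  count of exactly 0; a lexicon that matched nothing has an undefined
  (`NA`) weighted percentage rather than a silent 0.
* Spearman correlation on a constant rank vector is `NA` with a warning,
  never 0.
* Kappa with chance agreement 1 is defined as 1 when observed agreement
  is 1.
* The 50% English threshold is inclusive; an empty or URL-only text is not
  English; an empty location is not US.
* All generators, samplers and permutation tests are bit-reproducible under
  their seed; seeds derived for sub-streams stay below $2^{31}$.

## Known limitations

Beyond the synthetic-realism caveats above: the location rule cannot place
tweets whose location field is empty or fanciful (a large fraction of real
data); per-tweet-per-term counting means a term repeated in one tweet is
deliberately counted once, which is one defensible reading of the published
counting rule rather than a documented certainty; and correction factors
estimated from ≤30 judgments carry binomial noise of up to ±9 percentage
points, which propagates into validated counts of low-frequency terms.
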