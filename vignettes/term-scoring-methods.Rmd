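---
title: "Weighted keyword term scoring for large-scale screening: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted keyword term scoring for large-scale screening: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termscreen)
```

## The problem

A broad systematic review can return on the order of 10^5 candidate records
from database searches. Screening them serially is infeasible (roughly 470
titles/abstracts per reviewer-day; `workload_days(60000, 470)` is 128 days
for a single large seed set), and semi-automated screening tools that learn
from a handful of seed decisions are vulnerable to the *hasty
generalisation* problem — over-committing to whatever the few screened
records happen to look like — and to premature stopping. termscreen
implements a transparent, expert-driven triage layer for this situation:
weighted positive and negative keywords score every record, the scores
prioritise screening order, and the scored corpus can be split and exported
as a large, representative seed set for a semi-automated tool.

## The scoring model

Every record is reduced to the token sequence of its title followed by its
abstract (Unicode NFKC, lower case, punctuation stripped, whitespace split).
For a record with $W$ tokens and a registry of positive keywords $p = 1,
\dots, P$ and negative keywords $n = 1, \dots, N$, the term score is

$$
TS \;=\; \sum_{p=1}^{P} w_p\, m_p \;-\; 1.2 \left( \sum_{n=1}^{N} w_n\, m_n \right),
$$

where $w = \text{weight}/10$ for an integer expert weight in $1..10$, and
$m$ is the *match density*: the keyword's match count times its own word
count, divided by $W$. Higher scores mean more relevant; the 1.2 penalty
makes a negative match slightly more than cancel an equally weighted
positive match of the same density.

Two properties are worth knowing:

* **Length invariance.** Because both match counts and $W$ scale together,
  concatenating a document with itself leaves every $m$, and hence $TS$,
  unchanged. The tests verify this by fuzzing; the invariance is exact
  except in the contrived case where a keyword occurrence spans the
  concatenation seam (the last tokens of one copy plus the first tokens of
  the next), which is why multi-word matching policy matters (next point).
* **Match policy.** Matches are counted greedily left to right without
  overlap (in `[a, a, a]` the phrase `[a, a]` matches once). The policy is
  recorded in `scoring_config()` so alternatives remain explicit rather
  than implicit.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| keyword `weight` | — | integer 1..10 set by the domain expert; used as weight/10 |
| `penalty` | 1.2 | multiplier on the negative-keyword sum |
| `min_abstract_chars` | 200 | exclusion threshold, characters of trimmed abstract |
| `ineligible_article_types` | review, editorial, erratum, letter | type labels excluded outright |
| `overlap_policy` | non-overlapping | greedy left-to-right match counting |

Weights are read as *inclusive integers* 1..10: weight/10 then gives clean
one-decimal multipliers, and fractional weights are rejected so a registry
file is always exactly reproducible. Abstract length is counted in
characters of the raw, whitespace-trimmed abstract (not tokens); an
all-whitespace abstract counts as absent. The ineligible type list is a
package default — real reviews differ, so it is fully configurable and the
fired rules are logged per record.

Exclusion is deliberately *hard*: a record with no DOI, no abstract, a short
abstract or an ineligible type is never scored and is always ranked after
every scored record, whatever keywords it contains. Score ties are broken by
`record_id` so a ranking is a pure function of its inputs.

## Step 1 and Step 2

`title_screen()` implements the first-pass title-only elimination: with the
default rule a record is flagged for elimination when its title matches at
least one negative keyword and no positive keyword. Decisions are returned
as a table, not applied destructively — the workflow this supports is
text-mining *plus* manual review, with the keyword registry refined
iteratively (every `add_keyword()`/`revise_weight()` bumps a version counter
and appends to a revision log, so the registry's history is auditable and
reusable in review updates). `score_records()` + `rank_records()` implement
the second step over title+abstract tokens.

## The screening simulator

`simulate_rank_once()` and `simulate_active()` emulate how a semi-automated
screening tool consumes seed decisions. The external tool itself is *never*
called and its internal learners are not re-implemented; instead a
deliberately transparent reference ranker stands behind the same interface:
L2-normalised bag-of-words vectors, one centroid per screened class, and
score = cosine to the relevant centroid minus cosine to the irrelevant
centroid. It is deterministic given the screened set, which makes the
simulations bit-reproducible under `rng_seed`. The simulated reviewer is
the gold label — standard practice for screening simulations. The stopping
rule is the usual *k consecutive irrelevant screens* criterion, surfaced as
`stopping_k`.

Configuration profiles are expressed with `sim_config()`: minimal-seed
active learning (1 relevant + 1 irrelevant seed, ~20 manual screens),
rank-once with 20/20 or 50/50 seeds, and rank-once with ~70% of the corpus
as seeds (the cross-validation style of use). Seed sampling is stratified
exactly by class.

## The synthetic corpus generator

`generate_corpus()` emulates the statistics the method actually consumes,
not natural language: background tokens are uniform synthetic words; each
planted keyword phrase is spliced in as a contiguous block with a
class-conditional occurrence rate; titles are 5–15 tokens; abstract lengths
are negative-binomial (default mean 150 tokens, size 12, so lengths vary
realistically); missing DOIs, missing abstracts and sub-200-character
abstracts are injected independently at configurable rates. Phrases are
planted at background-token boundaries so one planted phrase can never
split another — empirical phrase frequencies therefore converge exactly to
their configured rates, which the tests check at n = 50,000 within three
standard errors.

`benchmark_corpus()` freezes one "strong-planting" instance used throughout
the tests: n = 5,000, prevalence 0.08, twelve positive and twelve negative
phrases (one- and two-word) with an 8× rate separation between classes,
defect rates 0.02/0.02/0.01 (≈5% of records trip the exclusion rules), seed
13, paired with `benchmark_registry()` whose weights ascend with planting
rate and span 1–10.

What passing on this corpus does **not** show: real titles and abstracts
have correlated vocabulary, synonymy, topic drift and class imbalance far
more hostile than independent Bernoulli planting. Results on the benchmark
demonstrate that the implementation is correct and that the method behaves
as intended *when its assumptions hold*, not that any particular recall
will be achieved on a real review.

## Numerical and design choices

* Scores are plain doubles; the score decomposition (`tidy()` on a
  `term_score`) re-derives $TS$ exactly from its components for audit.
* A zero-token, non-excluded record is an error, not a zero score — it
  signals a broken exclusion pipeline upstream.
* Spearman's ρ is the Pearson correlation of average-tie ranks; constant
  input is an error (ρ undefined) rather than `NA`.
* The top quartile is ranks 1..⌈n/4⌉; seed/test split sizes use half-up
  rounding (`floor(f·n + 0.5)`), so a 70% split of 10 records is 7/3.
* `workload_days()` uses a ceiling — partial screening days are whole days.
* No stemming or fuzzy matching: registry phrases are normalized with the
  same function as document text, so matching is exact by construction.
  This is the reference behaviour; a stemmer could be slotted into
  `tokenize()`'s place but all shipped numbers use exact matching.
* Problem sizes in the test suite: the benchmark corpus (n = 5,000) for
  end-to-end checks, 20 Monte-Carlo replicates for configuration
  comparisons, n = 50,000 for the single rate-convergence property; these
  sizes give stable statistics while keeping a full test run to a couple of
  minutes on one CPU.

## Known limitations

* Keywords and weights are domain-specific; a new review needs a new expert
  pass, and single-expert weighting can encode one person's biases. The
  revision log mitigates this by making every weighting decision visible.
* The reference ranker is a stand-in chosen for transparency and
  determinism; it is not a model of any particular tool's classifier, and
  absolute simulator numbers should not be read as predictions of a real
  tool's performance. Relative comparisons (more seeds help; rankings
  correlate with term scores) are the supported use.
* RIS support covers the common tag layout (`TY`/`TI`/`AB`/`DO`/`ID`, `ER`
  terminator, continuation lines); exotic dialects may need a column
  mapping or conversion to CSV first.
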