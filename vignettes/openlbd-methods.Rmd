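---
title: "Methods: supervised linking-concept selection for open literature-based discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised linking-concept selection for open LBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openlbd)
```

## The model

Open discovery follows the ABC co-occurrence model: from a starting
concept $C$, collect every MeSH term $B$ that co-occurs with $C$ in the
MeSH field of the time-filtered corpus (the *preliminary linking
concepts*); from relevant $B$'s, collect MeSH partners $A$ that never
co-occur with $C$ (the *targets*). The package's contribution-bearing step
is the supervised relevance filter on $B$: each $(C, B)$ pair becomes a
seven-dimensional vector

* $f_1, f_2$: mutual-information scores
  $\mathrm{MIM}(A,B) = \log_2\!\big(P_{AB}/(P_A P_B)\big)$ over document
  frequencies in the MeSH-field and title+abstract scopes;
* $f_3$–$f_6$: Boolean sentence-geometry evidence (same sentence; same
  sentence plus an interaction word; a two-neighboring-sentence window;
  such a window containing an interaction word);
* $f_7$: co-mention in the abstract field.

Targets are ranked by the number of relevant $B$'s with corroborating
textual evidence ("useful linking-term count") under Rule 1
(title/abstract co-occurrence of $B$ and $A$) or the stricter Rule 2 (one
sentence containing $B$, $A$ and an interaction word), and configurations
are compared by the percentage of useful LTC,
$100\cdot n_\text{useful}/n_\text{all}$.

Assumptions worth stating plainly: concept recognition is literal string
matching of MeSH descriptors (plus record-local abbreviations) — there is
no synonym or entry-term expansion; all counts are document-level, so a
pair co-mentioned in three sentences of one record counts once; and the
classifier sees only the seven features above, not raw text.

## Tunable parameters

| parameter | default | unit / range | why |
|---|---|---|---|
| `max_year` | `Inf` | calendar year, strict `<` | replicate pre-discovery literature windows |
| `mim_floor` | −20 | bits | finite stand-in for undefined MIM (zero counts); far below any observable score, so floored vectors are separable from real ones |
| window distance | ≤ 1 sentence | fixed | "two neighboring sentences"; a single sentence is a degenerate window, which keeps $f_3 \le f_5$ |
| `dfq` | 0.99 | DF quantile | "too general" negatives = inclusive top 1% of candidate document frequency (with a median guard for flat distributions) |
| `cost` | 1.0 | SVM soft-margin C | 7 dimensions and tens of examples; a gentle margin; exposed for sweeps |
| `rule` | `rule2` | — | the stricter, more precise evidence rule |
| linking / target types | 9 / 5 names | — | the classic disease-function and dietary-factor type sets |

The interaction lexicon ships as a documented ~60-entry seed list
(`default_interaction_lexicon()`: increase, decrease, inhibit, induce,
aggravate, ... plus inflectional variants enumerated, not stemmed — for
determinism and auditability). The historical 115-entry list is
unpublished; replication work should supply its own file
(`load_interaction_lexicon()`).

## Design choices where the design was open

* **Classifier.** No SVM library is assumed at runtime; the linear margin
  classifier is an L2-regularized squared-hinge primal solved by BFGS with
  analytic gradients and zero initialization — deterministic, which the
  reproducibility contract needs. Kernel choice and software were never
  specified for the original experiments; linear with per-feature
  standardization is the defensible default at this dimensionality.
* **Mention matching.** Each concept is matched independently
  (case-insensitive, word-boundary). A span-claiming "longest match wins"
  scheme was rejected because it makes mention sets non-monotone in the
  concept set: adding a longer concept would silently delete a shorter
  concept's mentions. Independent matching keeps monotonicity, which the
  property tests assert.
* **Abbreviations.** Only `concept (TOKEN)` with a single 1–10 character
  token immediately after a matched mention defines an abbreviation
  (short-form detection in the Schwartz–Hearst style), scoped to the
  record. Pronoun coreference is out of scope.
* **Feature VII.** Read loosely as "both concepts mentioned in the
  abstract text of some record". The strict "only in the abstract"
  reading (no window-level co-occurrence anywhere) is available as
  `strict_f7 = TRUE`; the two readings coexist in the source material and
  the loose one makes $f_7$ independent of $f_5$.
* **Feature VI.** The interaction word may sit anywhere in the
  two-sentence window, not necessarily in the sentence carrying a
  mention.
* **Ranking.** Dense ranking (ties share a rank, next distinct count gets
  rank + 1): two top-tied targets at rank 1 followed by rank 2 matches the
  published tie behavior; competition ranking does not.
* **Target exclusion scope.** "A must not co-occur with C" is evaluated in
  the MeSH field, the same scope that drives candidate generation.
* **Training set.** The original labeled pairs are unpublished, so the
  builder encodes the *rules*: positives are candidates with interaction
  evidence toward $C$ ($f_4$ or $f_6$), negatives drawn as evenly as
  possible from the three stated categories (too-general by DF; no
  window co-occurrence; window co-occurrence without an interaction
  word), balanced by seeded down-sampling. The build errors if the
  positive class or *all* negative categories are empty; a single empty
  negative category is tolerated (small corpora routinely lack one), the
  remaining categories absorb its share. A manual override file can pin
  labels.
* **Tiab probabilities** are computed over the full time-filtered corpus,
  not only records mentioning $C$.
* **Qualifier-bearing MH entries** (`Migraine/drug therapy`) are stripped
  to their descriptor; semantic filtering uses *all* types assigned to a
  concept, not a primary type.

## The synthetic world

`generate_corpus()` emits three record kinds with template sentences
("`<B> increases vascular tone in patients with <C>.`"): C-literature
(relevant $B$'s get same-sentence interaction evidence at
`interaction_rate`; decoys cycle through MeSH-only, non-adjacent-sentence,
and no-interaction kinds, plus high-DF "too general" terms),
A-literature ($B$–$A$ records with Rule-2 or Rule-1-only evidence, never
containing $C$), decoy background records (so decoys carry realistic
marginal document frequencies rather than artificially sharp MIM scores),
and noise records. Defaults — 3 relevant $B$'s, 20 decoys, 1 target,
`interaction_rate = 1`, 120 records — are the planted-chain setting the
acceptance tests exercise; rates below 1 degrade evidence monotonically,
which a 20-seed property test checks. The generator is seeded and
byte-reproducible, and it logs every planted mention, so index counts over
the rendered text are checked against plant-log aggregation — an
end-to-end audit of parsing, segmentation and mention finding.

What the generator does **not** emulate: natural prose, Zipfian term
frequency distributions, synonymy/entry terms, indexing inconsistency, or
historically realistic corpus sizes. A green planted-chain test therefore
establishes that the pipeline's *mechanics* (counting, features,
classification, pruning, ranking) are correct, not that the method would
attain any particular precision on real MEDLINE. The published historical
figures (the 1852→323 linking-concept reductions, Fish-Oil rank 45, the
ablation percentages) depend on pre-1986/pre-1988 snapshots and are
deliberately not asserted; only the Eq.-style arithmetic on their printed
counts and the qualitative classifier-gain claim are tested.

## Numerical notes

* `mim()` validates $0 \le n_{AB} \le \min(n_A, n_B) \le N$ and
  substitutes the floor for any zero count; otherwise it computes
  $\log_2(n_{AB} N / (n_A n_B))$ in double precision (checked to 1e-12
  against the definition on random tuples).
* Sentence boundaries: terminal punctuation followed by whitespace and an
  uppercase letter/digit, suppressed after listed abbreviations (`vs.`,
  `Fig.`, ...), after single uppercase letters (initials), and after
  dotted single letters (`e.g.`). One known limitation: boundary detection
  is heuristic, not a trained model.
* Class balance ties and category shortfalls in the training-set builder
  are resolved by a run-seeded shuffle; the same seed reproduces the same
  set bit-for-bit.
* Ranking ties break alphabetically for a deterministic listing order;
  ranks themselves are shared.
* One published percentage (398/529 printed as 75.8%) disagrees with its
  own numerator and denominator (= 75.2%); the package implements the
  ratio literally and documents the discrepancy rather than reproducing
  it.

## Known limitations

* String-level concept recognition misses synonyms, plurals and
  morphological variants unless they are separate lexicon/MeSH entries.
* The DF-quantile definition of "too general" is an operational stand-in
  for an undocumented manual judgment.
* The classifier is linear; with only seven features that is usually
  adequate, but no kernel search or calibration is attempted.
* Closed discovery (testing a given C–A pair) is out of scope.
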