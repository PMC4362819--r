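---
title: "Interaction-type enrichment of literature-mined gene-gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-type enrichment of literature-mined gene-gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itoenrich)
```

## The problem

Sentence-level literature mining of gene-gene interactions produces, for
every sentence that co-mentions two gene symbols together with an
interaction keyword ("binds", "neutralization", "myristoylates", ...), a
record linking the gene pair to one or more interaction *types*. When the
keywords are organized in an interaction-type ontology — a rooted `is_a`
DAG in which each term carries its surface-form keyword variants as an
annotation — these records become an annotated network: each ontology term
maps to the set of unique gene pairs reported with that interaction type.

The question this package answers is: **which interaction types are used
significantly more (or less) often in a concept-specific slice of the
literature than in the literature as a whole?** The motivating use case is
vaccine research: the sub-network is built from documents mentioning the
concept word and its variants ("vaccine", "vaccines", "vaccination",
"vaccinated") or any term from a list of specific concept names (e.g.,
"tuberculosis vaccine BCG"), and it is compared against the network mined
from the entire corpus.

## The statistical model

For each interaction-type term $t$ the unit of counting is the **unique
unordered gene pair**, after hierarchy propagation (below). With

* $a$ = sub-network pairs annotated to $t$, $b$ = sub-network pairs not
  annotated to $t$ (so $a + b$ = all sub-network pairs), and
* $A$, $B$ = the same counts in the whole network (which *contains* the
  sub-network),

the enrichment fold is the ratio of raw proportions

$$\mathrm{fold}(t) = \frac{a/(a+b)}{A/(A+B)},$$

and significance is assessed by a one-sided Fisher's exact test with a
conservative one-pair modification of the evidence cell (the EASE-score
idea from gene-set enrichment): for over-representation $a$ is replaced by
$\max(a-1, 0)$, for under-representation by $a+1$ (capped at
$\min(a+b, A)$), the margins are recomputed from the modified cells, and
the exact hypergeometric tail

$$p = \sum_{x \ge a'} \frac{\binom{m}{x}\binom{N-m}{k-x}}{\binom{N}{k}},
\qquad N = a'+b+A+B,\; m = a'+A,\; k = a'+b$$

is summed in log space (no chi-square or normal approximation). Removing
one pair from the evidence cell means a term supported by a single
borderline pair can never be called; the test is strictly conservative
relative to the unmodified Fisher test (a property the test suite verifies
exhaustively for all tables with total $\le 100$).

Terms are tested only if they carry at least `min_pairs = 5` unique pairs
in the sub-network. The candidate direction is over when fold > 1 and
under otherwise; Benjamini-Hochberg correction is applied across the
tested set only (its size is the BH $m$), and a term is finally called
over-represented iff BH $p < 0.05$ **and** fold $\ge 2$, under-represented
iff BH $p < 0.05$ and fold $\le 0.5$. All thresholds are arguments of
`run_enrichment()` with these defaults.

Two points are deliberate interpretations, exposed as flags rather than
hidden choices:

* **Sidedness.** One p-value is reported per term, computed one-sided in
  the fold-indicated direction; `sided = "two"` gives the usual two-sided
  exact p for sensitivity analysis.
* **The under direction.** The one-pair modification is defined for the
  over direction; for under-representation the symmetric $+1$ shift is
  used so both calls are conservative, and `modify = FALSE` disables the
  modification entirely.

The 2x2 is formed from the two columns *sub-network* and *whole network*
exactly as counted — the whole network is not replaced by its complement.
Folds and p-values are computed from propagated counts throughout.

## Hierarchy propagation

A pair reported with "mRNA cleavage" is implicitly also an instance of
"RNA cleavage", "nucleic acid cleavage" and "cleavage reaction". The
network builder therefore adds every record's pair to each directly
matched term *and* to all its ancestors (true-path rule), deduplicating by
set semantics along multi-parent paths. Consequently a parent's pair set
always contains the union of its children's sets, the root's set equals
the universe of annotated pairs, and a parent can legitimately be called
under-represented while some of its specific children are over-represented
— the parent's count aggregates the whole category. Propagation is applied
identically to the sub-network and to the whole network before any table
is built. Distinct-document counts per (term, pair) are carried along for
the "most frequent gene pair" report column only; they play no role in the
test.

## Tagging

Gene mentions and interaction keywords are found by dictionary matching:
tokens are maximal runs of `[A-Za-z0-9-]` (so "IL-12" and "IFN-gamma" are
single tokens), matching is case-insensitive on token sequences, and
overlapping hits are resolved longest-first, left-to-right, each token
consumed by at most one match per channel (the gene channel and the
keyword channel are independent, so "nucleic acid cleavage" beats bare
"cleavage" in the keyword channel without affecting gene matching). A
sentence with $g \ge 2$ distinct canonical genes and at least one matched
keyword term yields $\binom{g}{2}$ records, each carrying the full matched
term set; pairs are stored in lexicographic order and self-pairs are
impossible by construction. Sentence classification (e.g., an SVM over
dependency parses) is out of scope: records can carry externally computed
confidence scores, and `filter_by_score()` drops non-positive scores while
passing unscored records through.

## The synthetic-data generator

Real inputs at published scale (tens of millions of abstracts, hundreds of
thousands of background pairs) are not desk-reproducible, so the generator
emulates the statistical structure at roughly 1/1000 scale. The defaults
of `sim_config()` are the study conditions used by the test suite and are
not tuned per test:

* 5,000 whole-network gene pairs over 150 genes, 6,000 documents, and a
  concept subset of 4% (200 pairs, matching document pools);
* 30 ontology terms in a random rooted DAG (each non-root term has one
  parent among earlier terms, a second with probability 0.25), each with
  2-5 keyword variants formed as deterministic inflections of an invented
  unique stem (`...ate`, `...ates`, `...ated`, ...);
* background term-usage rates that are Zipf-distributed over non-root
  terms, $q_t = q_{\max}/\mathrm{rank}(t)$ with $q_{\max} = 0.3$ — a
  skewed usage profile, as in real keyword statistics;
* each (pair, term) annotation is supported by $1 + \mathrm{Poisson}(0.2)$
  distinct documents, giving the document-count column realistic ties.

A planted `(term, fold)` sets the concept subset's per-pair usage
probability to fold x background rate (erroring before generation if that
exceeds 1). Because the whole network contains the concept subset, the
*measured* fold of a term planted at $f$ has expectation
$f n / (n_c f + (n - n_c))$ — about 4.31 for $f = 5$ with $n = 5000$,
$n_c = 200$ — which is why the recovery check uses a +-20% band around the
target and why power simulations plant the fold on a *leaf* term: an
internal term's propagated count would mix in unplanted descendants and
dilute the signal further.

Template sentences (`"<gene> <keyword> <gene> in <context>."`) are
deliberately unambiguous — unique keyword stems, gene surfaces disjoint
from context words — so tagging recovery measures the pipeline, not lexical
luck; a flagged hard mode emits two-keyword sentences to exercise
multi-term records. What the generator does **not** emulate: real English
syntax, homonymous gene symbols, abbreviation ambiguity, cross-sentence
coreference, or classifier score distributions. Passing the simulation
suite therefore says nothing about named-entity accuracy on real text; it
validates the counting, propagation and testing machinery downstream of
tagging.

## Calibration at the study conditions

Two pipeline-level checks run at the default conditions over 200 seeds
each: under the null (no planted terms) the fraction of tested terms with
BH $p < 0.05$ must stay at or below nominal plus two binomial standard
errors — the modification makes the observed rate fall well below nominal
— and with a single leaf term planted at fold 5 the term must be called
over-represented in at least 95% of runs with mean measured fold within
+-20% of target. These sizes (5,000 background pairs, 200-pair subsets,
200 seeds) keep each simulation block in the low minutes on one CPU while
leaving the binomial error bounds meaningful.

## Numerical and degenerate-case choices

* Tails are summed from log-space hypergeometric masses with a max-shift
  (log-sum-exp); the exhaustive test grid pins the relative error against
  direct binomial-coefficient enumeration at $< 10^{-12}$.
* $a = 0$ in the over direction gives $p = 1$ exactly; thresholds outside
  the hypergeometric support return 0/1 without summation.
* Reported p-values are never rounded to zero internally; serialization
  uses `%.6e`.
* A term absent from the whole network has no defined fold (`NA`) and is
  excluded from calls; an empty sub-network is an error, not an empty
  result.
* BH ties and ordering follow the standard step-up as implemented by
  `stats::p.adjust`; the suite checks it against a hand-rolled oracle and
  for permutation equivariance.
* Top-pair ties are broken lexicographically on the `GENE1_GENE2` string.
* Obsolete ontology terms are dropped at parse time; `is_a` references to
  them are pruned, while references to identifiers absent from the file
  are an error. Cycles are an error naming one member.

## Known limitations

* Dictionary tagging takes the lexicon at face value: symbol/English-word
  homonyms ("WAS", "IMPACT") will false-positive on real text without a
  curated lexicon.
* Direction of an interaction cannot be inferred from co-occurrence: a
  pair annotated to "neutralization" means the two genes appear in a
  neutralization-related pattern, not that one neutralizes the other.
* Multiple keywords in one sentence are recorded independently; no
  composite interaction type is inferred from their combination.
* The whole network includes the sub-network, so folds saturate below the
  planted target as the concept fraction grows; fold targets refer to the
  background-relative rate, not the measured ratio.
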