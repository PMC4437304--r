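---
title: "Mining bio-entity associations from abstract corpora: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bio-entity associations from abstract corpora: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

## The problem

A single disease query against the biomedical literature returns tens of
thousands of abstracts. The genes, drugs, diseases and biological processes
mentioned in those abstracts — and the pattern of which entities appear
*together* in the same abstract — carry usable signal about functional
associations: a gene repeatedly co-mentioned with a drug and a disease is a
candidate link between them. `litnet` implements this co-occurrence mining
workflow offline, from plain files: a two-tier keyword search over an
abstract corpus, statistical scoring of entity associations, assembly of the
implicated proteins into a PPI/pathway meta-network, plus co-authorship
analytics and an NER evaluation harness. Everything is testable end-to-end
against a deterministic synthetic-data generator.

## Statistical model

### Query-entity association: the hypergeometric test

For a query (e.g. a disease name) and a candidate entity (e.g. a gene), the
universe is the set of $N$ abstracts containing at least one entity of the
candidate's class — the population in which the entity *could* have been
observed. Within it, $X$ abstracts match the query and $Z$ contain the
entity; $A$ is their overlap. The 2x2 table is completed by $B = X - A$,
$C = Z - A$, $D = N - X - Z + A$, with $Y = C + D$.

Under the null that the $Z$ entity-bearing abstracts fall on the query set
at random, the overlap count is hypergeometric:

$$P_{HGD}(A) \;=\; \frac{\binom{X}{A}\binom{Y}{C}}{\binom{N}{Z}},$$

and the default reported probability is the upper tail
$\sum_{a \ge A} P_{HGD}(a)$ — "at least this much overlap by chance", the
standard enrichment reading. The point-mass mode is retained
(`hypergeometric_p(tab, "point")`) because the two readings are not
distinguishable from the workflow description alone; the upper tail is the
default because a tail is what "probability of observing by chance" means
for an enrichment claim. Binomial coefficients overflow double precision
quickly, so both modes are computed in log space (`lchoose` plus a
log-sum-exp for the tail) and validated against exhaustive enumeration of
all $\binom{N}{Z}$ placements for every table with $N \le 12$.

The reported association score is

$$\mathrm{Score} = -\log_2(P_{HGD}) / 100,$$

a log transformation chosen because the probabilities span hundreds of
orders of magnitude; the division by the constant 100 only rescales. Higher
scores mean stronger association; $p = 1$ gives score 0 and $p = 2^{-100}$
gives exactly 1. The negation is part of the package's definition: the
score must increase with significance.

### Entity-entity co-occurrence: pointwise mutual information

Two entities co-occurring in $n_{xy}$ of $N$ context abstracts, with
marginal counts $n_x$ and $n_y$, score

$$MI = \log_2 \frac{n_{xy}/N}{(n_x/N)(n_y/N)},$$

the log-ratio of observed joint occurrence probability to the product of
marginals. $MI = 0$ at exact independence; $\log_2 L$ at lift $L$. The base
is 2 for consistency with the association score. Two contexts are scored:
the *query* context ($N$ = number of retrieved abstracts) and the *global*
context ($N$ = corpus size); a pair can be strongly associated within a
disease literature yet unremarkable corpus-wide, and the two scores separate
those cases. Pairs with zero support in a context get `NA` there —
$\log 0$ is not a score — and `mutual_information()` refuses $n_{xy} = 0$
outright.

### Triads

Triads (gene-drug-disease, gene-disease-process) are extracted from
abstracts containing all three members and scored with the hypergeometric
test by splitting the triad into its leading pair versus the third member:
$X$ = abstracts (in scope) containing members 1 and 2, $Z$ = abstracts
containing member 3, $A$ = abstracts containing all three, $N$ = scope
abstracts with at least one entity mention. This split asks "does the third
member land on the pair's literature more often than chance?" and is the
most defensible reading of a triad-by-hypergeometric design; because the
choice of "third" member is a genuine degree of freedom, a symmetric mode
(`split = "symmetric"`) averages the probability over the three splits.
The scope defaults to the query result; the background universe question
(query scope vs whole corpus) is decided in favor of query scope, since
triads are presented as refinements of a query's literature.

## Text matching and tagging

Primary/secondary keyword matching is literal-phrase, case-insensitive, on
word boundaries: `"|"` separates OR alternatives, `","` separates AND
groups, one secondary OR-group per line, and exclusion terms veto an
abstract. Exclusions are applied at the primary search, before secondary
bucketing, so every downstream statistic sees one consistent retrieved set.
Each retrieved abstract is assigned to exactly one secondary *combination
bucket*, keyed by the full set of secondary groups it matches — the buckets
are mutually exclusive and jointly cover the abstracts matching at least
one group, which the tests verify against power-set enumeration.

Dictionary tagging is deterministic left-to-right longest-match on word
boundaries. Two rules matter in practice:

* matching is case-insensitive *except* for short gene-symbol-like synonyms
  (length at most 4, no lowercase letters), which match case-sensitively —
  otherwise the gene symbol *WAS* fires on the English word "was";
* a synonym never matches inside a longer alphanumeric token, so *EGFR*
  does not fire inside *EGFRvIII*.

Ties between equal-length candidates at one position break to the
lexicographically smallest canonical id, making tagging a pure function of
(text, dictionary). Mention spans are 0-based half-open offsets into
`title + " " + body` (one separator character), the single convention used
by the mention TSV dialect, the tagger and the evaluation harness.
Occurrence indexing is presence-based (an entity is either in an abstract
or not); all scores are defined on abstract counts, so multiplicity within
an abstract carries no statistical weight here.

## Networks

PPI edges carry a STRING-style confidence in $[0,1]$ and are stratified
into high ($\ge 0.7$) and medium ($[0.4, 0.7)$) classes; the two published
thresholds overlap as stated ("$\ge 0.7$" and "$\ge 0.4$"), so the high
class is made exclusive of the medium interval — classes must partition.
Edges below 0.4 are dropped at load time and never stored. Neighborhoods
are breadth-first, up to two hops (interactors of direct interactors),
through edges of the requested class or better; all qualifying edges among
included nodes are kept. Up to five seed proteins can be merged: the union
of their neighborhoods (shared nodes keep the minimum hop distance),
followed by pathway overlay — any pathway intersecting the node set is
attached *in full* (configurable to members-only), its internal edges as
directed records distinct from coexisting undirected PPI edges. Proteins in
two or more pathways are crosstalk proteins. Expression overlays store
`log2(mean_b / mean_a)` per node with an up/down/unchanged call at a
user-set threshold (default 1, i.e. two-fold); this plain fold-change is a
deliberate stand-in for a full differential-expression model — with
replicate counts this small, a moderated test would be decoration.
Exports: SIF (relations `ppi` / `pathway:<id>`), GraphML with all
attributes, and a canonical JSON document that round-trips losslessly.

## The synthetic study generator

`generator_config()` fixes the study conditions: 2000 abstracts; 30 genes,
12 drugs, 8 diseases, 6 processes at base presence probability 0.08 per
abstract; a query token present at probability 0.09; a planted query-gene
association at lift 10, a planted gene-drug pair at lift 10 and a planted
gene-drug-disease triad at lift 6; pools of 40 authors and 5 countries; a
40-protein/120-edge PPI graph with a forced high-confidence 2-hop chain; 8
pathways with one protein planted in exactly 5; one gene with a noiseless
log2 fold-change of 2.

Entity presence is Bernoulli per abstract (set semantics, matching the
presence index). A planted tuple with members of marginal probability
$p_i$ and lift $L$ is drawn by mixture: with probability $q$ all members
are forced co-present, otherwise members are independent at rate
$(p_i - q)/(1 - q)$, which preserves every marginal exactly; $q$ is solved
numerically from $q + (1-q)\prod_i \frac{p_i - q}{1 - q} = L \prod_i p_i$.
Feasibility requires the target joint not to exceed any marginal — which
is why the defaults sit at 0.08/0.09: lift 10 forces
$L\, p_q p_e \le \min(p_q, p_e)$, i.e. a query marginal at or below 0.1.
Lifts below 1 have no such mixture representation with preserved marginals
and are rejected. Every present entity's preferred token is written into
the abstract body, so dictionary tagging provably rediscovers the gold
mentions (F = 1 in canonical-id mode) — that is a construction guarantee,
and passing it says nothing about tagging performance on real prose.

What the generator does *not* emulate: natural language (bodies are
templated token sequences — no ambiguity, no abbreviations, no
morphology), entity mention multiplicity, correlated entity co-occurrence
beyond the planted tuples, author-name homonymy, or realistic PPI degree
distributions. Tests passing on generated corpora therefore validate the
counting, scoring and graph machinery — not NER quality or biological
truth of any specific association.

## Numerical and design choices

* Hypergeometric tails in log space; probabilities clamped into $(0, 1]$
  after exponentiation.
* `sum` over log-point-masses uses log-sum-exp with the max subtracted; the
  point masses over the valid overlap range sum to 1 within $10^{-9}$.
* Tolerance for the planted-MI recovery check: the generator's "3 binomial
  standard errors" are propagated to the MI scale by the delta method over
  the three estimated counts,
  $\mathrm{se}(MI) = \frac{1}{\ln 2}\sqrt{\sum_k (1 - p_k)/n_k}$.
* Tie-breaks are deterministic everywhere: entity ranking by score, then
  count, then id; tagging by position, length, id; bucket keys sorted
  lexicographically. Reports are byte-stable across reruns.
* Degenerate inputs: empty corpora, empty mention files, queries with no
  hits, pathways without internal edges, proteins missing from the
  localization map (tagged `unknown`) and genes absent from the expression
  table (left unannotated) are all valid and tested.
* Country attribution is one country per paper, parsed from the last
  comma-separated token of the first affiliation against a bundled
  country-name list; unresolvable papers go to an explicit `unresolved`
  bucket so country counts always sum to the scope size. Author keys are
  surname + initials verbatim — no disambiguation, by design.

## Problem sizes used in the test-suite

Oracle equivalence runs at exhaustive-enumeration scale: all contingency
tables with $N \le 12$; fuzzed corpora of up to 100 abstracts for
pair/triad cross-product enumeration (20 seeds); random graphs of up to
200 nodes for BFS equivalence (20 seeds); up to 4 secondary groups for the
power-set bucket oracle. Planted-signal recovery uses the full study
conditions (2000 abstracts) across 10 seeds. These sizes make the oracles
exact while keeping the default test run fast.

## A worked example

```{r example}
gen <- generate_corpus(generator_config(seed = 1))
query_ids <- search_corpus(gen$corpus, parse_query(gen$query_term))
length(query_ids)
head(rank_entities(gen$corpus, query_ids, "gene",
                   dictionary = gen$dictionary), 3)
```

The planted gene `G001` ranks first with a score far above the rest; its
association score is $-\log_2 p / 100$ for the upper-tail probability of
its observed overlap with the query literature.

## Known limitations

Dictionary tagging is a stand-in for trained NER — it cannot resolve
abbreviations, novel surface forms, or cross-species normalization, and
its accuracy on real text is bounded by dictionary coverage. Co-occurrence
is abstract-level: it carries no relation semantics and no negation
handling. The triad hypergeometric depends on a split choice (documented
above). Multiple-testing correction is deliberately not applied — scores
are ranking devices, not calibrated p-values; treat them accordingly.
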