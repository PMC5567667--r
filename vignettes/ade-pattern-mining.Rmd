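---
title: "Mining associated adverse drug events with pattern structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining associated adverse drug events with pattern structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adepatterns)
```

## The problem and the model

Adverse drug events (ADEs) are complex: one event may involve several drugs
and manifest through several phenotypes, and the same event can be coded at
different granularities by different clinicians. This package mines
*associations between* ADEs — "patients who experience this kind of ADE also
tend to experience that kind" — in a way that can generalize over drug and
phenotype class hierarchies instead of treating every code as an opaque
token.

An ADE is a pair $(D, P)$ of a drug set and a phenotype set. A cohort is a
set of patients $G$, each mapped by $\delta$ to a description of its ADEs,
and descriptions live in a meet-semilattice $(\mathcal{D}, \sqcap)$: the
meet $X \sqcap Y$ is the most specific description of what $X$ and $Y$ have
in common, and induces the order $X \le Y \Leftrightarrow X \sqcap Y = X$
("$Y$ refines $X$"). The derivations

$$A^\Box = \sqcap_{g \in A}\, \delta(g), \qquad
  d^\Box = \{ g \in G \mid d \le \delta(g) \}$$

form a Galois connection; their fixed pairs $(A, d)$ — the pattern
concepts — organize the cohort into a lattice of patient subgroups, each
with the most specific ADE description all its members share. Association
rules are read off comparable concept pairs.

### The three description dialects

* **Dialect 1** indexes a patient's prescriptions by first-level phenotype
  class (ICD-9-CM chapter). Each component is an antichain of drug sets
  under $\subseteq$, and components meet by
  $X \sqcap_1 Y = \max(\subseteq, \{x \cap y\})$. No ontology semantics:
  generalization quickly degrades to empty sets, which is the motivation
  for the other two dialects.
* **Dialect 2** replaces drugs by their ATC classes and set intersection by
  the ontology meet
  $x \sqcap_\mathcal{O} y = \max(\sqsubseteq, \{\mathrm{LCA}(c_x, c_y)\})$.
  A drug mapped to several ATC classes simply contributes several classes.
* **Dialect 3** represents each ADE as a vector $\langle D, P \rangle$ of a
  drug-class antichain and a phenotype-class antichain, and a patient as an
  antichain of such vectors. The ADE meet applies $\sqcap_\mathcal{O}$ on
  both dimensions; when either side retains nothing below the ontology
  root, the result is the null vector $\langle \varnothing, \varnothing
  \rangle$ and is dropped, so meaningless generalizations do not propagate.

All three meets share one primitive, `generic_set_meet()`: all pairwise
element meets reduced to the maximal antichain. Associativity of the
reduced meet — the property the whole lattice construction rests on — is
exercised by property tests over hundreds of random instances per dialect.

## Extraction assumptions

The EHR extraction makes the usual short-term-reaction assumptions
explicit and configurable:

* **Window** (`max_interval_days = 14`): drugs from one visit, diagnoses
  from the next visit no more than 14 days later. A visit pair further
  apart contributes nothing. The bound is inclusive ($0 < \Delta \le 14$);
  candidate counts are non-decreasing in the bound, which the tests assert.
* **Same-day visits are merged** (union of drugs and diagnoses) before
  pairing, avoiding zero-length intervals whose direction would be
  arbitrary.
* **Side-effect filter**: a phenotype is kept only when it is a recorded
  side effect of at least one drug of the candidate's drug set.
* **Maximal drug sets**: within a patient, a candidate whose drug set is a
  strict subset of another's is discarded — a re-prescribed smaller set
  suggests tolerated drugs. Candidates with *identical* drug sets are
  merged with the union of their phenotypes: deleting both (a literal
  reading of the subset rule) would discard information, and merging keeps
  the operation idempotent.
* **Cohort filter** (`min_ades = 2`): associations need at least two ADEs
  per patient.

FAERS-like input skips the window logic (reports already are ADEs), applies
the same within-case drug-set inclusion exclusion, and keeps cases with at
least two distinct ADEs.

## Ontologies

ATC hierarchies are inferred from code syntax, keeping the three most
specific levels (pharmacological subgroup, chemical subgroup, chemical
substance) — the anatomical and therapeutic levels are too coarse to carry
signal and are dropped at load time. ICD-9-CM builders attach decimal codes
under three-digit codes under chapter ranges. Generic rooted DAGs
(SNOMED-like) load from parent–child edge lists; cycles are a hard error.

Two decisions matter downstream:

* **Level pruning is graph surgery**: for deep semantic comparison
  (dialect 3) the over-general levels (ICD chapters here) are deleted and
  their children re-parented to the root, so "excluded levels" is a
  structural property, not a query-time special case. The cut is exposed
  (`prune_general_levels()`) because hierarchies differ in depth.
* **DAG least common ancestors are sets**: on a DAG the LCA need not be
  unique; `lca()` returns all $\sqsubseteq$-minimal common ancestors and the
  meet flattens pairwise LCA sets before the max reduction. On trees this
  degenerates to the single-LCA behaviour.

Drugs or phenotypes without an ontology mapping become pseudo-classes
directly under the root: they compare only to themselves and can never
inflate a generalization.

## Lattice construction and numerical choices

Concepts are enumerated by CloseByOne over extents: patient sets are
extended one patient at a time in sorted-id order and closed through the
derivations, with a lectic canonicity test guaranteeing each concept is
produced exactly once. Runs are therefore bit-reproducible. Because
extension grows extents monotonically, a minimum-support threshold cannot
prune the search itself; `min_extent` filters the enumerated set (tested
equal to post-hoc filtering of the full lattice), and a `max_concepts`
guard aborts runaway enumerations with the partial count in the error.

Equality of descriptions is structural: every container is kept in a
canonical form (sorted codes, sorted elements) and serialized to a key;
meets, order checks and extents are memoized by key, which is what makes
the lattice affordable in pure R. Degenerate inputs are given definite
semantics: the empty chapter component is absorbing under the meet, the
empty prescription (`{}`) may survive as the sole maximal intersection, the
intent of an empty patient set is an error (the description top is not
constructible), and single-patient cohorts yield exactly one concept.

## Rules, filters, statistics

A rule comes from *any* comparable concept pair, not only lattice
neighbours — the definition only requires $\delta(l) <_\sqcap \delta(r)$,
and neighbours-only would lose transitive generalizations. Duplicate
$(L, R)$ pairs keep the largest-support instance. Defaults
(`min_support = 5`, `min_confidence = 0.75`, exclusion of ICD class 710 and
descendants, `alpha = 0.001`) follow standard practice for this kind of
screen and are all exposed as parameters.

The novelty filter keeps a rule only when its right-hand side introduces at
least one ADE whose drugs *and* phenotypes are hierarchy-incomparable with
every left-hand ADE; in dialects 1/2 the chapter key is the only phenotype
handle, so it plays the phenotype role there. Re-evaluation of a rule on a
second cohort (`evaluate_rule_on_cohort()`) counts the patients whose
description refines the rule's combined description — the in-memory
equivalent of re-running the rule as a database query against a larger
warehouse.

Pair statistics aggregate rules into drug-class pairs $(l, r)$ with
subclass-inclusive membership and *combined support* (union of supporting
patients — one patient can verify several rules, so supports are united,
never summed). Observed ratios are compared to the expected ratio of the
right class with a two-sided one-proportion Z-test; the two-sided choice
reflects that deviations in both directions are of interest. Expected
ratios of exactly 0 or 1, or empty rows, are marked untestable rather than
silently significant. No multiple-testing correction is applied; the
stringent default $\alpha = 0.001$ is the knob.

## What the synthetic generator does and does not emulate

`generate_cohort()` emulates the *structure* of a longitudinal EHR extract:
per-ADE visit pairs seven days apart (comfortably inside the window,
avoiding boundary ambiguity), successive pairs spaced 40 days (beyond any
tested window), a side-effect table covering every emitted pair plus
decoys, and planted associations: `carrier_count` patients (default 10)
receive both template ADEs, `exclusive_count` (default a quarter of the
carriers) receive only the first. The exclusive patients are essential: if
the two planted ADEs only ever occur together, their descriptions close to
a single concept and no rule can link them at confidence below 1 — the
asymmetry is what makes the association a rule at the default thresholds
(confidence $10/12 \approx 0.83$). Background ADEs are drawn from ontology
leaves hierarchy-incomparable with the planted classes, so recovery
supports are exact at zero noise; `noise_rate` adds one extra random ADE
per patient with the given probability. All sampling comes from one stream
keyed by `seed`.

What it does **not** emulate: realistic co-prescription patterns, disease
course, coding noise, confounding, drug forms, or temporal ordering of
ADEs. Passing the recovery suites therefore shows the machinery is sound —
extraction, generalization, closure and scoring do not lose or distort a
signal that is present — not that signals in real EHR data are this clean.
Test problem sizes (cohorts of 50–100 patients, toy ontologies of a few
dozen classes, 20 simulation seeds) were chosen as the smallest scales at
which every pipeline behaviour — generalization across classes, noise,
chance co-occurrence — is exercised; the design scales to thousands of
patients, but lattice size grows quickly with description detail, which is
the method's inherent cost.

## Known limitations

* Rules are co-occurrence statements: no causality, no temporal order.
* Lattice enumeration is exponential in the worst case; the `max_concepts`
  guard makes the failure mode explicit rather than open-ended.
* The dialect-1/2 chapter vector fixes the chapter key set cohort-wide; a
  phenotype outside every chapter contributes nothing in those dialects.
* Deep class hierarchies with many multi-parent nodes (full SNOMED) are
  supported structurally (set-valued LCAs) but have not been exercised
  beyond small random DAGs.
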