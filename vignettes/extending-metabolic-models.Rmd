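---
title: "Extending metabolic models with enzyme promiscuity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending metabolic models with enzyme promiscuity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmr)
options(emmr.verbose = FALSE)
```

## The problem

Genome-scale metabolic models catalogue the *annotated* activity of an
organism's enzymes. Most enzymes, however, also turn over substrates other
than their primary one ("underground metabolism"), and this promiscuous
activity is almost never represented in the model. `emmr` implements a
workflow that predicts such activity from the model itself: it learns local
biotransformation rules from the model's own reactions, applies them to the
model's metabolites, screens the predicted products against a metabolomics
table, and curates the survivors into balanced, evidence-classified
reactions that can be added to the model.

## The operator model

Every reaction with a resolvable main reactant–product pair is decomposed
into an **RDM pattern**:

* **R** — the reaction centre: the single mapped atom at which the
  transformation happens (it exists on both sides of the reaction);
* **D** — the difference region: atoms adjacent to R that are removed or
  added by the transformation;
* **M** — the matched region: atoms adjacent to R preserved by it.

Atoms are labelled with a KEGG-style atom-type code — a deterministic
function of the element, formal charge and radius-1 bonded environment
(about 30 codes; see `atom_type_table()` and
`inst/extdata/atom_types.tsv`). The lookup-table entry ("operator") has the
R and M types of the substrate as its key and the R and D types of the
product as its value, together with an explicit graph-edit payload (the
rooted fragment to delete and the rooted fragment to attach) so the rule
can be replayed on new molecules. Reactions are treated as reversible
unless the model bounds say otherwise, and a reversible reaction yields one
operator per direction. Pairs whose structural difference spans more than
one reaction centre are excluded — single-centre rules only — as are pairs
whose difference region is not attached to the centre (those are not local
edits).

The substrate–product atom correspondence is computed by a connected
maximum-common-substructure search (elements must agree; bonds between
mapped atoms must agree in presence and order on both sides). KEGG's own
curated reactant-pair alignments are not available offline, so this
alignment is the package's stand-in for them. Determinism matters more
here than speed: molecules are first relabelled into canonical order, the
branch-and-bound search visits candidates in a fixed order, and ties are
broken by mapped-atom count, then atom-type agreement, then the
lexicographically smallest mapping.

Applying an operator at a site is deliberately conservative: a candidate
site must carry the key's R type and contain the key's M and D types in its
first shell, and the branch to be deleted must be *exactly* isomorphic (as
a rooted fragment) to the operator's difference fragment. This prevents the
rule "remove a hydroxyl" from amputating half a phosphate group. After the
edit, implicit hydrogens are recomputed from a small valence model and the
product is revalidated; edits that violate valence are discarded with a
logged reason. Automorphic sites (equal rooted canonical keys) are
collapsed, so a symmetric molecule contributes each distinct site class
once.

## Structure identity

All deduplication, database matching and reference lookups use a canonical
structure key: constitution plus bond orders, with stereochemistry ignored
throughout (the transformation rules are constitutional, and printed
reaction equations distinguish stereoisomers by name, not by structure).
The key is computed by exact canonical labelling (igraph's BLISS backend)
of a coloured graph in which every bond is expanded into an auxiliary
vertex coloured by bond order. Identity is therefore exact, not
hash-based; atom-order permutation invariance is property-tested.

## Predicted products, metabolome screening

Operators are applied to a substrate pool. Following the study conditions
this package emulates, the pool is the set of metabolites with
concentration strictly above 1 µM ("above" read literally as strict
inequality; metabolites missing from the table fall into a retained
remainder pool that can be included with a flag). Products are enumerated
once — derivatives are not re-fed as substrates, since cascading
predictions multiply uncontrollably — and a derivative equal to its parent
is dropped. A prediction that merely rediscovers the operator's own native
reaction is flagged a self-transformation and excluded from new-prediction
reports.

Predicted products are then screened against a metabolomics table whose
records carry a declared primary (PubChem-like) id plus cross-references
(InChIKey, KEGG, CAS, ChEBI, BioCyc). Each cross-reference is resolved
through an offline lookup table (the deterministic stand-in for live
PubChem queries); the record's identity is settled by majority vote over
the resolved ids plus the declared id, one vote each. A strict majority
(more than half the cast votes) is required; anything else leaves the
record unresolved and excluded from matching — the conservative reading of
"majority vote" when no tie rule is stated. Matching prefers reconciled
primary ids and falls back to canonical structure keys when a record
carries a structure.

## Curation and the decision tree

Each verified substrate→product prediction is completed into a
stoichiometric reaction by copying the cofactor couple of the operator's
template (native) reaction side for side — NAD(H), NADP(H), ATP/ADP,
water, phosphate and so on, with template coefficients preserved. The
balance check reports signed per-element deltas (product minus substrate
side); a reaction passes when every heavy-atom delta is zero. Hydrogen and
charge deltas are reported separately and never asserted, because
protonation conventions differ across sources; an optional tolerance flag
allows the checker to absorb a residual O/H imbalance by adding only water
and protons, and logs the addition. The flag is off by default.

Kept candidates (after three discard filters applied in a fixed order:
externally-flagged infeasible, cofactor substrate, multi-centre) are
classified by a decision tree:

1. product already in the model: **C1** when the model documents the same
   substrate/product pair under a different enzyme (a parallel route),
   discard as already-in-model under the same enzyme;
2. otherwise, transformation documented for the organism in the reference
   databases: **C2** when the documented record matches at the equation
   level (or records no equation), **C1** when only the pair matches — a
   parallel route documented outside the model;
3. pair documented in other organisms only: **C3**;
4. otherwise: **C4**.

Step 2's equation-level test is a deliberate design choice. The curated
example set this package ships contains two candidates over the *same*
substrate/product pair and the same enzyme — one completed with the
phosphate/water couple, one with the ATP/ADP couple — that the source
curation places in different categories. A tree keyed on pairs alone
cannot separate them; keying the organism-documentation test on the full
participant multiset (direction-agnostic) reproduces the curated
assignment for all 23 candidates, and degrades gracefully to pair-level
matching for reference entries that record no equation. "Same enzyme" is
decided on gene sets when both sides carry genes, falling back to EC
numbers. The reference index is direction-agnostic throughout, consistent
with reversibility-by-default.

New-to-model metabolites are the distinct products of C2–C4 reactions not
already among the model's metabolite keys (C1 adds none). The count is
computed and reported transparently rather than asserted: the source
curation states a smaller figure than its own reaction list implies, and
does not say which derivatives it excluded.

## The synthetic universe generator

`generate_toy_universe()` builds desk-scale test worlds with known ground
truth. Molecules come from a small scaffold grammar — C4–C7 chains,
occasionally a ring, decorated with hydroxyl, carbonyl, carboxyl, amino
and phosphate groups — so that every native reaction is a single-centre
edit. Native reactions draw from five template chemistries (alcohol
oxidation with NAD⁺/NADH, phosphorylation with ATP/ADP, reductive
amination with NH₃ + NADH/H₂O + NAD⁺, decarboxylation releasing CO₂,
N-acetylation with acetyl-CoA/CoA), whose couples are chemically
consistent, so curated toy reactions are heavy-atom balanced by
construction. Cofactors are formula-only metabolites, which also exercises
the structure-less code path.

Promiscuity is planted by replaying real extracted operators on
non-native substrates and inserting the products into the synthetic
metabolome with consistent cross-references. The reference index is then
populated to realize a requested category mix: C2 pairs go into the
organism table, C3 pairs into the other-organism table, C4 pairs nowhere.
For C1 the generator adds the parallel native route to the model under a
fresh gene; the route's product enters the model *structure-less* and the
route carries no KEGG annotation, so it documents the pair without
spawning further operator applications — this keeps the invariant that
every planted product is reachable by exactly one application from exactly
one substrate, which is what makes planted labels unambiguous. A requested
mix that cannot be realized raises an error rather than silently
shrinking. All randomness flows through one integer seed, and the global
RNG state is restored on exit.

What passing these tests shows — and does not show. The generator's
chemistry is deliberately simple: no stereochemistry, no tautomers, no
aromatic heterocycle chemistry in the reaction rules, single-centre edits
only, and a metabolome whose records are either planted truths or designed
distractors. Perfect recall and label accuracy on these universes
demonstrate that the machinery is sound (extraction inverts application,
classification follows the reference data), not that real-world recall
would be perfect: on real data the binding constraints are the quality of
structure annotations, the coverage of the metabolomics table, and the
first-shell specificity of the operator keys.

## Numerical and engineering choices

* Implicit hydrogens everywhere; recomputed from charge-adjusted default
  valences (C4, N3, O2, S2/4/6, P3/5, halogens 1). Aromatic bonds count
  1.5 and the sum is rounded, which handles benzenoid and pyridine-type
  atoms exactly; pyrrole-type NH survives parsing (hydrogens are fixed
  before aromatization) but would be re-protonated incorrectly if a graph
  edit forced a global hydrogen recomputation on such a ring — a known
  limitation, irrelevant to the bundled chemistries.
* Aromaticity perception normalizes alternating Kekulé 5/6-rings to bond
  order 1.5 so that Kekulé and aromatic input collapse to one key.
* The MCS search carries a node budget (default 2×10⁵) as a safety valve
  against pathological symmetry; within desk scale it is exhaustive, and
  determinism is unaffected because exploration order is fixed.
* The pipeline reports one candidate reaction per verified
  (substrate, product) pair; when several operators predict the same pair
  the first in report order supplies the provenance and cofactor template.
  Pair multiplicity stays visible in the derivative report.
* Problem sizes used by the test-suite and the bundled examples: toy
  universes of about 10 scaffolds and 10 native reactions (≈20 operators,
  ≈20 planted products), five seeds for the property suites — small enough
  to re-derive every expected value by hand or brute force, large enough
  to exercise every branch of the decision tree.

## Known limitations

* Operator keys are strictly first-shell; chemistry whose selectivity
  depends on second-shell context will over- or under-match sites.
* Multi-centre transformations (transketolase-like) are excluded by
  design, mirroring the workflow this package implements; they are the
  natural next extension.
* The SBML reader covers the Level 3 core subset used by BiGG-style
  models (species, reactions, reversibility, RDF annotations, legacy
  GENE_ASSOCIATION notes), not groups or FBC objectives.
* Flux analysis of the extended model is out of scope; the output is a
  reaction list with provenance, balance reports and category labels.
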