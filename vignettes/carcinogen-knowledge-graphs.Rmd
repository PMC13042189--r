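---
title: "Carcinogen metabolism knowledge graphs: model, curation and scoring"
author: "xenoKG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carcinogen metabolism knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoKG)
```

## The model

`xenoKG` represents carcinogen metabolism as a typed property graph.
Nodes are one of five semantic types — carcinogens, enzymes, metabolites,
DNA adducts, and pathway context — and edges one of six directed
relationship types. The central modelling commitment is that *reaction
chaining is explicit*: an `ACTIVATES` edge runs from the enzyme to the
product it forms, and its `substrate_id` names the chemical consumed.
This turns the graph into two superimposed structures:

* a *bipartite catalysis structure* (enzyme → product, annotated with the
  substrate), which is what class filtering, search and neighbourhood
  queries operate on; and
* a *metabolic successor relation* between chemicals
  (substrate → product for activation; chemical → adduct for adduct
  formation), which is what reachability scoring operates on.

Assumptions worth stating. First, detoxification is terminal: the product
of a `DETOXIFIES` or `TRANSPORTS` edge is treated as a dead end, so a
conjugate never re-enters the successor relation. Consequently the
adducts an enzyme "averts" are those downstream of its *substrate*, not
its product. Second, kinetics are out of scope — edges are qualitative
assertions with provenance, not rate equations — so every derived
quantity is a set cardinality or a sum of curated activity scores, never
a flux. Third, the schema deliberately lets `ACTIVATES` target a
`CARCINOGEN` and `FORMS_ADDUCT` start from one: endogenous hormones are
both index carcinogens and metabolic products (testosterone → DHT,
testosterone → estradiol), and direct-acting alkylating agents form
adducts without a metabolite intermediate. A stricter enzyme → metabolite
reading would make the aromatase bridge unrepresentable.

Two schema invariants are enforced at the record level: an enzyme's role
bucket is `REPAIR` exactly when its phase is DNA repair and `TRANSPORT`
exactly when its phase is Phase III (the other three buckets —
activation, detoxification, mixed — are curation calls for Phase I/II
enzymes); and representative activity scores are non-negative and
enzyme-only. Container invariants (id uniqueness, endpoint-type table,
reference resolution, record-level edge uniqueness) are enforced on every
mutation, so downstream queries never defend against a half-valid graph.
The orphan rule — every node of a *built* reference graph has degree at
least one, counting substrate references as incidence — is checked only
by `validateGraph()`, because nodes are necessarily orphans mid-build and
isolated context nodes are legitimate in filtered views.

## The seed manifest and its curation choices

The packaged reference graph is built from a declarative JSON manifest
(`inst/extdata/reference_manifest.json`) with top-level keys `nodes`,
`edges` and `expected_inventory`. JSON was chosen over YAML because the
package's canonical graph dialect is JSON already and one parser fewer is
one failure mode fewer. Building is deterministic: the same manifest
yields byte-identical canonical serialisations.

The graph covers 15 index carcinogens in 9 classes, 36 enzymes
(14 Phase I, 14 Phase II, 3 transporters, 5 repair proteins), 28
metabolites, 11 adducts and 6 pathway nodes (four KEGG references plus
two curated context nodes: androgen-receptor signaling and an
oxidative-stress response node). The exemplar routes are curated in full:
benzo[a]pyrene → 7,8-epoxide → dihydrodiol → BPDE → BPDE-dG with
GSH-conjugate diversion; 4-aminobiphenyl N-hydroxylation with the
NAT2-detoxifies/NAT1-activates split; the androgen module with both the
5-alpha-reduction branch and the aromatase bridge into catechol-estrogen
quinone adducts; and aflatoxin B1 epoxidation with GST/EPHX1 diversion
and XPC repair. Beyond the named routes, the inventory is completed with
literature-standard intermediates (N-hydroxy-PhIP and its glucuronide,
methyldiazonium ion and O6-methylguanine for the nitrosamines, benzene
oxide/hydroquinone and 8-oxo-dG, chloroethylene oxide and etheno-dA,
direct N7-hydroxyethylguanine alkylation by ethylene oxide, the
DHEA/androstenedione synthesis context). These completions are manifest
content — curated, editable data — not derived facts.

Class tags are *stored* on nodes and edges so that filter results are
manifest-controlled, and `deriveClassMembership()` recomputes them from
topology as an audit: a class closure starts from the carcinogens tagged
with it, closes over the successor relation, then admits the enzymes
acting on closure chemicals, detoxification products, and repair enzymes
of closure adducts. On the packaged graph, derived and stored tags agree
exactly. Pathway-context membership is the one place derivation cannot
reach (class edges never target pathway nodes), so pathway nodes keep
their curated tags: the two androgen context nodes and their membership
edges are explicitly tagged, which is why the androgen filter view
includes its pathway context while all other pathway scaffolding stays
global. One consequence of the stored-tag design is that a filtered
edge may reference a substrate outside the retained set (the
androstenedione → testosterone step is androgen-tagged through its
target only); `filterGraph()` drops such substrate references rather
than the edge, keeping the subgraph valid.

Thirteen enzymes carry representative activity scores spanning eight of
the nine classes. The scored set was chosen to include every gene for
which a standard pharmacogenomic activity convention exists in this
pathway set — CYP1A1 (*2C high activity), GSTM1 and GSTT1 (null
deletions), NAT2 (slow acetylator), SRD5A2 (V89L/A49T), CYP19A1
(repeat-length variation), UGT2B17 (deletion), plus CYP1A2, CYP1B1,
CYP2A6, CYP3A4, EPHX1 and XPC — and covers all four role buckets
(7 activation, 4 detoxification, 1 mixed, 1 repair). The solvent class
is deliberately unscored: CYP2E1, its main activating enzyme, has no
standardised star-allele activity convention. Scores are dimensionless
on a normal-function = 1.0 scale and are ordinary manifest fields, meant
to be re-curated as conventions mature.

## Scoring definitions

`downstreamAdducts()` computes the fixed point of the successor relation
as a set closure (breadth-first over sets, not path enumeration), so it
terminates on metabolic cycles such as quinone/hydroquinone redox pairs.

`geneImpactScore()` reports `|A ∪ D ∪ R|`: formed (downstream of
activation products), averted (downstream of detoxification/transport
substrates) and repaired (direct repair targets) adducts, counted once
each. A *count of distinct adducts* was chosen over any weighted or
distance-discounted variant because it is the simplest statistic that is
auditable against the edge list by hand; per-role weights
(`w_A |A| + w_D |D| + w_R |R|`) are available as options with default 1,
and no cross-graph normalisation is applied — positioning raw counts is
a presentation choice, not a modelling one. Class reservoirs sum scored
activity by role with detoxification and transport negated, matching the
signed-bar convention of activation/detoxification reservoir plots;
mixed-function sums and repair counts are reported as separate fields
rather than folded into either sign. Output tables are ordered by gene
id, and ties everywhere resolve lexicographically, so exports are
reproducible byte-for-byte.

## Numerical and serialisation conventions

The canonical JSON dialect is versioned (`format_version`, currently
1.0); readers reject unknown major versions and report schema violations
with JSON-pointer paths. Serialisation is byte-stable: nodes, edges and
annotation keys are sorted, sets are emitted as sorted arrays, and
floats use full round-trip precision. Graph equality in tests is defined
as byte equality of canonical serialisations. CSV and GraphML exports
join multi-valued cells with `"|"`; hex colours are stored lowercase
with a leading `#`. Degenerate inputs are first-class: empty graphs
serialise and re-parse in every format, an empty class set filters to an
empty graph (distinct from `NULL`, which means "no restriction"), and an
all-whitespace search query is an error rather than a match-everything.

## The fixture generator and what the tests show

`generateFixture()` produces small random schema-valid graphs as a pure
function of an explicit seed (the caller's global RNG state is saved and
restored). Endpoints are sampled uniformly among type-admissible pairs,
substrates among chemicals, and duplicate records are never emitted;
unless cycles are requested, chemicals are totally ordered and
activation runs forward along that order, so the successor relation is a
DAG. The property suite runs the scoring layer against an independent
igraph-based reachability oracle on 100 fixtures of at most 30 nodes
(and a second hundred in the unit tests), checks tallies and
neighbourhoods against linear-scan oracles, and exercises closure
termination on an explicit redox-style cycle. Fixtures emulate the
*shape* of the data — typed nodes, substrate-chained reactions, partial
scoring — but not its biology: topology is uniform rather than
hub-dominated, class structure is degenerate (one class per fixture
carcinogen), and annotations are empty. Passing fixtures therefore
demonstrates correctness of the graph machinery, not realism of any
curated content; the reference graph's own checks (inventory
verification, route completeness, derived-vs-stored tags) carry that
burden. Problem sizes were chosen so the whole suite stays interactive
(well under a minute) while still giving the oracle comparisons hundreds
of non-trivial cases.

## Known limitations

* Edges are qualitative: no stoichiometry, kinetics, induction or
  co-exposure modulation; the impact score is a reachability count, not
  a risk estimate, and the package intentionally stops short of any
  patient-level composite risk classification.
* Activity scores are representative single values, not
  diplotype-resolved phenotypes; translating genotypes to scores is out
  of scope.
* The extension node types (`GENE`, `TISSUE`) are admitted by the schema
  switch and style map but the packaged reference content does not use
  them; receptor/tissue/variant extension content is a curation project,
  not a code change.
* The reference manifest is hand-maintained. Its counts are verified on
  every build, but its biology is a curated snapshot, not a live mirror
  of IARC/KEGG/PharmVar/CPIC.
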