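# xenoKG

Typed knowledge graphs for carcinogen metabolism and DNA-adduct pathways.

Most chemical carcinogens are pro-carcinogens: the parent compound is
harmless until xenobiotic-metabolizing enzymes bioactivate it into a
reactive ultimate carcinogen that covalently modifies DNA. Whether a given
exposure ends in a DNA adduct depends on the balance of four enzyme
layers — Phase I activation (largely cytochrome P450s), Phase II
conjugation (GSTs, NATs, UGTs, SULTs, COMT), Phase III efflux transport
(ABC transporters), and DNA repair — and that balance is strongly shaped
by pharmacogenomic variation (GSTM1 null, NAT2 slow acetylation, CYP1A1
high-activity alleles, UGT2B17 deletion, ...). `xenoKG` gives researchers
working on gene–environment interaction a validated, scriptable engine
for exactly this structure: a typed property graph of
carcinogen → enzyme → metabolite → DNA-adduct pathways with class
filtering, metadata search, topology-aware pharmacogenomic scoring, and
standard graph-format export.

## The model

The schema admits five node types (`CARCINOGEN`, `ENZYME`, `METABOLITE`,
`DNA_ADDUCT`, `PATHWAY`; plus `GENE`/`TISSUE` in extension mode) and six
directed edge types (`ACTIVATES`, `DETOXIFIES`, `TRANSPORTS`,
`FORMS_ADDUCT`, `REPAIRS`, `PATHWAY`), each with endpoint-type
constraints. Activation, detoxification and transport edges carry a
`substrate_id` naming the chemical acted upon, which makes reaction
chaining explicit: the *metabolic successor relation*

```
succ(x) = { target(e) : e in ACTIVATES, substrate(e) = x }
        ∪ { target(e) : e in FORMS_ADDUCT, source(e) = x }
```

is the backbone of everything downstream. For a chemical *x*,
`downstreamAdducts(g, x)` is the set of DNA-adduct nodes in the closure of
*succ* from *x*. For an enzyme *E*, the topology-aware gene impact score
is the distinct-adduct count

```
impact(E) = | A(E) ∪ D(E) ∪ R(E) |
```

where `A` are adducts downstream of the products of its activation edges,
`D` adducts downstream of the substrates of its
detoxification/transport edges (the damage it helps avert), and `R` the
direct targets of its repair edges. Class-level reservoirs sum the
representative activity scores of scored enzymes per carcinogen class,
with activation positive and detoxification/transport negative.

The packaged reference graph — built deterministically from a declarative
JSON manifest — covers 9 carcinogen classes across 15 index carcinogens,
36 enzymes (14 Phase I, 14 Phase II, 3 Phase III, 5 DNA repair), 28
metabolites, 11 DNA adducts and 6 pathway nodes: 96 nodes and 102 edges
in total, including the benzo[a]pyrene diol-epoxide route, the
4-aminobiphenyl N-hydroxylation route, the aflatoxin B1 epoxide route and
the androgen/aromatase bridge into catechol-estrogen genotoxicity.

## Worked example

```r
library(xenoKG)

g <- referenceGraph()
g
#> KnowledgeGraph 'carcinogen-metabolism-reference' (format 1.0)
#>   96 nodes, 102 edges
#>   nodes: CARCINOGEN=15, ENZYME=36, METABOLITE=28, DNA_ADDUCT=11, PATHWAY=6
#>   edges: ACTIVATES=25, DETOXIFIES=16, TRANSPORTS=3, FORMS_ADDUCT=11, REPAIRS=9, PATHWAY=38

downstreamAdducts(g, "benzo_a_pyrene")
#> [1] "BPDE-dG"

andro <- filterGraph(g, classes = "ANDROGEN")
c(nodes = numNodes(andro), edges = numEdges(andro))
#> nodes edges
#>    26    19

searchGraph(g, "CYP1")$matched
#> [1] "CYP17A1" "CYP19A1" "CYP1A1"  "CYP1A2"  "CYP1B1"

tabs <- scoreAll(g)
nrow(tabs$genes); nrow(tabs$classes)
#> [1] 13
#> [1] 8
head(tabs$genes, 4)
#>   gene_id       role activity_score impact_score class_touch_count
#> 1 CYP19A1 ACTIVATION           1.00            2                 2
#> 2  CYP1A1 ACTIVATION           1.50            1                 1
#> 3  CYP1A2 ACTIVATION           1.00            4                 3
#> 4  CYP1B1 ACTIVATION           1.25            3                 3
```

The androgen filter retains 26 nodes and 19 edges because the aromatase
bridge (CYP19A1) pulls the estrogen-quinone branch — catechol formation,
the depurinating adenine/guanine adducts and their handling enzymes —
into the androgen view together with the curated AR-signaling and steroid
biosynthesis pathway context. The scoring table shows, e.g., that CYP1A2
influences 4 distinct adducts (heterocyclic amine, aromatic amine and
aflatoxin routes) across 3 carcinogen classes.

A command-line wrapper is installed at `inst/scripts/xenokg`:

```sh
Rscript inst/scripts/xenokg build --out graph.json
Rscript inst/scripts/xenokg filter --class androgen --in graph.json --out androgen.json
Rscript inst/scripts/xenokg score --gene-csv genes.csv --class-csv classes.csv
Rscript inst/scripts/xenokg export --format graphml --out graph.graphml
```

## Documentation

The methods vignette (`vignettes/carcinogen-knowledge-graphs.Rmd`)
describes the schema and its validity rules, the seed manifest and the
curation choices behind it, the scoring definitions, the numerical and
serialisation conventions, the random-fixture generator used by the
property tests, and known limitations.
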