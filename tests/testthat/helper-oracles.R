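# Independent brute-force oracles, coded only against the public record
# accessors. They deliberately re-derive everything from flat edge lists
# (via igraph where reachability is needed) rather than reusing any of the
# package's traversal code.

edgeRecords <- function(g) lapply(edgeIds(g), function(id) getEdge(g, id))
nodeRecords <- function(g) lapply(nodeIds(g), function(id) getNode(g, id))

# linear-scan tally of node types / enzyme phases
oracleTypeTally <- function(g) {
  tab <- setNames(rep(0L, length(nodeTypes())), nodeTypes())
  for (n in nodeRecords(g)) tab[[n$node_type]] <- tab[[n$node_type]] + 1L
  tab
}

oraclePhaseTally <- function(g) {
  tab <- setNames(rep(0L, length(enzymePhases())), enzymePhases())
  for (n in nodeRecords(g)) {
    if (n$node_type == "ENZYME") tab[[n$phase]] <- tab[[n$phase]] + 1L
  }
  tab
}

# neighbourhood by exhaustive edge scan; substrate references count as
# incoming incidence on the substrate node
oracleNeighbors <- function(g, id, direction = "both") {
  out <- character()
  for (e in edgeRecords(g)) {
    sub <- e$substrate_id
    if (direction %in% c("out", "both") && e$source == id) {
      out <- c(out, e$target, sub)
    }
    if (direction %in% c("in", "both")) {
      if (e$target == id) out <- c(out, e$source)
      if (!is.null(sub) && sub == id) out <- c(out, e$source, e$target)
    }
  }
  sort(setdiff(unique(out), id))
}

# downstream adducts via igraph reachability over the explicit successor
# relation (activation substrate -> product; chemical source -> adduct)
oracleDownstream <- function(g, start) {
  pairs <- list()
  for (e in edgeRecords(g)) {
    if (e$edge_type == "ACTIVATES" && !is.null(e$substrate_id)) {
      pairs[[length(pairs) + 1L]] <- c(e$substrate_id, e$target)
    } else if (e$edge_type == "FORMS_ADDUCT") {
      pairs[[length(pairs) + 1L]] <- c(e$source, e$target)
    }
  }
  if (!length(pairs)) return(character())
  em <- do.call(rbind, pairs)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2]), directed = TRUE,
    vertices = data.frame(name = nodeIds(g)))
  reach <- names(igraph::subcomponent(ig, start, mode = "out"))
  adducts <- vapply(nodeRecords(g), function(n)
    if (n$node_type == "DNA_ADDUCT") n$id else NA_character_, "")
  sort(intersect(reach, adducts[!is.na(adducts)]))
}

# gene impact recomputed from the flat edge list and oracleDownstream
oracleImpact <- function(g, enzId) {
  adducts <- vapply(nodeRecords(g), function(n)
    if (n$node_type == "DNA_ADDUCT") n$id else NA_character_, "")
  adducts <- adducts[!is.na(adducts)]
  chems <- vapply(nodeRecords(g), function(n)
    if (n$node_type %in% c("CARCINOGEN", "METABOLITE")) n$id
    else NA_character_, "")
  chems <- chems[!is.na(chems)]
  hit <- character()
  for (e in edgeRecords(g)) {
    if (e$source != enzId) next
    if (e$edge_type == "ACTIVATES") {
      if (e$target %in% adducts) hit <- c(hit, e$target)
      if (e$target %in% chems) hit <- c(hit, oracleDownstream(g, e$target))
    } else if (e$edge_type %in% c("DETOXIFIES", "TRANSPORTS")) {
      if (!is.null(e$substrate_id))
        hit <- c(hit, oracleDownstream(g, e$substrate_id))
    } else if (e$edge_type == "REPAIRS") {
      hit <- c(hit, e$target)
    }
  }
  length(unique(hit))
}

# tiny hand-built graph used across store/scoring tests
tinyChainGraph <- function() {
  g <- emptyGraph(name = "tiny-chain")
  g <- addNode(g, kgNode("C1", "carcinogen", "CARCINOGEN",
                         classes = "PAH"))
  g <- addNode(g, kgNode("E1", "activase", "ENZYME", phase = "PHASE_I",
                         role = "ACTIVATION", activityScore = 1))
  g <- addNode(g, kgNode("E2", "conjugase", "ENZYME", phase = "PHASE_II",
                         role = "DETOXIFICATION", activityScore = 0.5))
  g <- addNode(g, kgNode("R1", "repairase", "ENZYME",
                         phase = "DNA_REPAIR", role = "REPAIR"))
  g <- addNode(g, kgNode("M1", "reactive metabolite", "METABOLITE"))
  g <- addNode(g, kgNode("M2", "conjugate", "METABOLITE"))
  g <- addNode(g, kgNode("A1", "adduct", "DNA_ADDUCT"))
  g <- addEdge(g, kgEdge("e1", "E1", "M1", "ACTIVATES",
                         substrateId = "C1"))
  g <- addEdge(g, kgEdge("e2", "M1", "A1", "FORMS_ADDUCT"))
  g <- addEdge(g, kgEdge("e3", "E2", "M2", "DETOXIFIES",
                         substrateId = "M1"))
  g <- addEdge(g, kgEdge("e4", "R1", "A1", "REPAIRS"))
  xenoKG:::.stampDerivedClasses(g)
}

# metabolite cycle (M1 -> M2 -> M1 through two activation steps)
cyclicGraph <- function() {
  g <- emptyGraph(name = "cycle")
  g <- addNode(g, kgNode("C1", "carcinogen", "CARCINOGEN",
                         classes = "SOLVENT"))
  g <- addNode(g, kgNode("E1", "oxidase", "ENZYME", phase = "PHASE_I",
                         role = "ACTIVATION"))
  g <- addNode(g, kgNode("E2", "reductase", "ENZYME", phase = "PHASE_II",
                         role = "DETOXIFICATION"))
  g <- addNode(g, kgNode("M1", "quinone", "METABOLITE"))
  g <- addNode(g, kgNode("M2", "hydroquinone", "METABOLITE"))
  g <- addNode(g, kgNode("A1", "oxidative lesion", "DNA_ADDUCT"))
  g <- addEdge(g, kgEdge("e1", "E1", "M1", "ACTIVATES",
                         substrateId = "C1"))
  g <- addEdge(g, kgEdge("e2", "E1", "M2", "ACTIVATES",
                         substrateId = "M1"))
  g <- addEdge(g, kgEdge("e3", "E2", "M1", "ACTIVATES",
                         substrateId = "M2"))
  g <- addEdge(g, kgEdge("e4", "M2", "A1", "FORMS_ADDUCT"))
  g
}
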