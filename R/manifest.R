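# Seed manifest: declarative JSON description from which the packaged
# reference graph is built deterministically, plus the printed inventory
# expectations it must reproduce.

.MANIFEST_KEYS <- c("name", "version", "nodes", "edges",
                    "expected_inventory")

.referenceCarcinogens <- function() {
  c("benzo_a_pyrene", "DMBA", "PhIP", "MeIQx", "4-ABP", "benzidine",
    "NNK", "NDMA", "aflatoxin_B1", "estradiol", "testosterone", "DHT",
    "benzene", "vinyl_chloride", "ethylene_oxide")
}

.referenceEnzymePhases <- function() {
  c(CYP1A1 = "PHASE_I", CYP1B1 = "PHASE_I", CYP1A2 = "PHASE_I",
    CYP2A6 = "PHASE_I", CYP2A13 = "PHASE_I", CYP2E1 = "PHASE_I",
    CYP3A4 = "PHASE_I", CYP17A1 = "PHASE_I", SRD5A1 = "PHASE_I",
    SRD5A2 = "PHASE_I", CYP19A1 = "PHASE_I", CYP3A5 = "PHASE_I",
    AKR1C3 = "PHASE_I", HSD3B2 = "PHASE_I",
    EPHX1 = "PHASE_II", GSTM1 = "PHASE_II", GSTT1 = "PHASE_II",
    GSTP1 = "PHASE_II", NAT1 = "PHASE_II", NAT2 = "PHASE_II",
    SULT1A1 = "PHASE_II", UGT1A1 = "PHASE_II", UGT2B7 = "PHASE_II",
    UGT2B17 = "PHASE_II", UGT2B15 = "PHASE_II", NQO1 = "PHASE_II",
    COMT = "PHASE_II", AKR1C2 = "PHASE_II",
    ABCB1 = "PHASE_III", ABCG2 = "PHASE_III", ABCC2 = "PHASE_III",
    OGG1 = "DNA_REPAIR", XRCC1 = "DNA_REPAIR", ERCC2 = "DNA_REPAIR",
    XPC = "DNA_REPAIR", MGMT = "DNA_REPAIR")
}

.referenceKeggPathways <- function() {
  c("hsa00980", "hsa00140", "hsa05204", "hsa05208")
}

# Required curated routes (source, edge type, target, substrate or NA):
# the exemplar activation/detoxification/adduct/repair chains the
# reference graph must contain.
.requiredRouteEdges <- function() {
  rbind(
    c("CYP1A1", "ACTIVATES", "BaP-7,8-epoxide", "benzo_a_pyrene"),
    c("CYP1B1", "ACTIVATES", "BaP-7,8-epoxide", "benzo_a_pyrene"),
    c("EPHX1", "ACTIVATES", "BaP-7,8-dihydrodiol", "BaP-7,8-epoxide"),
    c("CYP1A1", "ACTIVATES", "BPDE", "BaP-7,8-dihydrodiol"),
    c("BPDE", "FORMS_ADDUCT", "BPDE-dG", NA),
    c("GSTM1", "DETOXIFIES", "BPDE-GSH", "BPDE"),
    c("GSTP1", "DETOXIFIES", "BPDE-GSH", "BPDE"),
    c("CYP1A2", "ACTIVATES", "N-OH-4-ABP", "4-ABP"),
    c("NAT2", "DETOXIFIES", "N-acetyl-4-ABP", "4-ABP"),
    c("NAT1", "ACTIVATES", "N-acetoxy-4-ABP", "N-OH-4-ABP"),
    c("N-acetoxy-4-ABP", "FORMS_ADDUCT", "dG-C8-4-ABP", NA),
    c("SRD5A1", "ACTIVATES", "DHT", "testosterone"),
    c("SRD5A2", "ACTIVATES", "DHT", "testosterone"),
    c("CYP19A1", "ACTIVATES", "estradiol", "testosterone"),
    c("CYP1B1", "ACTIVATES", "4-OH-estradiol", "estradiol"),
    c("CYP1B1", "ACTIVATES", "estradiol-3,4-quinone", "4-OH-estradiol"),
    c("estradiol-3,4-quinone", "FORMS_ADDUCT", "4-OHE2-N3-adenine", NA),
    c("estradiol-3,4-quinone", "FORMS_ADDUCT", "4-OHE2-N7-guanine", NA),
    c("CYP3A4", "ACTIVATES", "AFB1-8,9-epoxide", "aflatoxin_B1"),
    c("CYP1A2", "ACTIVATES", "AFB1-8,9-epoxide", "aflatoxin_B1"),
    c("AFB1-8,9-epoxide", "FORMS_ADDUCT", "AFB1-N7-Gua", NA),
    c("GSTM1", "DETOXIFIES", "AFB1-GSH", "AFB1-8,9-epoxide"),
    c("GSTT1", "DETOXIFIES", "AFB1-GSH", "AFB1-8,9-epoxide"),
    c("EPHX1", "DETOXIFIES", "AFB1-dihydrodiol", "AFB1-8,9-epoxide"),
    c("XPC", "REPAIRS", "AFB1-N7-Gua", NA))
}

#' Load a seed manifest
#'
#' Parses the declarative JSON manifest (top-level keys `nodes`, `edges`,
#' `expected_inventory`) and performs schema checks: unique node ids and
#' resolvable edge declarations. Declarations keep file order.
#'
#' @param path Path to a manifest JSON file. The packaged reference
#'   manifest is the default.
#' @return A list of class `kgSeedManifest`.
#' @export
loadManifest <- function(path = referenceManifestPath()) {
  if (!file.exists(path))
    stop("manifest file does not exist: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                             collapse = "\n"), simplifyVector = FALSE),
    error = function(e)
      stop("manifest parse error in '", path, "': ",
           conditionMessage(e), call. = FALSE))
  if (!all(c("nodes", "edges") %in% names(doc)))
    stop("manifest schema mismatch: top-level 'nodes' and 'edges' required",
         call. = FALSE)
  if (!length(doc$nodes))
    stop("manifest schema mismatch: no node declarations", call. = FALSE)
  ids <- vapply(doc$nodes, function(n) as.character(n$id %||% ""), "")
  dup <- ids[duplicated(ids)]
  if (any(!nzchar(ids)))
    stop("manifest schema mismatch: node declaration without id",
         call. = FALSE)
  if (length(dup))
    stop("manifest schema mismatch: duplicate node id(s) ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  for (e in doc$edges) {
    for (ref in c(e$source, e$target, e$substrate_id)) {
      if (!ref %in% ids)
        stop(sprintf(
          "manifest schema mismatch: edge '%s' references unknown node '%s'",
          e$id %||% "<no id>", ref), call. = FALSE)
    }
  }
  structure(list(name = doc$name %||% "reference-graph",
                 version = doc$version %||% "1.0",
                 nodes = doc$nodes, edges = doc$edges,
                 expected_inventory = lapply(doc$expected_inventory,
                                             as.numeric)),
            class = "kgSeedManifest")
}

#' Path of the packaged reference manifest
#' @return File path inside the installed package.
#' @export
referenceManifestPath <- function() {
  system.file("extdata", "reference_manifest.json", package = "xenoKG",
              mustWork = TRUE)
}

#' Build the reference knowledge graph from a manifest
#'
#' Deterministically constructs the graph (same manifest, same bytes under
#' canonical serialisation), validates every container invariant, and
#' checks the required reference content: the 15 index carcinogens, the 36
#' enzymes with their functional phases, the four KEGG pathway nodes plus
#' two curated pathway-context nodes, and the exemplar
#' activation/detoxification/adduct/repair routes (benzo[a]pyrene,
#' 4-aminobiphenyl, the androgen/aromatase bridge, aflatoxin B1). A
#' missing required entity raises a completeness error naming it.
#'
#' @param manifest A `kgSeedManifest` from [loadManifest()], or a path to
#'   a manifest file.
#' @return A validated [KnowledgeGraph-class] object.
#' @examples
#' g <- buildReferenceGraph(loadManifest())
#' numNodes(g)
#' @export
buildReferenceGraph <- function(manifest = loadManifest()) {
  if (is.character(manifest)) manifest <- loadManifest(manifest)
  stopifnot(inherits(manifest, "kgSeedManifest"))
  g <- emptyGraph(name = manifest$name, version = manifest$version)
  for (nd in manifest$nodes) {
    g <- addNode(g, kgNode(
      id = nd$id, label = nd$label %||% nd$id, nodeType = nd$node_type,
      classes = unlist(nd$classes) %||% character(),
      phase = nd$phase, role = nd$role,
      activityScore = nd$activity_score,
      annotations = nd$annotations))
  }
  for (ed in manifest$edges) {
    g <- addEdge(g, kgEdge(
      id = ed$id, source = ed$source, target = ed$target,
      edgeType = ed$edge_type, substrateId = ed$substrate_id,
      classes = unlist(ed$classes) %||% character(),
      annotations = ed$annotations))
  }
  v <- validateGraph(g)
  if (length(v))
    stop("reference graph invalid: ", paste(v, collapse = "; "),
         call. = FALSE)
  .checkReferenceCompleteness(g)
  g
}

.checkReferenceCompleteness <- function(g) {
  miss <- setdiff(.referenceCarcinogens(), nodeIds(g))
  if (length(miss))
    stop("reference graph incomplete: missing carcinogen(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  phases <- .referenceEnzymePhases()
  for (enz in names(phases)) {
    if (!enz %in% nodeIds(g))
      stop("reference graph incomplete: missing enzyme ", enz,
           call. = FALSE)
    n <- getNode(g, enz)
    if (!identical(n$phase, unname(phases[enz])))
      stop(sprintf("reference graph incomplete: enzyme %s must be %s",
                   enz, phases[enz]), call. = FALSE)
  }
  miss <- setdiff(.referenceKeggPathways(), nodeIds(g))
  if (length(miss))
    stop("reference graph incomplete: missing KEGG pathway node(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  pw <- nodeIds(g)[vapply(g@nodes, `[[`, "", "node_type") == "PATHWAY"]
  if (length(setdiff(pw, .referenceKeggPathways())) != 2L)
    stop("reference graph incomplete: expected exactly 2 curated pathway-context nodes",
         call. = FALSE)
  req <- .requiredRouteEdges()
  for (i in seq_len(nrow(req))) {
    hit <- any(vapply(g@edges, function(e) {
      e$source == req[i, 1] && e$edge_type == req[i, 2] &&
        e$target == req[i, 3] &&
        (is.na(req[i, 4]) || identical(e$substrate_id, req[i, 4]))
    }, NA))
    if (!hit)
      stop(sprintf(
        "reference graph incomplete: missing required route edge %s -[%s]-> %s",
        req[i, 1], req[i, 2], req[i, 3]), call. = FALSE)
  }
  invisible(TRUE)
}

#' The packaged reference graph
#'
#' Builds (and memoises for the session) the reference graph from the
#' packaged manifest: 96 nodes and 102 directed edges spanning the nine
#' carcinogen classes.
#'
#' @return A [KnowledgeGraph-class] object.
#' @examples
#' referenceGraph()
#' @export
referenceGraph <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildReferenceGraph(loadManifest())
    cache
  }
})

#' Verify a graph against printed inventory expectations
#'
#' Recomputes, for each expectation key, the observed value from the graph
#' and reports a one-row-per-check table. Supported keys: `total_nodes`,
#' `total_edges`, `nodes_<NODETYPE>`, `enzymes_<PHASE>`,
#' `carcinogen_classes` (distinct classes on carcinogen nodes),
#' `node_types` / `edge_types` (distinct types present),
#' `androgen_filter_nodes` / `androgen_filter_edges` (androgen class
#' subgraph), `scored_enzymes` and `scored_classes` (scoring-table row
#' counts).
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param expected Named numeric vector or list of expected counts; by
#'   default the packaged manifest's `expected_inventory`.
#' @return A data frame with columns `check`, `expected`, `observed`,
#'   `pass`; attribute `pass` is `TRUE` iff all rows pass.
#' @examples
#' rep <- verifyInventory(referenceGraph())
#' all(rep$pass)
#' @export
verifyInventory <- function(graph,
                            expected = loadManifest()$expected_inventory) {
  expected <- unlist(expected)
  observe <- function(key) {
    counts <- nodeCountsByType(graph)
    phases <- enzymeCountsByPhase(graph)
    if (key == "total_nodes") return(numNodes(graph))
    if (key == "total_edges") return(numEdges(graph))
    if (grepl("^nodes_", key)) {
      tp <- sub("^nodes_", "", key)
      if (!tp %in% names(counts)) return(NA_real_)
      return(counts[[tp]])
    }
    if (grepl("^enzymes_", key)) {
      ph <- sub("^enzymes_", "", key)
      if (!ph %in% names(phases)) return(NA_real_)
      return(phases[[ph]])
    }
    if (key == "carcinogen_classes") {
      carc <- Filter(function(n) n$node_type == "CARCINOGEN", graph@nodes)
      return(length(unique(unlist(lapply(carc, `[[`, "classes")))))
    }
    if (key == "node_types")
      return(length(unique(vapply(graph@nodes, `[[`, "", "node_type"))))
    if (key == "edge_types")
      return(length(unique(vapply(graph@edges, `[[`, "", "edge_type"))))
    if (key == "androgen_filter_nodes")
      return(numNodes(filterGraph(graph, classes = "ANDROGEN")))
    if (key == "androgen_filter_edges")
      return(numEdges(filterGraph(graph, classes = "ANDROGEN")))
    if (key == "scored_enzymes") return(nrow(scoreAll(graph)$genes))
    if (key == "scored_classes") return(nrow(scoreAll(graph)$classes))
    NA_real_
  }
  observed <- vapply(names(expected), observe, 0)
  out <- data.frame(check = names(expected),
                    expected = as.numeric(expected),
                    observed = as.numeric(observed),
                    pass = !is.na(observed) &
                      as.numeric(observed) == as.numeric(expected),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pass") <- all(out$pass)
  out
}
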