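#' DNA adducts reachable downstream of a chemical
#'
#' Computes the fixed point of the metabolic successor relation from a
#' carcinogen or metabolite node — activation edges are followed through
#' their substrate reference to the product they yield, adduct-formation
#' edges from their chemical source to the adduct — and returns every
#' DNA-adduct node in the closure. Implemented as a set closure, not a
#' path enumeration, so it terminates on metabolic cycles.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param id Id of a CARCINOGEN or METABOLITE node.
#' @return Sorted character vector of DNA_ADDUCT node ids.
#' @examples
#' downstreamAdducts(referenceGraph(), "benzo_a_pyrene")
#' @export
downstreamAdducts <- function(graph, id) {
  n <- getNode(graph, id)
  if (!n$node_type %in% c("CARCINOGEN", "METABOLITE"))
    stop(sprintf("downstreamAdducts starts from a CARCINOGEN or METABOLITE, '%s' is a %s",
                 id, n$node_type), call. = FALSE)
  closure <- .metabolicClosure(graph, id)
  sort(closure[vapply(graph@nodes[closure], `[[`, "", "node_type") ==
                 "DNA_ADDUCT"])
}

#' Topology-aware gene impact score
#'
#' Scores an enzyme by its position relative to downstream DNA-adduct
#' formation and repair: the impact score is the number of *distinct*
#' adducts the enzyme can influence, the union of three sets. Formed
#' adducts (A): adducts downstream of the products of the enzyme's
#' activation edges. Averted adducts (D): adducts downstream of the
#' substrates of its detoxification and transport edges — the damage the
#' enzyme helps divert (products of detoxification are dead ends by
#' construction, so the substrate, not the product, carries the risk).
#' Repaired adducts (R): direct targets of its repair edges. Optional
#' per-role weights turn the default distinct-adduct count
#' (`weights = c(1, 1, 1)`, a plain union cardinality) into the weighted
#' sum `w_A |A| + w_D |D| + w_R |R|`.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param id Id of an ENZYME node.
#' @param weights Numeric length-3 vector `c(activation, averted, repair)`;
#'   the default `c(1, 1, 1)` reports `|A u D u R|`.
#' @return A one-row data frame with columns `gene_id`, `role`,
#'   `activity_score` (NA when the enzyme is unscored), `impact_score`,
#'   `class_touch_count`.
#' @examples
#' geneImpactScore(referenceGraph(), "XPC")
#' @export
geneImpactScore <- function(graph, id, weights = c(1, 1, 1)) {
  n <- getNode(graph, id)
  if (!identical(n$node_type, "ENZYME"))
    stop(sprintf("geneImpactScore expects an ENZYME node, '%s' is a %s",
                 id, n$node_type), call. = FALSE)
  stopifnot(is.numeric(weights), length(weights) == 3L)
  adductIds <- names(graph@nodes)[vapply(graph@nodes, `[[`, "",
                                         "node_type") == "DNA_ADDUCT"]
  A <- D <- R <- character()
  for (eid in graph@outIndex[[id]] %||% character()) {
    e <- graph@edges[[eid]]
    if (e$edge_type == "ACTIVATES") {
      A <- c(A, intersect(e$target, adductIds))
      if (graph@nodes[[e$target]]$node_type %in%
          c("CARCINOGEN", "METABOLITE"))
        A <- c(A, downstreamAdducts(graph, e$target))
    } else if (e$edge_type %in% c("DETOXIFIES", "TRANSPORTS")) {
      if (!is.null(e$substrate_id))
        D <- c(D, downstreamAdducts(graph, e$substrate_id))
    } else if (e$edge_type == "REPAIRS") {
      R <- c(R, e$target)
    }
  }
  A <- unique(A); D <- unique(D); R <- unique(R)
  impact <- if (identical(as.numeric(weights), c(1, 1, 1))) {
    length(unique(c(A, D, R)))
  } else {
    weights[1] * length(A) + weights[2] * length(D) + weights[3] * length(R)
  }
  data.frame(gene_id = id,
             role = n$role,
             activity_score = n$activity_score %||% NA_real_,
             impact_score = impact,
             class_touch_count = length(n$classes),
             stringsAsFactors = FALSE)
}

#' Class-level reservoir of scored activation and detoxification support
#'
#' Summarises the scored enzymes (those carrying a representative activity
#' score) tagged with a carcinogen class. Activation capacity is the sum
#' of their activity scores; detoxification capacity — including transport
#' — is reported as a negative sum, matching the signed bar convention of
#' class-reservoir plots; mixed-function and repair contributions are
#' reported as separate fields.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param carcinogenClass One of [carcinogenClasses()].
#' @return A one-row data frame with columns `carcinogen_class`,
#'   `activation_sum`, `detoxification_sum` (<= 0), `mixed_sum`,
#'   `repair_count`, `scored_gene_count`.
#' @export
classReservoir <- function(graph, carcinogenClass) {
  if (!carcinogenClass %in% carcinogenClasses())
    stop("unknown carcinogen class: ", carcinogenClass, call. = FALSE)
  scored <- Filter(function(n) identical(n$node_type, "ENZYME") &&
                     !is.null(n$activity_score) &&
                     carcinogenClass %in% n$classes, graph@nodes)
  roleOf <- vapply(scored, `[[`, "", "role")
  scoreOf <- vapply(scored, `[[`, 0, "activity_score")
  data.frame(
    carcinogen_class = carcinogenClass,
    activation_sum = sum(scoreOf[roleOf == "ACTIVATION"]),
    detoxification_sum = -sum(scoreOf[roleOf %in%
                                        c("DETOXIFICATION", "TRANSPORT")]),
    mixed_sum = sum(scoreOf[roleOf == "MIXED"]),
    repair_count = sum(roleOf == "REPAIR"),
    scored_gene_count = length(scored),
    stringsAsFactors = FALSE)
}

#' @rdname scoreAll
#' @export
setGeneric("scoreAll", function(graph, weights = c(1, 1, 1))
  standardGeneric("scoreAll"))

#' Score every annotated enzyme and summarise every touched class
#'
#' Produces the two tables behind a pharmacogenomic risk-scoring
#' foundation plot: one [geneImpactScore()] row per enzyme carrying a
#' representative activity score (ordered by gene id), and one
#' [classReservoir()] row per carcinogen class containing at least one
#' scored enzyme (in vocabulary order). Enzymes touching several classes
#' contribute to each, so summed `scored_gene_count` over classes is at
#' least the number of scored genes.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param weights Per-role impact weights, see [geneImpactScore()].
#' @return A list with data frames `genes` and `classes`.
#' @examples
#' tabs <- scoreAll(referenceGraph())
#' nrow(tabs$genes)   # scored enzymes
#' nrow(tabs$classes) # classes with scored support
#' @name scoreAll
NULL

setMethod("scoreAll", "KnowledgeGraph", function(graph,
                                                 weights = c(1, 1, 1)) {
  scoredIds <- sort(names(graph@nodes)[vapply(graph@nodes, function(n)
    identical(n$node_type, "ENZYME") && !is.null(n$activity_score), NA)])
  rows <- lapply(scoredIds, function(id)
    geneImpactScore(graph, id, weights = weights))
  genes <- if (length(rows)) {
    do.call(rbind, c(rows, make.row.names = FALSE))
  } else {
    data.frame(gene_id = character(), role = character(),
               activity_score = numeric(), impact_score = numeric(),
               class_touch_count = integer(), stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, c(lapply(carcinogenClasses(), function(cl)
    classReservoir(graph, cl)), make.row.names = FALSE))
  classes <- classes[classes$scored_gene_count >= 1L, , drop = FALSE]
  rownames(classes) <- NULL
  list(genes = genes, classes = classes)
})

#' Write the scoring tables as CSV
#'
#' Column order is fixed and documented: gene table `gene_id, role,
#' activity_score, impact_score, class_touch_count`; class table
#' `carcinogen_class, activation_sum, detoxification_sum, mixed_sum,
#' repair_count, scored_gene_count`.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param genePath,classPath Output CSV paths.
#' @param weights Per-role impact weights, see [geneImpactScore()].
#' @return Invisibly, the list returned by [scoreAll()].
#' @export
writeScoreTables <- function(graph, genePath, classPath,
                             weights = c(1, 1, 1)) {
  tabs <- scoreAll(graph, weights = weights)
  utils::write.csv(tabs$genes, genePath, row.names = FALSE)
  utils::write.csv(tabs$classes, classPath, row.names = FALSE)
  invisible(tabs)
}
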