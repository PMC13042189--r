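#' Extract a class/type-filtered subgraph
#'
#' Retains the nodes whose carcinogen-class tag set intersects `classes`
#' (when given) and whose type is in `nodeTypes` (when given); retains the
#' edges whose class tags intersect `classes`, whose type is in
#' `edgeTypes`, and whose endpoints are both retained. Filtering on node
#' types never drops edges of untouched types directly; an edge vanishes
#' only when an endpoint vanishes, so filters compose predictably.
#' `NULL` arguments mean "no restriction"; an explicitly empty `classes`
#' vector retains nothing. Substrate references to non-retained nodes are
#' dropped from the retained edges so the result remains a valid graph
#' (orphan rule suspended: isolated context nodes are legitimate in a
#' filtered view).
#'
#' Pathway nodes and pathway-membership edges appear in class subgraphs
#' only when the manifest tags them explicitly; untagged pathway context is
#' global and is excluded by the class intersection rule.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param classes Optional character vector of carcinogen classes.
#' @param nodeTypes Optional character vector of node types to retain.
#' @param edgeTypes Optional character vector of edge types to retain.
#' @return A new `KnowledgeGraph` containing the retained subgraph.
#' @examples
#' g <- referenceGraph()
#' androgen <- filterGraph(g, classes = "ANDROGEN")
#' c(numNodes(androgen), numEdges(androgen))
#' @export
filterGraph <- function(graph, classes = NULL, nodeTypes = NULL,
                        edgeTypes = NULL) {
  keepNode <- function(n) {
    (is.null(classes) || length(intersect(n$classes, classes)) > 0) &&
      (is.null(nodeTypes) || n$node_type %in% nodeTypes)
  }
  kept <- names(graph@nodes)[vapply(graph@nodes, keepNode, NA)]
  keepEdge <- function(e) {
    (is.null(classes) || length(intersect(e$classes, classes)) > 0) &&
      (is.null(edgeTypes) || e$edge_type %in% edgeTypes) &&
      e$source %in% kept && e$target %in% kept
  }
  out <- emptyGraph(name = graph@metadata$name,
                    version = graph@metadata$version,
                    extensionMode = graph@metadata$extension_mode)
  for (id in kept) out <- addNode(out, graph@nodes[[id]])
  for (e in graph@edges) {
    if (!keepEdge(e)) next
    if (!is.null(e$substrate_id) && !e$substrate_id %in% kept)
      e$substrate_id <- NULL
    out <- addEdge(out, e)
  }
  out
}

.searchableFields <- c("label", "id", "detail", "iarc_group", "tissue",
                       "variant", "phenotype", "source_db", "pmids")

#' Substring metadata search with neighbour expansion
#'
#' Plain case-insensitive substring matching (no tokenisation, fuzziness or
#' autocomplete) over node labels, identifiers, detail text, IARC group,
#' tissue, variant, phenotype, source database and PubMed ids. Matched
#' nodes are expanded to their immediate (1-hop, either direction,
#' substrate-aware) neighbours, mirroring how an interactive viewer
#' highlights a hit together with its local context.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param query Non-empty search string (leading/trailing whitespace is
#'   trimmed; an empty or all-whitespace query is an error).
#' @return A list of class `kgSearchResult` with `matched` (sorted node
#'   ids), `expanded` (sorted 1-hop neighbour ids, disjoint from
#'   `matched`) and `matchedFields` (per matched node, the fields that
#'   contained the query).
#' @examples
#' res <- searchGraph(referenceGraph(), "CYP1")
#' head(res$matched)
#' @export
searchGraph <- function(graph, query) {
  query <- trimws(query)
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("search query must be a non-empty string", call. = FALSE)
  q <- tolower(query)
  matchedFields <- list()
  for (n in graph@nodes) {
    hay <- list(label = n$label, id = n$id,
                detail = n$annotations$detail,
                iarc_group = n$annotations$iarc_group,
                tissue = n$annotations$tissue,
                variant = n$annotations$variant,
                phenotype = n$annotations$phenotype,
                source_db = n$annotations$source_db,
                pmids = n$annotations$pmids)
    hits <- names(hay)[vapply(hay, function(x)
      any(grepl(q, tolower(x), fixed = TRUE)), NA)]
    if (length(hits)) matchedFields[[n$id]] <- hits
  }
  matched <- sort(as.character(names(matchedFields)))
  expanded <- sort(setdiff(
    unique(unlist(lapply(matched, function(id)
      nodeNeighbors(graph, id, direction = "both")), use.names = FALSE)),
    matched))
  structure(list(matched = matched, expanded = expanded,
                 matchedFields = matchedFields[matched]),
            class = "kgSearchResult")
}

#' @export
print.kgSearchResult <- function(x, ...) {
  cat(sprintf("kgSearchResult: %d matched, %d expanded\n",
              length(x$matched), length(x$expanded)))
  if (length(x$matched))
    cat("  matched:", paste(x$matched, collapse = ", "), "\n")
  if (length(x$expanded))
    cat("  expanded:", paste(x$expanded, collapse = ", "), "\n")
  invisible(x)
}

#' Derive carcinogen-class membership from graph topology
#'
#' Makes the stored class tags auditable. For each class, the derivation
#' starts from the carcinogen nodes stored with that class tag, closes
#' over the metabolic successor relation (activation edges followed via
#' their substrate reference, adduct-formation edges via their source),
#' then adds: enzymes with any activation/detoxification/transport edge
#' whose substrate or target lies in the closure, the product nodes of
#' detoxification and transport edges acting on closure chemicals, and
#' repair enzymes with repair edges into closure adducts. Pathway-context
#' membership is curated, not topological: derived tags for PATHWAY nodes
#' are their stored tags.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @return Named list mapping every node id to its derived (sorted)
#'   character vector of class tags.
#' @export
deriveClassMembership <- function(graph) {
  derived <- stats::setNames(
    replicate(length(graph@nodes), character(), simplify = FALSE),
    names(graph@nodes))
  for (cl in carcinogenClasses()) {
    seeds <- names(graph@nodes)[vapply(graph@nodes, function(n)
      identical(n$node_type, "CARCINOGEN") && cl %in% n$classes, NA)]
    if (!length(seeds)) next
    closure <- .metabolicClosure(graph, seeds)
    members <- closure
    for (e in graph@edges) {
      if (e$edge_type %in% c("ACTIVATES", "DETOXIFIES", "TRANSPORTS")) {
        touches <- (!is.null(e$substrate_id) &&
                      e$substrate_id %in% closure) ||
                   e$target %in% closure
        if (touches) {
          members <- c(members, e$source)
          if (e$edge_type %in% c("DETOXIFIES", "TRANSPORTS") &&
              !is.null(e$substrate_id) && e$substrate_id %in% closure)
            members <- c(members, e$target)
        }
      } else if (e$edge_type == "REPAIRS" && e$target %in% closure) {
        members <- c(members, e$source)
      }
    }
    for (id in unique(members)) derived[[id]] <- c(derived[[id]], cl)
  }
  for (id in names(graph@nodes)) {
    if (identical(graph@nodes[[id]]$node_type, "PATHWAY")) {
      derived[[id]] <- graph@nodes[[id]]$classes
    } else {
      derived[[id]] <- sort(unique(derived[[id]]))
    }
  }
  derived
}

# Fixed point of the metabolic successor relation:
#   succ(x) = targets of ACTIVATES edges with substrate x
#           u targets of FORMS_ADDUCT edges with source x
.metabolicClosure <- function(graph, startIds) {
  seen <- unique(startIds)
  frontier <- seen
  while (length(frontier)) {
    nxt <- character()
    for (e in graph@edges) {
      if (e$edge_type == "ACTIVATES" && !is.null(e$substrate_id) &&
          e$substrate_id %in% frontier) {
        nxt <- c(nxt, e$target)
      } else if (e$edge_type == "FORMS_ADDUCT" && e$source %in% frontier) {
        nxt <- c(nxt, e$target)
      }
    }
    frontier <- setdiff(unique(nxt), seen)
    seen <- c(seen, frontier)
  }
  seen
}
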