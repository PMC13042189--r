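#' KnowledgeGraph: validated container for typed metabolism graphs
#'
#' An S4 container holding id-unique node and edge records, directional
#' adjacency indices, and graph metadata. Every mutating verb
#' ([addNode()], [addEdge()], [removeNode()], [removeEdge()]) returns a new
#' consistent container; endpoint-type constraints and reference resolution
#' are enforced at insertion time, so queries and scoring can assume a
#' valid graph. The orphan-node rule (every node of a built reference
#' graph has degree >= 1, counting substrate references) is checked only by
#' [validateGraph()], since nodes are necessarily orphans mid-build.
#'
#' @slot nodes Named list of node records (names are node ids).
#' @slot edges Named list of edge records (names are edge ids).
#' @slot outIndex,inIndex Named lists mapping node id to the character
#'   vector of incident edge ids (outgoing / incoming).
#' @slot substrateIndex Named list mapping node id to the edge ids that
#'   reference it as a substrate.
#' @slot metadata List with `name`, `version` and `extension_mode`.
#' @name KnowledgeGraph-class
#' @aliases KnowledgeGraph
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
  representation(nodes = "list", edges = "list", outIndex = "list",
                 inIndex = "list", substrateIndex = "list",
                 metadata = "list"),
  prototype(nodes = structure(list(), names = character()),
            edges = structure(list(), names = character()),
            outIndex = list(), inIndex = list(), substrateIndex = list(),
            metadata = list(name = "knowledge-graph", version = "1.0",
                            extension_mode = FALSE)))

setValidity("KnowledgeGraph", function(object) {
  msg <- character()
  nn <- names(object@nodes)
  ne <- names(object@edges)
  if (length(object@nodes) && (is.null(nn) || anyDuplicated(nn)))
    msg <- c(msg, "node ids must be unique and name the node list")
  if (length(object@edges) && (is.null(ne) || anyDuplicated(ne)))
    msg <- c(msg, "edge ids must be unique and name the edge list")
  for (i in seq_along(object@nodes)) {
    if (!identical(object@nodes[[i]]$id, nn[i])) {
      msg <- c(msg, "node list names must equal record ids")
      break
    }
  }
  if (!all(c("name", "version", "extension_mode") %in%
           names(object@metadata)))
    msg <- c(msg, "metadata must carry name, version and extension_mode")
  if (length(msg)) msg else TRUE
})

#' Create an empty knowledge graph
#'
#' @param name,version Graph metadata strings.
#' @param extensionMode Logical; admit `GENE`/`TISSUE` node types.
#' @return An empty [KnowledgeGraph-class] object.
#' @examples
#' g <- emptyGraph()
#' numNodes(g)
#' @export
emptyGraph <- function(name = "knowledge-graph", version = "1.0",
                       extensionMode = FALSE) {
  new("KnowledgeGraph",
      metadata = list(name = name, version = version,
                      extension_mode = isTRUE(extensionMode)))
}

#' @describeIn KnowledgeGraph-class Compact summary of the container.
#' @param object A `KnowledgeGraph`.
#' @export
setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf("KnowledgeGraph '%s' (format %s%s)\n",
              object@metadata$name, object@metadata$version,
              if (isTRUE(object@metadata$extension_mode))
                ", extension mode" else ""))
  cat(sprintf("  %d nodes, %d edges\n", length(object@nodes),
              length(object@edges)))
  if (length(object@nodes)) {
    tt <- nodeCountsByType(object)
    tt <- tt[tt > 0]
    cat("  nodes:", paste(sprintf("%s=%d", names(tt), tt),
                          collapse = ", "), "\n")
  }
  if (length(object@edges)) {
    et <- table(factor(vapply(object@edges, `[[`, "", "edge_type"),
                       levels = edgeTypes()))
    et <- et[et > 0]
    cat("  edges:", paste(sprintf("%s=%d", names(et), et),
                          collapse = ", "), "\n")
  }
  invisible(object)
})

## ---- accessors -----------------------------------------------------------

#' Accessors for knowledge-graph content
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param id A node or edge id.
#' @return `nodeIds`/`edgeIds` return character vectors; `getNode`/`getEdge`
#'   return the stored record (error on unknown id); `numNodes`/`numEdges`
#'   return counts; `graphMetadata` returns the metadata list.
#' @name kg-accessors
NULL

#' @rdname kg-accessors
#' @export
nodeIds <- function(graph) names(graph@nodes)

#' @rdname kg-accessors
#' @export
edgeIds <- function(graph) names(graph@edges)

#' @rdname kg-accessors
#' @export
numNodes <- function(graph) length(graph@nodes)

#' @rdname kg-accessors
#' @export
numEdges <- function(graph) length(graph@edges)

#' @rdname kg-accessors
#' @export
getNode <- function(graph, id) {
  if (!id %in% names(graph@nodes))
    stop("unknown node id: ", id, call. = FALSE)
  graph@nodes[[id]]
}

#' @rdname kg-accessors
#' @export
getEdge <- function(graph, id) {
  if (!id %in% names(graph@edges))
    stop("unknown edge id: ", id, call. = FALSE)
  graph@edges[[id]]
}

#' @rdname kg-accessors
#' @export
graphMetadata <- function(graph) graph@metadata

## ---- mutation ------------------------------------------------------------

.appendIndex <- function(index, key, value) {
  index[[key]] <- c(index[[key]], value)
  index
}

#' @rdname kg-mutators
#' @export
setGeneric("addNode", function(graph, node) standardGeneric("addNode"))

#' @rdname kg-mutators
#' @export
setGeneric("addEdge", function(graph, edge) standardGeneric("addEdge"))

#' @rdname kg-mutators
#' @export
setGeneric("removeNode", function(graph, id) standardGeneric("removeNode"))

#' @rdname kg-mutators
#' @export
setGeneric("removeEdge", function(graph, id) standardGeneric("removeEdge"))

#' Add or remove nodes and edges
#'
#' `addNode` rejects records failing [validateNode()] and duplicate ids.
#' `addEdge` additionally enforces the endpoint-type table
#' ([allowedEndpoints()]), resolution of endpoints and substrate
#' references, and uniqueness of the `(source, target, edge_type,
#' substrate_id)` record: parallel edges of *different* type between the
#' same pair are legitimate biology (one enzyme can both form and divert
#' the same chemical context), identical records are curation errors.
#' `removeNode` refuses to drop a node that still has incident edges or
#' substrate references.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param node,edge Records from [kgNode()] / [kgEdge()].
#' @param id Node or edge id to remove.
#' @return The updated `KnowledgeGraph`.
#' @name kg-mutators
NULL

setMethod("addNode", "KnowledgeGraph", function(graph, node) {
  v <- validateNode(node, extensionMode = graph@metadata$extension_mode)
  if (length(v))
    stop("invalid node: ", paste(v, collapse = "; "), call. = FALSE)
  if (node$id %in% names(graph@nodes))
    stop("duplicate node id: ", node$id, call. = FALSE)
  graph@nodes[[node$id]] <- node
  graph
})

setMethod("addEdge", "KnowledgeGraph", function(graph, edge) {
  v <- .validateEdgeLocal(edge)
  if (length(v))
    stop("invalid edge: ", paste(v, collapse = "; "), call. = FALSE)
  if (edge$id %in% names(graph@edges))
    stop("duplicate edge id: ", edge$id, call. = FALSE)
  for (endp in c("source", "target")) {
    if (!edge[[endp]] %in% names(graph@nodes))
      stop(sprintf("edge '%s': %s node '%s' does not exist",
                   edge$id, endp, edge[[endp]]), call. = FALSE)
  }
  allowed <- allowedEndpoints(edge$edge_type)
  st <- graph@nodes[[edge$source]]$node_type
  tt <- graph@nodes[[edge$target]]$node_type
  if (!st %in% allowed$source || !tt %in% allowed$target) {
    stop(sprintf(
      "edge '%s': %s edges require source in {%s} and target in {%s}, got %s -> %s",
      edge$id, edge$edge_type, paste(allowed$source, collapse = ","),
      paste(allowed$target, collapse = ","), st, tt), call. = FALSE)
  }
  if (!is.null(edge$substrate_id)) {
    sub <- edge$substrate_id
    if (!sub %in% names(graph@nodes))
      stop(sprintf("edge '%s': substrate '%s' does not exist", edge$id, sub),
           call. = FALSE)
    subType <- graph@nodes[[sub]]$node_type
    if (!subType %in% c("CARCINOGEN", "METABOLITE"))
      stop(sprintf(
        "edge '%s': substrate '%s' must be a CARCINOGEN or METABOLITE, got %s",
        edge$id, sub, subType), call. = FALSE)
  }
  key <- .edgeRecordKey(edge)
  if (any(vapply(graph@edges, .edgeRecordKey, "") == key))
    stop(sprintf(
      "edge '%s': duplicate (source, target, edge_type, substrate) record",
      edge$id), call. = FALSE)
  graph@edges[[edge$id]] <- edge
  graph@outIndex <- .appendIndex(graph@outIndex, edge$source, edge$id)
  graph@inIndex <- .appendIndex(graph@inIndex, edge$target, edge$id)
  if (!is.null(edge$substrate_id))
    graph@substrateIndex <- .appendIndex(graph@substrateIndex,
                                         edge$substrate_id, edge$id)
  graph
})

.edgeRecordKey <- function(edge) {
  paste(edge$source, edge$target, edge$edge_type,
        if (is.null(edge$substrate_id)) "" else edge$substrate_id,
        sep = "\r")
}

setMethod("removeEdge", "KnowledgeGraph", function(graph, id) {
  e <- getEdge(graph, id)
  graph@edges[[id]] <- NULL
  drop1 <- function(index, key) {
    left <- setdiff(index[[key]], id)
    if (length(left)) index[[key]] <- left else index[[key]] <- NULL
    index
  }
  graph@outIndex <- drop1(graph@outIndex, e$source)
  graph@inIndex <- drop1(graph@inIndex, e$target)
  if (!is.null(e$substrate_id))
    graph@substrateIndex <- drop1(graph@substrateIndex, e$substrate_id)
  graph
})

setMethod("removeNode", "KnowledgeGraph", function(graph, id) {
  getNode(graph, id)
  incident <- c(graph@outIndex[[id]], graph@inIndex[[id]],
                graph@substrateIndex[[id]])
  if (length(incident))
    stop(sprintf("node '%s' still has incident edges (%s); remove them first",
                 id, paste(incident, collapse = ", ")), call. = FALSE)
  graph@nodes[[id]] <- NULL
  graph
})

## ---- counting and neighbourhoods -----------------------------------------

#' @rdname kg-counts
#' @export
setGeneric("nodeCountsByType",
           function(graph) standardGeneric("nodeCountsByType"))

#' @rdname kg-counts
#' @export
setGeneric("enzymeCountsByPhase",
           function(graph) standardGeneric("enzymeCountsByPhase"))

#' Inventory tallies
#'
#' `nodeCountsByType` tallies nodes over the admitted node types;
#' `enzymeCountsByPhase` tallies enzyme nodes over the four functional
#' phases. Both always return a complete named integer vector (zeros for
#' absent categories) whose sum equals the relevant node count.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @return Named integer vector of counts.
#' @examples
#' nodeCountsByType(emptyGraph())
#' @name kg-counts
NULL

setMethod("nodeCountsByType", "KnowledgeGraph", function(graph) {
  lv <- nodeTypes(extension = isTRUE(graph@metadata$extension_mode))
  types <- vapply(graph@nodes, `[[`, "", "node_type")
  out <- table(factor(types, levels = lv))
  stats::setNames(as.integer(out), lv)
})

setMethod("enzymeCountsByPhase", "KnowledgeGraph", function(graph) {
  enz <- Filter(function(n) identical(n$node_type, "ENZYME"), graph@nodes)
  phases <- vapply(enz, function(n) n$phase %||% NA_character_, "")
  out <- table(factor(phases, levels = enzymePhases()))
  stats::setNames(as.integer(out), enzymePhases())
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjacent node ids
#'
#' Returns the node ids adjacent to `id` via edges of the requested
#' direction and (optionally) edge types. Substrate references count as
#' *incoming* incidence on the substrate node: the enzyme acting on a
#' chemical is part of that chemical's local neighbourhood even though the
#' directed edge runs enzyme-to-product.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param id Node id (error when unknown).
#' @param direction `"both"` (default), `"in"` or `"out"`.
#' @param edgeTypes Optional character vector restricting the edge types
#'   considered.
#' @return Sorted character vector of adjacent node ids (never contains
#'   `id` itself).
#' @export
nodeNeighbors <- function(graph, id, direction = c("both", "in", "out"),
                          edgeTypes = NULL) {
  direction <- match.arg(direction)
  getNode(graph, id)
  keep <- function(eids) {
    if (is.null(edgeTypes)) return(eids)
    eids[vapply(graph@edges[eids], `[[`, "", "edge_type") %in% edgeTypes]
  }
  out <- character()
  if (direction %in% c("out", "both")) {
    eids <- keep(graph@outIndex[[id]] %||% character())
    out <- c(out, vapply(graph@edges[eids], `[[`, "", "target"),
             vapply(graph@edges[eids], function(e)
               e$substrate_id %||% NA_character_, ""))
  }
  if (direction %in% c("in", "both")) {
    eids <- keep(c(graph@inIndex[[id]] %||% character(),
                   graph@substrateIndex[[id]] %||% character()))
    out <- c(out, vapply(graph@edges[eids], `[[`, "", "source"),
             vapply(graph@edges[eids], `[[`, "", "target"))
  }
  sort(setdiff(unique(out[!is.na(out)]), id))
}
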