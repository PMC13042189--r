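# Canonical JSON dialect. Versioned ("format_version", major.minor);
# readers reject unknown major versions. Serialisation is byte-stable:
# nodes and edges sorted by id, annotation keys sorted, sets as sorted
# arrays, floats at full round-trip precision.

.CANONICAL_FORMAT_VERSION <- "1.0"

.annotationsForJSON <- function(ann) {
  ann <- .asAnnotations(ann)
  keys <- sort(.annotationFields)
  out <- lapply(keys, function(k) {
    if (k == "pmids") I(ann$pmids) else ann[[k]]
  })
  stats::setNames(out, keys)
}

.nodeForJSON <- function(n) {
  out <- list(id = n$id, label = n$label, node_type = n$node_type,
              classes = I(sort(n$classes)))
  if (!is.null(n$phase)) out$phase <- n$phase
  if (!is.null(n$role)) out$role <- n$role
  if (!is.null(n$activity_score)) out$activity_score <- n$activity_score
  out$annotations <- .annotationsForJSON(n$annotations)
  if (!is.null(n$position))
    out$position <- list(x = n$position[1], y = n$position[2])
  out
}

.edgeForJSON <- function(e) {
  out <- list(id = e$id, source = e$source, target = e$target,
              edge_type = e$edge_type)
  if (!is.null(e$substrate_id)) out$substrate_id <- e$substrate_id
  out$classes <- I(sort(e$classes))
  out$annotations <- .annotationsForJSON(e$annotations)
  out
}

#' Serialise a graph to the canonical JSON dialect
#'
#' The canonical dialect is this package's published interchange schema:
#' a versioned JSON document with `format_version`, `metadata`, and
#' id-sorted `nodes` and `edges` arrays. Serialising the same graph twice
#' yields identical bytes (fixed key order, sorted sets, full-precision
#' floats), so documents diff cleanly under version control.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param path Output file path, or `NULL` to return the JSON string.
#' @return Invisibly the JSON string (also written to `path` when given).
#' @examples
#' json <- writeCanonicalGraph(emptyGraph())
#' @export
writeCanonicalGraph <- function(graph, path = NULL) {
  doc <- list(
    format_version = .CANONICAL_FORMAT_VERSION,
    metadata = list(
      name = graph@metadata$name,
      version = graph@metadata$version,
      extension_mode = isTRUE(graph@metadata$extension_mode)),
    nodes = lapply(graph@nodes[order(names(graph@nodes))], .nodeForJSON),
    edges = lapply(graph@edges[order(names(graph@edges))], .edgeForJSON))
  names(doc$nodes) <- NULL
  names(doc$edges) <- NULL
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

.jsonStop <- function(pointer, msg) {
  stop(sprintf("canonical JSON parse error at %s: %s", pointer, msg),
       call. = FALSE)
}

.chr1 <- function(x, pointer) {
  if (is.null(x) || !is.character(unlist(x)) || length(unlist(x)) != 1L)
    .jsonStop(pointer, "expected a string")
  unlist(x)
}

#' Read a graph from the canonical JSON dialect
#'
#' Validates the document against the published schema while parsing;
#' violations are reported with a JSON-pointer path to the offending
#' element. Unknown major format versions are rejected.
#'
#' @param path Path to a canonical JSON file, or a JSON string.
#' @return A [KnowledgeGraph-class] object.
#' @export
readCanonicalGraph <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    .jsonStop("/", conditionMessage(e)))
  fv <- doc$format_version
  if (is.null(fv)) .jsonStop("/format_version", "missing")
  major <- strsplit(as.character(fv), ".", fixed = TRUE)[[1]][1]
  if (!identical(major,
                 strsplit(.CANONICAL_FORMAT_VERSION, ".",
                          fixed = TRUE)[[1]][1]))
    .jsonStop("/format_version",
              sprintf("unsupported major version '%s'", fv))
  meta <- doc$metadata %||% list()
  g <- emptyGraph(name = meta$name %||% "knowledge-graph",
                  version = meta$version %||% "1.0",
                  extensionMode = isTRUE(meta$extension_mode))
  ext <- isTRUE(meta$extension_mode)
  for (i in seq_along(doc$nodes)) {
    nd <- doc$nodes[[i]]
    ptr <- sprintf("/nodes/%d", i - 1L)
    nt <- .chr1(nd$node_type, paste0(ptr, "/node_type"))
    if (!nt %in% nodeTypes(ext))
      .jsonStop(paste0(ptr, "/node_type"),
                sprintf("unknown node_type '%s'", nt))
    node <- kgNode(id = .chr1(nd$id, paste0(ptr, "/id")),
                   label = .chr1(nd$label %||% nd$id, paste0(ptr, "/label")),
                   nodeType = nt,
                   classes = unlist(nd$classes) %||% character(),
                   phase = nd$phase, role = nd$role,
                   activityScore = nd$activity_score,
                   annotations = nd$annotations,
                   position = if (!is.null(nd$position))
                     c(nd$position$x, nd$position$y))
    g <- tryCatch(addNode(g, node),
                  error = function(e) .jsonStop(ptr, conditionMessage(e)))
  }
  for (i in seq_along(doc$edges)) {
    ed <- doc$edges[[i]]
    ptr <- sprintf("/edges/%d", i - 1L)
    et <- .chr1(ed$edge_type, paste0(ptr, "/edge_type"))
    if (!et %in% edgeTypes())
      .jsonStop(paste0(ptr, "/edge_type"),
                sprintf("unknown edge_type '%s'", et))
    edge <- kgEdge(id = .chr1(ed$id, paste0(ptr, "/id")),
                   source = .chr1(ed$source, paste0(ptr, "/source")),
                   target = .chr1(ed$target, paste0(ptr, "/target")),
                   edgeType = et,
                   substrateId = ed$substrate_id,
                   classes = unlist(ed$classes) %||% character(),
                   annotations = ed$annotations)
    g <- tryCatch(addEdge(g, edge),
                  error = function(e) .jsonStop(ptr, conditionMessage(e)))
  }
  g
}

#' Canonical equality of two graphs
#'
#' Two graphs are canonically equal when their canonical serialisations
#' are byte-identical (same nodes, edges, metadata, annotations and
#' positions, irrespective of insertion order).
#'
#' @param a,b [KnowledgeGraph-class] objects.
#' @return Logical.
#' @export
graphsIdentical <- function(a, b) {
  identical(writeCanonicalGraph(a), writeCanonicalGraph(b))
}
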