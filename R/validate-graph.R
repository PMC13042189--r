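#' Validate a knowledge graph against all container invariants
#'
#' Checks every node record, edge record, reference resolution, the
#' endpoint-type table, record-level edge uniqueness, index consistency
#' and (optionally) the orphan rule: in a built reference graph every node
#' must have degree >= 1, counting substrate references as incidence.
#' Violations are returned as data, one message each; an empty character
#' vector means the graph is valid. The function is pure: calling it twice
#' on the same object yields identical results.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param orphanCheck Logical; enforce the orphan-node rule. Suspended for
#'   graphs under construction and for filtered subgraphs.
#' @return Character vector of violation messages (possibly empty).
#' @examples
#' validateGraph(emptyGraph())
#' @export
validateGraph <- function(graph, orphanCheck = TRUE) {
  v <- character()
  ext <- isTRUE(graph@metadata$extension_mode)
  ids <- names(graph@nodes)
  if (anyDuplicated(ids))
    v <- c(v, "duplicate node ids")
  if (anyDuplicated(names(graph@edges)))
    v <- c(v, "duplicate edge ids")
  for (n in graph@nodes) v <- c(v, validateNode(n, extensionMode = ext))
  seenKeys <- character()
  for (e in graph@edges) {
    v <- c(v, .validateEdgeLocal(e))
    for (endp in c("source", "target")) {
      if (!e[[endp]] %in% ids) {
        v <- c(v, sprintf("edge '%s': dangling %s '%s'", e$id, endp,
                          e[[endp]]))
      }
    }
    if (e$edge_type %in% edgeTypes() &&
        all(c(e$source, e$target) %in% ids)) {
      allowed <- allowedEndpoints(e$edge_type)
      st <- graph@nodes[[e$source]]$node_type
      tt <- graph@nodes[[e$target]]$node_type
      if (!st %in% allowed$source || !tt %in% allowed$target)
        v <- c(v, sprintf("edge '%s': %s edge violates endpoint table (%s -> %s)",
                          e$id, e$edge_type, st, tt))
    }
    if (!is.null(e$substrate_id)) {
      if (!e$substrate_id %in% ids) {
        v <- c(v, sprintf("edge '%s': dangling substrate '%s'", e$id,
                          e$substrate_id))
      } else if (!graph@nodes[[e$substrate_id]]$node_type %in%
                 c("CARCINOGEN", "METABOLITE")) {
        v <- c(v, sprintf("edge '%s': substrate '%s' is not a CARCINOGEN or METABOLITE",
                          e$id, e$substrate_id))
      }
    }
    key <- .edgeRecordKey(e)
    if (key %in% seenKeys)
      v <- c(v, sprintf("edge '%s': duplicate (source, target, edge_type, substrate) record",
                        e$id))
    seenKeys <- c(seenKeys, key)
  }
  # index consistency: each edge in exactly one out bucket (its source) and
  # one in bucket (its target)
  for (e in graph@edges) {
    if (sum(vapply(names(graph@outIndex), function(k)
          e$id %in% graph@outIndex[[k]], NA)) != 1L ||
        !e$id %in% (graph@outIndex[[e$source]] %||% character()))
      v <- c(v, sprintf("index: edge '%s' missing from its source out-bucket",
                        e$id))
    if (sum(vapply(names(graph@inIndex), function(k)
          e$id %in% graph@inIndex[[k]], NA)) != 1L ||
        !e$id %in% (graph@inIndex[[e$target]] %||% character()))
      v <- c(v, sprintf("index: edge '%s' missing from its target in-bucket",
                        e$id))
  }
  if (orphanCheck && length(graph@nodes)) {
    touched <- unique(unlist(lapply(graph@edges, function(e)
      c(e$source, e$target, e$substrate_id)), use.names = FALSE))
    orphans <- setdiff(ids, touched)
    if (length(orphans))
      v <- c(v, sprintf("orphan node '%s' (degree 0, counting substrate references)",
                        orphans))
  }
  v
}
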