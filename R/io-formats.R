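#' Viewer colour map by node type
#'
#' Hex colours are stored lowercase with a leading `#`. The two
#' extension-only types (`GENE`, `TISSUE`) are always present in the map
#' so that extension graphs export without special-casing.
#'
#' @return Named character vector mapping node type to hex colour.
#' @examples
#' styleMap()[["CARCINOGEN"]]
#' @export
styleMap <- function() {
  c(CARCINOGEN = "#e05565", ENZYME = "#4f98a3", GENE = "#3d8b8b",
    METABOLITE = "#e8945a", DNA_ADDUCT = "#a86fdf", PATHWAY = "#5591c7",
    TISSUE = "#c2855a")
}

.pipeJoin <- function(x) paste(x, collapse = "|")

## ---- GraphML -------------------------------------------------------------

.graphmlKeys <- function() {
  nodeAttrs <- c("label", "node_type", "classes", "phase", "role",
                 "activity_score", "detail", "iarc_group", "tissue",
                 "variant", "phenotype", "source_db", "evidence", "pmids",
                 "reactivity")
  edgeAttrs <- c("edge_type", "substrate_id", "classes", "detail")
  list(node = nodeAttrs, edge = edgeAttrs)
}

#' Export a graph as GraphML
#'
#' Writes a directed GraphML document with typed attribute keys for node
#' and edge properties (class sets joined by `"|"`, annotations
#' flattened), suitable for import into general-purpose network tools.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeGraphML <- function(graph, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- .graphmlKeys()
  addKey <- function(id, domain, type = "string") {
    xml2::xml_add_child(doc, "key", id = paste0(substr(domain, 1, 1), "_",
                                                id),
                        `for` = domain, attr.name = id, attr.type = type)
  }
  for (k in keys$node)
    addKey(k, "node", if (k == "activity_score") "double" else "string")
  for (k in keys$edge) addKey(k, "edge")
  gEl <- xml2::xml_add_child(doc, "graph", id = graph@metadata$name,
                             edgedefault = "directed")
  addData <- function(el, key, value, domain) {
    if (is.null(value) || (is.character(value) && !length(value))) return()
    d <- xml2::xml_add_child(el, "data",
                             key = paste0(substr(domain, 1, 1), "_", key))
    xml2::xml_text(d) <- as.character(value)
  }
  for (n in graph@nodes[order(names(graph@nodes))]) {
    el <- xml2::xml_add_child(gEl, "node", id = n$id)
    addData(el, "label", n$label, "node")
    addData(el, "node_type", n$node_type, "node")
    if (length(n$classes)) addData(el, "classes", .pipeJoin(n$classes),
                                   "node")
    addData(el, "phase", n$phase, "node")
    addData(el, "role", n$role, "node")
    if (!is.null(n$activity_score))
      addData(el, "activity_score", format(n$activity_score, digits = 17),
              "node")
    ann <- n$annotations
    for (k in setdiff(.annotationFields, "pmids"))
      if (nzchar(ann[[k]])) addData(el, k, ann[[k]], "node")
    if (length(ann$pmids)) addData(el, "pmids", .pipeJoin(ann$pmids),
                                   "node")
  }
  for (e in graph@edges[order(names(graph@edges))]) {
    el <- xml2::xml_add_child(gEl, "edge", id = e$id, source = e$source,
                              target = e$target)
    addData(el, "edge_type", e$edge_type, "edge")
    addData(el, "substrate_id", e$substrate_id, "edge")
    if (length(e$classes)) addData(el, "classes", .pipeJoin(e$classes),
                                   "edge")
    if (nzchar(e$annotations$detail))
      addData(el, "detail", e$annotations$detail, "edge")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- Cytoscape JSON ------------------------------------------------------

#' Export a graph as a Cytoscape JSON elements document
#'
#' Emits the `{"elements": {"nodes": [...], "edges": [...]}}` structure
#' used by Cytoscape-style viewers. Each node datum carries id, label,
#' node type and its display colour from the style map; edges carry
#' source, target and edge type.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param path Output file path, or `NULL` to return the JSON string.
#' @param style Named colour map, see [styleMap()].
#' @return Invisibly the JSON string.
#' @export
writeCytoscapeJSON <- function(graph, path = NULL, style = styleMap()) {
  nodes <- lapply(graph@nodes[order(names(graph@nodes))], function(n) {
    data <- list(id = n$id, label = n$label, node_type = n$node_type,
                 color = unname(style[[n$node_type]]),
                 classes = I(sort(n$classes)))
    if (!is.null(n$phase)) data$phase <- n$phase
    if (!is.null(n$role)) data$role <- n$role
    if (!is.null(n$activity_score)) data$activity_score <- n$activity_score
    if (nzchar(n$annotations$detail)) data$detail <- n$annotations$detail
    el <- list(data = data)
    if (!is.null(n$position))
      el$position <- list(x = n$position[1], y = n$position[2])
    el
  })
  edges <- lapply(graph@edges[order(names(graph@edges))], function(e) {
    data <- list(id = e$id, source = e$source, target = e$target,
                 edge_type = e$edge_type)
    if (!is.null(e$substrate_id)) data$substrate_id <- e$substrate_id
    list(data = data)
  })
  doc <- list(elements = list(nodes = unname(nodes), edges = unname(edges)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

## ---- CSV tables ----------------------------------------------------------

.nodeCsvColumns <- c("id", "label", "node_type", "classes", "phase",
                     "role", "activity_score", "detail", "iarc_group",
                     "tissue", "variant", "phenotype", "source_db",
                     "pmids")
.edgeCsvColumns <- c("id", "source", "target", "edge_type", "substrate_id",
                     "classes")

#' Export / import a graph as node and edge CSV tables
#'
#' Fixed, documented column orders; multi-valued cells (class sets, PMID
#' lists) joined by `"|"`. The round trip is lossless for the covered
#' fields (evidence, reactivity and layout positions live only in the
#' canonical dialect).
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param nodePath,edgePath CSV file paths.
#' @return `writeCsvTables` invisibly returns the two paths;
#'   `readCsvTables` returns a [KnowledgeGraph-class] object.
#' @export
writeCsvTables <- function(graph, nodePath, edgePath) {
  ns <- graph@nodes[order(names(graph@nodes))]
  nodeTab <- data.frame(
    id = vapply(ns, `[[`, "", "id"),
    label = vapply(ns, `[[`, "", "label"),
    node_type = vapply(ns, `[[`, "", "node_type"),
    classes = vapply(ns, function(n) .pipeJoin(n$classes), ""),
    phase = vapply(ns, function(n) n$phase %||% "", ""),
    role = vapply(ns, function(n) n$role %||% "", ""),
    activity_score = vapply(ns, function(n)
      n$activity_score %||% NA_real_, 0),
    detail = vapply(ns, function(n) n$annotations$detail, ""),
    iarc_group = vapply(ns, function(n) n$annotations$iarc_group, ""),
    tissue = vapply(ns, function(n) n$annotations$tissue, ""),
    variant = vapply(ns, function(n) n$annotations$variant, ""),
    phenotype = vapply(ns, function(n) n$annotations$phenotype, ""),
    source_db = vapply(ns, function(n) n$annotations$source_db, ""),
    pmids = vapply(ns, function(n) .pipeJoin(n$annotations$pmids), ""),
    stringsAsFactors = FALSE)
  es <- graph@edges[order(names(graph@edges))]
  edgeTab <- data.frame(
    id = vapply(es, `[[`, "", "id"),
    source = vapply(es, `[[`, "", "source"),
    target = vapply(es, `[[`, "", "target"),
    edge_type = vapply(es, `[[`, "", "edge_type"),
    substrate_id = vapply(es, function(e) e$substrate_id %||% "", ""),
    classes = vapply(es, function(e) .pipeJoin(e$classes), ""),
    stringsAsFactors = FALSE)
  if (!nrow(nodeTab)) nodeTab <- .emptyFrame(.nodeCsvColumns)
  if (!nrow(edgeTab)) edgeTab <- .emptyFrame(.edgeCsvColumns)
  utils::write.csv(nodeTab[, .nodeCsvColumns], nodePath, row.names = FALSE)
  utils::write.csv(edgeTab[, .edgeCsvColumns], edgePath, row.names = FALSE)
  invisible(c(nodePath, edgePath))
}

.emptyFrame <- function(cols) {
  stats::setNames(
    data.frame(matrix(character(), nrow = 0, ncol = length(cols)),
               stringsAsFactors = FALSE), cols)
}

.pipeSplit <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|",
                                                        fixed = TRUE)[[1]]
}

.orNull <- function(x) {
  if (is.na(x) || (is.character(x) && !nzchar(x))) NULL else x
}

#' @rdname writeCsvTables
#' @export
readCsvTables <- function(nodePath, edgePath) {
  nodeTab <- utils::read.csv(nodePath, stringsAsFactors = FALSE,
                             colClasses = "character")
  edgeTab <- utils::read.csv(edgePath, stringsAsFactors = FALSE,
                             colClasses = "character")
  for (tab in list(nodes = nodeTab)) {
    missing <- setdiff(.nodeCsvColumns, names(nodeTab))
    if (length(missing))
      stop("node table: missing column(s) ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  missing <- setdiff(.edgeCsvColumns, names(edgeTab))
  if (length(missing))
    stop("edge table: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- emptyGraph()
  for (i in seq_len(nrow(nodeTab))) {
    r <- nodeTab[i, ]
    score <- .orNull(r$activity_score)
    node <- kgNode(id = r$id, label = r$label, nodeType = r$node_type,
                   classes = .pipeSplit(r$classes),
                   phase = .orNull(r$phase), role = .orNull(r$role),
                   activityScore = if (is.null(score)) NULL
                                   else as.numeric(score),
                   annotations = kgAnnotations(
                     detail = r$detail, iarc_group = r$iarc_group,
                     tissue = r$tissue, variant = r$variant,
                     phenotype = r$phenotype, source_db = r$source_db,
                     pmids = .pipeSplit(r$pmids)))
    g <- tryCatch(addNode(g, node), error = function(e)
      stop(sprintf("node table row %d: %s", i, conditionMessage(e)),
           call. = FALSE))
  }
  for (i in seq_len(nrow(edgeTab))) {
    r <- edgeTab[i, ]
    edge <- kgEdge(id = r$id, source = r$source, target = r$target,
                   edgeType = r$edge_type,
                   substrateId = .orNull(r$substrate_id),
                   classes = .pipeSplit(r$classes))
    g <- tryCatch(addEdge(g, edge), error = function(e)
      stop(sprintf("edge table row %d: %s", i, conditionMessage(e)),
           call. = FALSE))
  }
  g
}

## ---- layout --------------------------------------------------------------

#' Save and restore node layout positions
#'
#' A layout document maps node ids to `(x, y)` coordinates; `writeLayout`
#' emits entries only for nodes that carry a position, `applyLayout`
#' attaches saved positions to an existing graph and rejects ids that do
#' not resolve.
#'
#' @param graph A [KnowledgeGraph-class] object.
#' @param path Layout JSON path (`writeLayout`: `NULL` returns the string).
#' @param layout For `applyLayout`, either a path to a layout JSON file or
#'   a named list of `list(x =, y =)` entries.
#' @return `writeLayout` invisibly returns the JSON string; `applyLayout`
#'   returns the updated graph.
#' @export
writeLayout <- function(graph, path = NULL) {
  withPos <- Filter(function(n) !is.null(n$position), graph@nodes)
  doc <- lapply(withPos[order(names(withPos))], function(n)
    list(x = n$position[1], y = n$position[2]))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

#' @rdname writeLayout
#' @export
applyLayout <- function(graph, layout) {
  if (is.character(layout) && length(layout) == 1L) {
    txt <- if (file.exists(layout))
      paste(readLines(layout, warn = FALSE), collapse = "\n") else layout
    layout <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  }
  unknown <- setdiff(names(layout), names(graph@nodes))
  if (length(unknown))
    stop("layout references unknown node id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (id in names(layout)) {
    graph@nodes[[id]]$position <- c(as.numeric(layout[[id]]$x),
                                    as.numeric(layout[[id]]$y))
  }
  graph
}
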