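# Node and edge records are plain named lists; the KnowledgeGraph container
# owns them. Constructors normalise optional fields, validators return
# violations as character vectors (data, not conditions).

.annotationFields <- c("detail", "iarc_group", "tissue", "variant",
                       "phenotype", "source_db", "evidence", "pmids",
                       "reactivity")

#' Build a normalised annotation record
#'
#' All fields are optional free text except `detail`, which is always
#' present (possibly the empty string) and is never dropped from
#' serialisations. `pmids` is a character vector of PubMed identifiers.
#'
#' @param detail,iarc_group,tissue,variant,phenotype,source_db,evidence,reactivity
#'   Length-one character values; empty string when unknown.
#' @param pmids Character vector of PubMed ids (may be empty).
#' @return A named list with the nine annotation fields in fixed order.
#' @export
kgAnnotations <- function(detail = "", iarc_group = "", tissue = "",
                          variant = "", phenotype = "", source_db = "",
                          evidence = "", pmids = character(),
                          reactivity = "") {
  list(detail = as.character(detail)[1],
       iarc_group = as.character(iarc_group)[1],
       tissue = as.character(tissue)[1],
       variant = as.character(variant)[1],
       phenotype = as.character(phenotype)[1],
       source_db = as.character(source_db)[1],
       evidence = as.character(evidence)[1],
       pmids = as.character(pmids),
       reactivity = as.character(reactivity)[1])
}

.asAnnotations <- function(x) {
  if (is.null(x)) return(kgAnnotations())
  known <- x[intersect(names(x), .annotationFields)]
  do.call(kgAnnotations, known)
}

#' Construct a node record
#'
#' @param id Unique, non-empty, whitespace-free identifier (case-sensitive
#'   slug used as the join key across formats).
#' @param label Display text; defaults to `id`.
#' @param nodeType One of [nodeTypes()] (extension values `GENE`/`TISSUE`
#'   only validate in extension mode).
#' @param classes Character vector of carcinogen-class tags.
#' @param phase Enzyme functional phase (enzymes only), one of
#'   [enzymePhases()].
#' @param role Enzyme role bucket (enzymes only), one of [roleBuckets()].
#' @param activityScore Optional non-negative representative activity score
#'   (dimensionless; enzymes only).
#' @param annotations A list as produced by [kgAnnotations()].
#' @param position Optional numeric `c(x, y)` layout coordinates.
#' @return A node record (named list).
#' @examples
#' kgNode("CYP1A1", "CYP1A1", "ENZYME", classes = "PAH",
#'        phase = "PHASE_I", role = "ACTIVATION", activityScore = 1.5)
#' @export
kgNode <- function(id, label = id, nodeType, classes = character(),
                   phase = NULL, role = NULL, activityScore = NULL,
                   annotations = kgAnnotations(), position = NULL) {
  list(id = as.character(id)[1],
       label = as.character(label)[1],
       node_type = as.character(nodeType)[1],
       classes = sort(unique(as.character(classes))),
       phase = if (is.null(phase)) NULL else as.character(phase)[1],
       role = if (is.null(role)) NULL else as.character(role)[1],
       activity_score = if (is.null(activityScore)) NULL
                        else as.numeric(activityScore)[1],
       annotations = .asAnnotations(annotations),
       position = if (is.null(position)) NULL
                  else as.numeric(position)[1:2])
}

#' Construct an edge record
#'
#' @param id Unique edge identifier.
#' @param source,target Node ids (must differ).
#' @param edgeType One of [edgeTypes()].
#' @param substrateId Optional node id of the chemical acted upon
#'   (activation/detoxification/transport edges); must reference a
#'   carcinogen or metabolite node.
#' @param classes Character vector of carcinogen-class tags.
#' @param annotations A list as produced by [kgAnnotations()].
#' @return An edge record (named list).
#' @export
kgEdge <- function(id, source, target, edgeType, substrateId = NULL,
                   classes = character(), annotations = kgAnnotations()) {
  list(id = as.character(id)[1],
       source = as.character(source)[1],
       target = as.character(target)[1],
       edge_type = as.character(edgeType)[1],
       substrate_id = if (is.null(substrateId)) NULL
                      else as.character(substrateId)[1],
       classes = sort(unique(as.character(classes))),
       annotations = .asAnnotations(annotations))
}

#' Validate a node record against the schema
#'
#' Pure and side-effect free: violations are returned as a character
#' vector, one message per broken rule, naming the field involved; an empty
#' vector means the record is well formed.
#'
#' @param node A node record from [kgNode()].
#' @param extensionMode Logical; admit the `GENE`/`TISSUE` node types.
#' @return Character vector of violation messages (possibly empty).
#' @examples
#' validateNode(kgNode("BaP", "benzo[a]pyrene", "CARCINOGEN"))
#' @export
validateNode <- function(node, extensionMode = FALSE) {
  v <- character()
  id <- node$id
  if (is.null(id) || !nzchar(id) || is.na(id)) {
    v <- c(v, "id: must be a non-empty string")
    id <- "<missing>"
  } else if (grepl("[[:space:]]", id)) {
    v <- c(v, sprintf("id: '%s' contains whitespace", id))
  }
  admitted <- nodeTypes(extensionMode)
  if (is.null(node$node_type) || !node$node_type %in% admitted) {
    v <- c(v, sprintf("node_type: '%s' not admitted (%s mode)",
                      if (is.null(node$node_type)) "<missing>"
                      else node$node_type,
                      if (extensionMode) "extension" else "reference"))
  }
  bad <- setdiff(node$classes, carcinogenClasses())
  if (length(bad)) {
    v <- c(v, sprintf("classes: unknown class tag(s) %s on '%s'",
                      paste(bad, collapse = ", "), id))
  }
  isEnzyme <- identical(node$node_type, "ENZYME")
  if (isEnzyme) {
    if (is.null(node$phase) || !node$phase %in% enzymePhases()) {
      v <- c(v, sprintf("phase: ENZYME '%s' must carry exactly one phase",
                        id))
    }
    if (is.null(node$role) || !node$role %in% roleBuckets()) {
      v <- c(v, sprintf("role: ENZYME '%s' must carry a role bucket", id))
    } else if (!is.null(node$phase)) {
      # REPAIR iff DNA_REPAIR phase; TRANSPORT iff PHASE_III
      if ((node$role == "REPAIR") != (node$phase == "DNA_REPAIR")) {
        v <- c(v, sprintf("role: '%s' role REPAIR requires phase DNA_REPAIR (and conversely)", id))
      }
      if ((node$role == "TRANSPORT") != (node$phase == "PHASE_III")) {
        v <- c(v, sprintf("role: '%s' role TRANSPORT requires phase PHASE_III (and conversely)", id))
      }
    }
    if (!is.null(node$activity_score) &&
        (is.na(node$activity_score) || node$activity_score < 0)) {
      v <- c(v, sprintf("activity_score: '%s' must be non-negative", id))
    }
  } else {
    if (!is.null(node$phase)) {
      v <- c(v, sprintf("phase: only ENZYME nodes carry a phase ('%s')", id))
    }
    if (!is.null(node$role)) {
      v <- c(v, sprintf("role: only ENZYME nodes carry a role ('%s')", id))
    }
    if (!is.null(node$activity_score)) {
      v <- c(v, sprintf("activity_score: only ENZYME nodes are scored ('%s')",
                        id))
    }
  }
  if (!is.null(node$position) &&
      (length(node$position) != 2L || anyNA(node$position))) {
    v <- c(v, sprintf("position: '%s' must be a finite (x, y) pair", id))
  }
  v
}

# Edge-local checks that need no graph context (endpoint resolution and the
# type table are enforced by the container).
.validateEdgeLocal <- function(edge) {
  v <- character()
  if (is.null(edge$id) || !nzchar(edge$id) || is.na(edge$id)) {
    v <- c(v, "id: edge id must be a non-empty string")
  }
  if (!edge$edge_type %in% edgeTypes()) {
    v <- c(v, sprintf("edge_type: '%s' is not an admitted edge type",
                      edge$edge_type))
  }
  if (identical(edge$source, edge$target)) {
    v <- c(v, sprintf("endpoints: edge '%s' is a self-loop (%s)",
                      edge$id, edge$source))
  }
  v
}
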