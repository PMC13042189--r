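#' Controlled vocabularies of the carcinogen-metabolism schema
#'
#' The schema is a typed property graph. Entities are one of five node
#' types (seven when extension mode admits gene and tissue context nodes),
#' relationships one of six directed edge types. Carcinogens are organised
#' into nine chemical/metabolic classes; enzymes carry exactly one
#' functional phase and a derived role bucket.
#'
#' @param extension Logical; when `TRUE`, [nodeTypes()] additionally admits
#'   the extension-only values `GENE` and `TISSUE`.
#' @return A character vector of admitted vocabulary values.
#' @examples
#' nodeTypes()
#' edgeTypes()
#' carcinogenClasses()
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
nodeTypes <- function(extension = FALSE) {
  base <- c("CARCINOGEN", "ENZYME", "METABOLITE", "DNA_ADDUCT", "PATHWAY")
  if (extension) c(base, "GENE", "TISSUE") else base
}

#' @rdname vocabulary
#' @export
edgeTypes <- function() {
  c("ACTIVATES", "DETOXIFIES", "TRANSPORTS", "FORMS_ADDUCT", "REPAIRS",
    "PATHWAY")
}

#' @rdname vocabulary
#' @export
carcinogenClasses <- function() {
  c("PAH", "HCA", "AROMATIC_AMINE", "NITROSAMINE", "MYCOTOXIN", "ESTROGEN",
    "ANDROGEN", "SOLVENT", "ALKYLATING_AGENT")
}

#' @rdname vocabulary
#' @export
enzymePhases <- function() {
  c("PHASE_I", "PHASE_II", "PHASE_III", "DNA_REPAIR")
}

#' @rdname vocabulary
#' @export
roleBuckets <- function() {
  c("ACTIVATION", "DETOXIFICATION", "MIXED", "TRANSPORT", "REPAIR")
}

#' Endpoint-type constraints for each edge type
#'
#' Returns the admissible source and target node types for a directed edge
#' type. Activation edges run from an enzyme to the metabolite it produces;
#' the target set also admits `CARCINOGEN` so that cross-links between index
#' carcinogens (aromatisation of testosterone to estradiol, reduction to
#' DHT) can be represented: a single chemical may be both an index
#' carcinogen and a metabolic product. Adduct formation likewise accepts a
#' `CARCINOGEN` source for direct-acting alkylating agents that need no
#' metabolic intermediate.
#'
#' @param edgeType One of [edgeTypes()].
#' @return A list with character vectors `source` and `target`.
#' @examples
#' allowedEndpoints("REPAIRS")
#' @export
allowedEndpoints <- function(edgeType) {
  table <- list(
    ACTIVATES    = list(source = "ENZYME",
                        target = c("METABOLITE", "CARCINOGEN")),
    DETOXIFIES   = list(source = "ENZYME", target = "METABOLITE"),
    TRANSPORTS   = list(source = "ENZYME", target = "METABOLITE"),
    FORMS_ADDUCT = list(source = c("METABOLITE", "CARCINOGEN"),
                        target = "DNA_ADDUCT"),
    REPAIRS      = list(source = "ENZYME", target = "DNA_ADDUCT"),
    PATHWAY      = list(source = setdiff(nodeTypes(TRUE), "PATHWAY"),
                        target = "PATHWAY")
  )
  if (!is.character(edgeType) || length(edgeType) != 1L ||
      !edgeType %in% names(table)) {
    stop("unknown edge type: ", paste(edgeType, collapse = ", "),
         " (valid: ", paste(edgeTypes(), collapse = ", "), ")",
         call. = FALSE)
  }
  table[[edgeType]]
}
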