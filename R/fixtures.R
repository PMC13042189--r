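#' Deterministic random schema-valid graph generator
#'
#' Generates small random graphs for property tests and oracle
#' comparisons. Generation is a pure function of its arguments: the
#' explicit seed drives a private RNG stream (the caller's global RNG
#' state is saved and restored), so the same spec always yields a
#' byte-identical graph under canonical serialisation. Edge endpoints are
#' sampled uniformly among type-admissible pairs, substrates among
#' carcinogen/metabolite nodes, and duplicate `(source, target, type,
#' substrate)` records are never emitted. Unless `allowCycles` is set,
#' chemicals are ordered (carcinogens before metabolites, then by index)
#' and activation edges only run forward along that order, so the
#' metabolic successor relation is acyclic; with `allowCycles`,
#' metabolite-to-metabolite activation may loop, exercising closure
#' termination in the scoring layer.
#'
#' @param seed Integer seed.
#' @param nPerType Named integer vector of node counts per node type,
#'   e.g. `c(CARCINOGEN = 2, ENZYME = 5, METABOLITE = 5, DNA_ADDUCT = 2)`.
#' @param nEdgesPerType Named integer vector of edge counts per edge type.
#' @param scoredFraction Fraction (0..1) of enzymes given a representative
#'   activity score; `floor(scoredFraction * nEnzymes)` enzymes are scored.
#' @param allowCycles Logical; permit cyclic metabolic successor chains.
#' @param classes Logical; when `TRUE` (default) carcinogens get random
#'   class tags and derived class tags are stamped onto all nodes/edges.
#' @return A [KnowledgeGraph-class] object passing [validateGraph()] with
#'   the orphan rule suspended.
#' @examples
#' g <- generateFixture(1, c(CARCINOGEN = 1, ENZYME = 3, METABOLITE = 4,
#'                           DNA_ADDUCT = 2),
#'                      c(ACTIVATES = 4, FORMS_ADDUCT = 2))
#' numEdges(g)
#' @export
generateFixture <- function(seed,
                            nPerType = c(CARCINOGEN = 2, ENZYME = 5,
                                         METABOLITE = 6, DNA_ADDUCT = 3,
                                         PATHWAY = 1),
                            nEdgesPerType = c(ACTIVATES = 6,
                                              DETOXIFIES = 3,
                                              TRANSPORTS = 1,
                                              FORMS_ADDUCT = 3,
                                              REPAIRS = 2, PATHWAY = 2),
                            scoredFraction = 0, allowCycles = FALSE,
                            classes = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  counts <- stats::setNames(rep(0L, 5), nodeTypes())
  counts[names(nPerType)] <- as.integer(nPerType)
  prefix <- c(CARCINOGEN = "CAR", ENZYME = "ENZ", METABOLITE = "MET",
              DNA_ADDUCT = "ADD", PATHWAY = "PWY")
  g <- emptyGraph(name = sprintf("fixture-seed-%d", as.integer(seed)))
  idsOf <- list()
  for (tp in nodeTypes()) {
    ids <- if (counts[[tp]] > 0)
      sprintf("%s%02d", prefix[[tp]], seq_len(counts[[tp]]))
    else character()
    idsOf[[tp]] <- ids
    for (i in seq_along(ids)) {
      node <- if (tp == "ENZYME") {
        phase <- sample(enzymePhases(), 1)
        role <- switch(phase,
                       PHASE_III = "TRANSPORT",
                       DNA_REPAIR = "REPAIR",
                       sample(c("ACTIVATION", "DETOXIFICATION", "MIXED"),
                              1))
        kgNode(ids[i], sprintf("Enzyme %d", i), "ENZYME",
               phase = phase, role = role)
      } else {
        cls <- if (tp == "CARCINOGEN" && isTRUE(classes))
          sample(carcinogenClasses(), 1) else character()
        kgNode(ids[i], sprintf("%s %d", tp, i), tp, classes = cls)
      }
      g <- addNode(g, node)
    }
  }
  chemicals <- c(idsOf$CARCINOGEN, idsOf$METABOLITE)
  chemOrder <- stats::setNames(seq_along(chemicals), chemicals)

  if (scoredFraction > 0 && length(idsOf$ENZYME)) {
    nScored <- floor(scoredFraction * length(idsOf$ENZYME))
    scoredIds <- idsOf$ENZYME[seq_len(nScored)]
    for (id in scoredIds)
      g@nodes[[id]]$activity_score <- round(stats::runif(1, 0, 2), 2)
  }

  wanted <- stats::setNames(rep(0L, 6), edgeTypes())
  wanted[names(nEdgesPerType)] <- as.integer(nEdgesPerType)
  eIdx <- 0L
  for (et in edgeTypes()) {
    need <- wanted[[et]]
    if (need == 0L) next
    allowed <- allowedEndpoints(et)
    srcPool <- unlist(idsOf[intersect(allowed$source, nodeTypes())])
    tgtPool <- unlist(idsOf[intersect(allowed$target, nodeTypes())])
    if (!length(srcPool) || !length(tgtPool))
      stop(sprintf(
        "fixture spec unrealizable: no admissible endpoints for %s edges",
        et), call. = FALSE)
    needsSub <- et %in% c("ACTIVATES", "DETOXIFIES", "TRANSPORTS")
    if (needsSub && !length(chemicals))
      stop(sprintf(
        "fixture spec unrealizable: %s edges need carcinogen/metabolite substrates",
        et), call. = FALSE)
    made <- 0L
    tries <- 0L
    maxTries <- 500L * need
    while (made < need) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop(sprintf(
          "fixture spec unrealizable: cannot place %d unique %s edges",
          need, et), call. = FALSE)
      src <- sample(srcPool, 1)
      tgt <- sample(tgtPool, 1)
      if (src == tgt) next
      sub <- NULL
      if (needsSub) {
        sub <- sample(chemicals, 1)
        if (et == "ACTIVATES" && tgt %in% chemicals && !allowCycles &&
            chemOrder[[sub]] >= chemOrder[[tgt]]) next
      }
      eIdx <- eIdx + 1L
      edge <- kgEdge(sprintf("E%03d", eIdx), src, tgt, et,
                     substrateId = sub)
      ok <- tryCatch({g <- addEdge(g, edge); TRUE},
                     error = function(e) FALSE)
      if (!ok) {
        eIdx <- eIdx - 1L
        next
      }
      made <- made + 1L
    }
  }
  if (isTRUE(classes)) g <- .stampDerivedClasses(g)
  g
}

# Stamp derived class tags onto nodes and the induced tags onto edges
# (union of the classes of an edge's non-enzyme source/target/substrate).
# Explicit tags on PATHWAY nodes and edges survive.
.stampDerivedClasses <- function(graph) {
  derived <- deriveClassMembership(graph)
  for (id in names(graph@nodes)) {
    if (!identical(graph@nodes[[id]]$node_type, "PATHWAY"))
      graph@nodes[[id]]$classes <- derived[[id]]
  }
  for (eid in names(graph@edges)) {
    e <- graph@edges[[eid]]
    if (e$edge_type == "PATHWAY") next
    parts <- c(e$source, e$target, e$substrate_id)
    parts <- parts[vapply(graph@nodes[parts], `[[`, "", "node_type") !=
                     "ENZYME"]
    graph@edges[[eid]]$classes <-
      sort(unique(c(e$classes,
                    unlist(lapply(graph@nodes[parts], `[[`, "classes"),
                           use.names = FALSE))))
  }
  graph
}
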