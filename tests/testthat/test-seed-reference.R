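test_that("packaged manifest loads with declarations in file order", {
  m <- loadManifest()
  expect_s3_class(m, "kgSeedManifest")
  expect_length(m$nodes, 96)
  expect_length(m$edges, 102)
  # carcinogens are declared first
  expect_identical(m$nodes[[1]]$node_type, "CARCINOGEN")
})

test_that("malformed manifests are rejected with schema errors", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  expect_error(loadManifest(empty), "parse error")

  dup <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "a", "node_type": "CARCINOGEN"},
                         {"id": "a", "node_type": "CARCINOGEN"}],
              "edges": []}', dup)
  expect_error(loadManifest(dup), "duplicate node id")

  dangling <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "a", "node_type": "CARCINOGEN"}],
              "edges": [{"id": "e", "source": "a", "target": "b",
                         "edge_type": "PATHWAY"}]}', dangling)
  expect_error(loadManifest(dangling), "unknown node")

  expect_error(loadManifest("no/such/file.json"), "does not exist")
})

test_that("reference graph reproduces the printed inventory", {
  g <- buildReferenceGraph(loadManifest())
  expect_equal(numNodes(g), 96)
  expect_equal(numEdges(g), 102)
  counts <- nodeCountsByType(g)
  expect_equal(counts[["CARCINOGEN"]], 15)
  expect_equal(counts[["ENZYME"]], 36)
  expect_equal(counts[["METABOLITE"]], 28)
  expect_equal(counts[["DNA_ADDUCT"]], 11)
  expect_equal(counts[["PATHWAY"]], 6)
  phases <- enzymeCountsByPhase(g)
  expect_equal(unname(phases[enzymePhases()]), c(14, 14, 3, 5))
  expect_identical(validateGraph(g), character())
})

test_that("inventory verification reports per-check rows", {
  g <- referenceGraph()
  rep <- verifyInventory(g)
  expect_true(all(rep$pass))
  expect_true(attr(rep, "pass"))
  expect_setequal(
    c("total_nodes", "total_edges", "androgen_filter_nodes",
      "scored_enzymes"),
    intersect(rep$check, c("total_nodes", "total_edges",
                           "androgen_filter_nodes", "scored_enzymes")))
  # a mutilated graph fails exactly the corresponding rows
  g2 <- removeEdge(g, edgeIds(g)[numEdges(g)])
  rep2 <- verifyInventory(g2, loadManifest()$expected_inventory)
  expect_false(rep2$pass[rep2$check == "total_edges"])
  expect_true(rep2$pass[rep2$check == "total_nodes"])
  expect_false(attr(rep2, "pass"))
})

test_that("required exemplar routes are present and traversable", {
  g <- referenceGraph()
  # BaP route terminates in its guanine adduct
  expect_true("BPDE-dG" %in% downstreamAdducts(g, "benzo_a_pyrene"))
  # aflatoxin route carries XPC repair support
  xpcRepairs <- vapply(edgeIds(g), function(id) {
    e <- getEdge(g, id)
    e$source == "XPC" && e$edge_type == "REPAIRS" &&
      e$target == "AFB1-N7-Gua"
  }, NA)
  expect_true(any(xpcRepairs))
  # aromatase bridge: testosterone reaches the depurinating adducts
  expect_setequal(
    intersect(downstreamAdducts(g, "testosterone"),
              c("4-OHE2-N3-adenine", "4-OHE2-N7-guanine")),
    c("4-OHE2-N3-adenine", "4-OHE2-N7-guanine"))
  # every index carcinogen with an activation route reaches its adducts
  expect_true("dG-C8-4-ABP" %in% downstreamAdducts(g, "4-ABP"))
  expect_true("O6-methylguanine" %in% downstreamAdducts(g, "NNK"))
})

test_that("a manifest missing a required enzyme raises a completeness error", {
  m <- loadManifest()
  keep <- vapply(m$nodes, function(n) n$id != "CYP19A1", NA)
  m$nodes <- m$nodes[keep]
  m$edges <- Filter(function(e)
    !("CYP19A1" %in% c(e$source, e$target, e$substrate_id)), m$edges)
  expect_error(buildReferenceGraph(m), "CYP19A1")
})

test_that("building twice from the same manifest is deterministic", {
  m <- loadManifest()
  expect_identical(writeCanonicalGraph(buildReferenceGraph(m)),
                   writeCanonicalGraph(buildReferenceGraph(m)))
})
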