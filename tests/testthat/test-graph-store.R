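test_that("node insertion enforces validity and id uniqueness", {
  g <- emptyGraph()
  g <- addNode(g, kgNode("CYP1A1", "CYP1A1", "ENZYME", phase = "PHASE_I",
                         role = "ACTIVATION"))
  expect_equal(numNodes(g), 1)
  expect_error(addNode(g, kgNode("CYP1A1", "dup", "ENZYME",
                                 phase = "PHASE_I",
                                 role = "ACTIVATION")),
               "duplicate node id")
  expect_error(addNode(g, kgNode("M", "m", "METABOLITE",
                                 phase = "PHASE_I")),
               "invalid node")
})

test_that("edge insertion enforces the endpoint table and references", {
  g <- tinyChainGraph()
  expect_error(addEdge(g, kgEdge("bad1", "R1", "M1", "REPAIRS")),
               "REPAIRS edges require")
  expect_error(addEdge(g, kgEdge("bad2", "E1", "ghost", "ACTIVATES")),
               "does not exist")
  expect_error(addEdge(g, kgEdge("bad3", "E1", "M2", "ACTIVATES",
                                 substrateId = "A1")),
               "substrate")
  # identical (source, target, type, substrate) records are duplicates …
  expect_error(addEdge(g, kgEdge("e1b", "E1", "M1", "ACTIVATES",
                                 substrateId = "C1")),
               "duplicate")
  # … but a parallel edge of a different type is legitimate
  g2 <- addEdge(g, kgEdge("e5", "E1", "M1", "DETOXIFIES",
                          substrateId = "M1"))
  expect_equal(numEdges(g2), numEdges(g) + 1)
})

test_that("tallies match brute-force scans on random fixtures", {
  for (seed in 1:10) {
    g <- generateFixture(seed, scoredFraction = 0.5)
    expect_identical(nodeCountsByType(g), oracleTypeTally(g))
    expect_identical(enzymeCountsByPhase(g), oraclePhaseTally(g))
    expect_equal(sum(nodeCountsByType(g)), numNodes(g))
    expect_equal(sum(enzymeCountsByPhase(g)),
                 nodeCountsByType(g)[["ENZYME"]])
  }
})

test_that("neighbourhood queries equal a brute-force edge scan", {
  for (seed in 1:8) {
    g <- generateFixture(seed)
    for (id in nodeIds(g)) {
      for (dir in c("in", "out", "both")) {
        expect_identical(nodeNeighbors(g, id, direction = dir),
                         oracleNeighbors(g, id, dir),
                         info = sprintf("seed %d node %s dir %s", seed,
                                        id, dir))
      }
    }
  }
  expect_error(nodeNeighbors(generateFixture(1), "ghost"),
               "unknown node")
})

test_that("isolated nodes have empty neighbourhoods", {
  g <- addNode(emptyGraph(), kgNode("X", "x", "METABOLITE"))
  expect_identical(nodeNeighbors(g, "X"), character())
})

test_that("edge-type restricted neighbourhoods subset the full set", {
  g <- referenceGraph()
  full <- nodeNeighbors(g, "BPDE")
  forms <- nodeNeighbors(g, "BPDE", direction = "out",
                         edgeTypes = "FORMS_ADDUCT")
  expect_true("BPDE-dG" %in% forms)
  expect_true(all(forms %in% full))
})

test_that("adding then removing a node restores an identical graph", {
  g <- tinyChainGraph()
  before <- writeCanonicalGraph(g)
  g2 <- addNode(g, kgNode("TMP", "temp", "METABOLITE"))
  expect_false(identical(writeCanonicalGraph(g2), before))
  g3 <- removeNode(g2, "TMP")
  expect_identical(writeCanonicalGraph(g3), before)
  # removal refuses while edges (or substrate references) remain
  expect_error(removeNode(g, "M1"), "incident")
  g4 <- removeEdge(removeEdge(removeEdge(g, "e1"), "e2"), "e3")
  expect_silent(removeNode(g4, "M1"))
})

test_that("validateGraph flags dangling references and orphans", {
  g <- tinyChainGraph()
  expect_identical(validateGraph(g), character())
  g@nodes[["ORPHAN"]] <- kgNode("ORPHAN", "o", "METABOLITE")
  expect_length(validateGraph(g), 1)
  expect_match(validateGraph(g), "orphan")
  expect_identical(validateGraph(g, orphanCheck = FALSE), character())
  g@edges[["e1"]]$substrate_id <- "ghost"
  expect_true(any(grepl("dangling substrate", validateGraph(g))))
})

test_that("every edge sits in exactly one out- and one in-index bucket", {
  for (seed in 1:5) {
    g <- generateFixture(seed)
    for (eid in edgeIds(g)) {
      e <- getEdge(g, eid)
      outHits <- sum(vapply(g@outIndex, function(b) eid %in% b, NA))
      inHits <- sum(vapply(g@inIndex, function(b) eid %in% b, NA))
      expect_equal(outHits, 1)
      expect_equal(inHits, 1)
      expect_true(eid %in% g@outIndex[[e$source]])
      expect_true(eid %in% g@inIndex[[e$target]])
    }
  }
})
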