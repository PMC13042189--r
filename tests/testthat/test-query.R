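test_that("androgen class filter retains its curated subgraph", {
  g <- referenceGraph()
  sub <- filterGraph(g, classes = "ANDROGEN")
  expect_equal(numNodes(sub), 26)
  expect_equal(numEdges(sub), 19)
  # the aromatase bridge pulls the estrogen quinone branch into the view
  expect_true(all(c("testosterone", "DHT", "estradiol", "CYP19A1",
                    "SRD5A2", "estradiol-3,4-quinone",
                    "4-OHE2-N7-guanine", "AR_signaling") %in%
                    nodeIds(sub)))
  expect_identical(validateGraph(sub, orphanCheck = FALSE), character())
})

test_that("PAH filter isolates the diol-epoxide route", {
  sub <- filterGraph(referenceGraph(), classes = "PAH")
  expect_true(all(c("CYP1A1", "EPHX1", "BPDE", "BPDE-dG") %in%
                    nodeIds(sub)))
  expect_false("aflatoxin_B1" %in% nodeIds(sub))
})

test_that("empty and absent filter specs behave differently", {
  g <- referenceGraph()
  copy <- filterGraph(g)
  expect_true(graphsIdentical(copy, g))
  none <- filterGraph(g, classes = character())
  expect_equal(numNodes(none), 0)
  expect_equal(numEdges(none), 0)
})

test_that("filtering is idempotent and monotone in the class set", {
  g <- referenceGraph()
  for (cls in list("ANDROGEN", c("PAH", "MYCOTOXIN"))) {
    once <- filterGraph(g, classes = cls)
    twice <- filterGraph(once, classes = cls)
    expect_true(graphsIdentical(once, twice))
  }
  grow <- list(c("PAH"), c("PAH", "ESTROGEN"),
               c("PAH", "ESTROGEN", "ANDROGEN"),
               carcinogenClasses())
  sizes <- vapply(grow, function(cl)
    numNodes(filterGraph(g, classes = cl)), 0)
  expect_true(all(diff(sizes) >= 0))
  prev <- character()
  for (cl in grow) {
    cur <- nodeIds(filterGraph(g, classes = cl))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("node-type filtering drops edges only via lost endpoints", {
  g <- referenceGraph()
  noPathway <- filterGraph(g, nodeTypes = setdiff(nodeTypes(), "PATHWAY"))
  expect_equal(numNodes(noPathway), 90)
  lost <- setdiff(edgeIds(g), edgeIds(noPathway))
  lostTypes <- vapply(lost, function(id) getEdge(g, id)$edge_type, "")
  expect_true(all(lostTypes == "PATHWAY"))
  # edge-type filter composes with the untouched node set
  repairs <- filterGraph(g, edgeTypes = "REPAIRS")
  expect_true(all(vapply(edgeIds(repairs), function(id)
    getEdge(repairs, id)$edge_type, "") == "REPAIRS"))
  expect_equal(numNodes(repairs), numNodes(g))
})

test_that("substring search matches the documented metadata fields", {
  g <- referenceGraph()
  res <- searchGraph(g, "CYP1")
  expect_true(all(c("CYP1A1", "CYP1A2", "CYP1B1") %in% res$matched))
  expect_length(intersect(res$matched, res$expanded), 0)
  # matched CYP1A1 brings its neighbourhood context along
  expect_true(any(c("BaP-7,8-epoxide", "benzo_a_pyrene") %in%
                    c(res$matched, res$expanded)))
  # annotation fields are searchable: the slow-acetylator phenotype
  res2 <- searchGraph(g, "slow acetylator")
  expect_true("NAT2" %in% res2$matched)
  expect_true("phenotype" %in% res2$matchedFields[["NAT2"]])
  # case-insensitive, plain substring
  expect_identical(searchGraph(g, "bpde")$matched,
                   searchGraph(g, "BPDE")$matched)
  expect_identical(searchGraph(g, "zzzz-no-such-token")$matched,
                   character())
  expect_error(searchGraph(g, "   "), "non-empty")
})

test_that("prefix-extending a query never grows the matched set", {
  g <- referenceGraph()
  queries <- c("C", "CY", "CYP", "CYP1", "CYP1A", "CYP1A1")
  prev <- NULL
  for (q in queries) {
    cur <- searchGraph(g, q)$matched
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("search expansion equals a brute-force neighbour scan on fixtures", {
  for (seed in 1:5) {
    g <- generateFixture(seed)
    id <- nodeIds(g)[1 + (seed %% numNodes(g))]
    res <- searchGraph(g, getNode(g, id)$label)
    expect_true(id %in% res$matched)
    scan <- sort(setdiff(unique(unlist(
      lapply(res$matched, oracleNeighbors, g = g))), res$matched))
    expect_identical(res$expanded, scan)
  }
})

test_that("derived class membership equals the stored manifest tags", {
  g <- referenceGraph()
  derived <- deriveClassMembership(g)
  stored <- lapply(setNames(nodeIds(g), nodeIds(g)),
                   function(id) getNode(g, id)$classes)
  expect_identical(derived, stored)
})

test_that("a simple activation chain is tagged with its carcinogen class", {
  g <- tinyChainGraph()
  derived <- deriveClassMembership(g)
  expect_identical(derived[["C1"]], "PAH")
  expect_identical(derived[["M1"]], "PAH")
  expect_identical(derived[["A1"]], "PAH")
  expect_identical(derived[["E1"]], "PAH")   # activates along the chain
  expect_identical(derived[["E2"]], "PAH")   # diverts the chain
  expect_identical(derived[["M2"]], "PAH")   # detoxification product
  expect_identical(derived[["R1"]], "PAH")   # repairs the chain adduct
  expect_identical(deriveClassMembership(emptyGraph()),
                   setNames(list(), character()))
})
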