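test_that("downstream adduct closure follows the successor relation", {
  g <- referenceGraph()
  expect_true("BPDE-dG" %in% downstreamAdducts(g, "benzo_a_pyrene"))
  expect_identical(downstreamAdducts(g, "BPDE-GSH"), character())
  expect_error(downstreamAdducts(g, "CYP1A1"), "CARCINOGEN or METABOLITE")
  expect_error(downstreamAdducts(g, "nope"), "unknown node")
})

test_that("closure terminates on metabolic cycles", {
  g <- cyclicGraph()
  expect_identical(downstreamAdducts(g, "C1"), "A1")
  expect_identical(downstreamAdducts(g, "M1"), "A1")
  expect_identical(downstreamAdducts(g, "M2"), "A1")
  expect_identical(downstreamAdducts(g, "C1"), oracleDownstream(g, "C1"))
})

test_that("gene impact counts distinct formed, averted and repaired adducts", {
  g <- tinyChainGraph()
  expect_equal(geneImpactScore(g, "E1")$impact_score, 1)  # forms A1
  expect_equal(geneImpactScore(g, "E2")$impact_score, 1)  # averts A1
  expect_equal(geneImpactScore(g, "R1")$impact_score, 1)  # repairs A1
  ref <- referenceGraph()
  xpc <- geneImpactScore(ref, "XPC")
  expect_gte(xpc$impact_score, 1)
  expect_identical(xpc$role, "REPAIR")
  # an enzyme with no edges has zero impact
  g2 <- addNode(g, kgNode("E9", "idle", "ENZYME", phase = "PHASE_I",
                          role = "ACTIVATION"))
  expect_equal(geneImpactScore(g2, "E9")$impact_score, 0)
  expect_error(geneImpactScore(g, "C1"), "ENZYME")
})

test_that("per-role weights generalise the distinct-adduct count", {
  g <- tinyChainGraph()
  expect_equal(geneImpactScore(g, "E1",
                               weights = c(2, 0, 0))$impact_score, 2)
  expect_equal(geneImpactScore(g, "R1",
                               weights = c(1, 1, 3))$impact_score, 3)
})

test_that("impact equals brute-force recomputation on random fixtures", {
  checked <- 0L
  for (seed in 1:100) {
    g <- generateFixture(seed, allowCycles = (seed %% 3 == 0))
    expect_lte(numNodes(g), 30)
    for (id in nodeIds(g)) {
      n <- getNode(g, id)
      if (n$node_type %in% c("CARCINOGEN", "METABOLITE")) {
        expect_identical(downstreamAdducts(g, id),
                         oracleDownstream(g, id),
                         info = sprintf("seed %d chem %s", seed, id))
      } else if (n$node_type == "ENZYME") {
        expect_equal(geneImpactScore(g, id)$impact_score,
                     oracleImpact(g, id),
                     info = sprintf("seed %d enzyme %s", seed, id))
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 100L)
})

test_that("adding an adduct-formation edge never lowers impact scores", {
  for (seed in 1:10) {
    g <- generateFixture(seed, scoredFraction = 0.4)
    enzymes <- nodeIds(g)[vapply(nodeIds(g), function(id)
      getNode(g, id)$node_type == "ENZYME", NA)]
    before <- vapply(enzymes, function(id)
      geneImpactScore(g, id)$impact_score, 0)
    chems <- nodeIds(g)[vapply(nodeIds(g), function(id)
      getNode(g, id)$node_type %in% c("CARCINOGEN", "METABOLITE"), NA)]
    adducts <- nodeIds(g)[vapply(nodeIds(g), function(id)
      getNode(g, id)$node_type == "DNA_ADDUCT", NA)]
    placed <- FALSE
    for (src in chems) {
      for (tgt in adducts) {
        ok <- tryCatch({
          g2 <- addEdge(g, kgEdge("extraFA", src, tgt, "FORMS_ADDUCT"))
          TRUE
        }, error = function(e) FALSE)
        if (ok) { placed <- TRUE; break }
      }
      if (placed) break
    }
    if (!placed) next
    after <- vapply(enzymes, function(id)
      geneImpactScore(g2, id)$impact_score, 0)
    expect_true(all(after >= before))
  }
})

test_that("class reservoirs follow the signed-bar convention", {
  g <- referenceGraph()
  pah <- classReservoir(g, "PAH")
  expect_gt(pah$activation_sum, 0)
  expect_lt(pah$detoxification_sum, 0)   # scored GSTM1 pulls it negative
  expect_gt(pah$mixed_sum, 0)            # scored EPHX1 is mixed-function
  expect_gte(pah$repair_count, 1)        # scored XPC repairs BPDE-dG
  solvent <- classReservoir(g, "SOLVENT")
  expect_equal(solvent$scored_gene_count, 0)
  expect_equal(solvent$activation_sum, 0)
  expect_equal(solvent$detoxification_sum, 0)
  expect_error(classReservoir(g, "NOT_A_CLASS"), "unknown")
  # arithmetic on a constructed two-enzyme class
  g2 <- tinyChainGraph()
  g2 <- addNode(g2, kgNode("E3", "activase 2", "ENZYME",
                           phase = "PHASE_I", role = "ACTIVATION",
                           activityScore = 0.5, classes = "PAH"))
  g2 <- addEdge(g2, kgEdge("e9", "E3", "M1", "ACTIVATES",
                           substrateId = "C1"))
  res <- classReservoir(g2, "PAH")
  expect_equal(res$activation_sum, 1.5)
  expect_equal(res$detoxification_sum, -0.5)
})

test_that("scoreAll reports 13 scored genes spanning 8 classes", {
  tabs <- scoreAll(referenceGraph())
  expect_equal(nrow(tabs$genes), 13)
  expect_equal(nrow(tabs$classes), 8)
  expect_true(all(tabs$classes$scored_gene_count >= 1))
  expect_identical(tabs$genes$gene_id, sort(tabs$genes$gene_id))
  # genes touching several classes are counted in each
  expect_gte(sum(tabs$classes$scored_gene_count), nrow(tabs$genes))
  # impact never exceeds the adduct inventory; touches never exceed 9
  expect_true(all(tabs$genes$impact_score <= 11))
  expect_true(all(tabs$genes$class_touch_count <= 9))
})

test_that("an unscored graph yields empty scoring tables", {
  tabs <- scoreAll(generateFixture(3, scoredFraction = 0))
  expect_equal(nrow(tabs$genes), 0)
  expect_equal(nrow(tabs$classes), 0)
})

test_that("score tables export with the documented column order", {
  genePath <- withr::local_tempfile(fileext = ".csv")
  classPath <- withr::local_tempfile(fileext = ".csv")
  writeScoreTables(referenceGraph(), genePath, classPath)
  genes <- read.csv(genePath)
  expect_identical(names(genes),
                   c("gene_id", "role", "activity_score", "impact_score",
                     "class_touch_count"))
  classes <- read.csv(classPath)
  expect_identical(names(classes),
                   c("carcinogen_class", "activation_sum",
                     "detoxification_sum", "mixed_sum", "repair_count",
                     "scored_gene_count"))
  expect_equal(nrow(genes), 13)
})
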