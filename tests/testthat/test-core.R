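# worked-example fixtures: query DEG "a" coexpressed with 3 of the 5 DEG
# members of gene set A (see helper-fixtures.R)

test_that("a gene set's testable membership is its DEG intersection", {
    gs <- GeneSet("S", c("a", "b", "c", "d"))
    expect_setequal(setDegs(gs, c("b", "d", "e")), c("b", "d"))
    expect_equal(setDegs(gs, c("x", "y")), character())
    expect_setequal(setDegs(gs, c("a", "b", "c", "d", "e")),
                    c("a", "b", "c", "d"))
})

test_that("gene-level pair counts reproduce the worked example", {
    net <- workedExampleNetwork()
    degs <- c("a", paste0("g", 1:5))
    setA <- GeneSet("SetA", paste0("g", 1:5))
    coll <- GeneSetCollection(list(setA))

    pc <- pairCountsGene("a", setA, coll, degs, net)
    expect_equal(pc$m, 3L)
    expect_equal(pc$n, 5L)
    # single-set collection: background equals the per-set counts
    expect_equal(pc$M, 3L)
    expect_equal(pc$N, 5L)

    # no network edges -> m = 0
    empty <- coexpressionNetwork(NULL, nodes = degs, threshold = 0.7)
    pc0 <- pairCountsGene("a", setA, coll, degs, empty)
    expect_equal(pc0$m, 0L)
    expect_equal(pc0$n, 5L)

    # the query gene inside the set: self-pair excluded, n = 4
    setB <- GeneSet("SetB", c("a", paste0("g", 1:4)))
    collB <- GeneSetCollection(list(setB))
    pcB <- pairCountsGene("a", setB, collB, degs, net)
    expect_equal(pcB$n, 4L)
    expect_equal(pcB$m, 3L)

    expect_error(pairCountsGene("zz", setA, coll, degs, net), "not a")
})

test_that("background counts sum per-set contributions (and dedup on request)", {
    net <- workedExampleNetwork()
    degs <- c("a", paste0("g", 1:5))
    setA <- GeneSet("SetA", paste0("g", 1:5))
    setC <- GeneSet("SetC", c("g1", "g4"))       # overlaps SetA
    coll <- GeneSetCollection(list(setA, setC))

    pc <- pairCountsGene("a", setA, coll, degs, net)
    expect_equal(pc$N, 5L + 2L)                  # g1, g4 counted twice
    expect_equal(pc$M, 3L + 1L)                  # a-g1 edge counted twice

    pcU <- pairCountsGene("a", setA, coll, degs, net,
                          background = "dedup_union")
    expect_equal(pcU$N, 5L)                      # distinct partners
    expect_equal(pcU$M, 3L)
})

test_that("hypergeometric upper tail is exact, monotone and guarded", {
    expect_equal(hypergeomUpperTail(0, 5, 3, 10), 1)
    expect_equal(hypergeomUpperTail(1, 1, 3, 10), 0.3)
    expect_equal(hypergeomUpperTail(3, 5, 20, 60),
                 hypergeomOracle(3, 5, 20, 60), tolerance = 1e-12)
    # non-increasing in m at fixed (n, M, N)
    p <- vapply(0:5, function(m) hypergeomUpperTail(m, 5, 20, 60),
                numeric(1))
    expect_true(all(diff(p) <= 0))
    expect_error(hypergeomUpperTail(6, 5, 20, 60), "invariants")
    expect_error(hypergeomUpperTail(2, 5, 1, 60), "invariants")
    expect_error(hypergeomUpperTail(0, 0, 0, 10), "n >= 1")
})

test_that("gene-level association handles saturation, NA sets and BH families", {
    # saturated urn: every possible pair coexpressed -> p = q = 1
    net <- coexpressionNetwork(
        data.frame(gene_a = "a", gene_b = c("g1", "g2")),
        nodes = c("a", "g1", "g2"), threshold = 0.7)
    degs <- c("a", "g1", "g2")
    coll <- GeneSetCollection(list(GeneSet("S1", c("g1", "g2"))))
    res <- geneAssociation("a", coll, degs, net)
    expect_equal(res$p_value, 1)
    expect_equal(res$q_value, 1)
    expect_false(res$significant)

    # a set with no DEG members is reported NA and kept out of the BH family
    coll2 <- GeneSetCollection(list(
        GeneSet("S1", c("g1", "g2")), GeneSet("S0", c("x1", "x2"))))
    res2 <- geneAssociation("a", coll2, degs, net)
    expect_equal(res2$n[res2$set_id == "S0"], 0L)
    expect_true(is.na(res2$p_value[res2$set_id == "S0"]))
    expect_true(is.na(res2$q_value[res2$set_id == "S0"]))
    # BH family size 1: q equals p for the testable set
    expect_equal(res2$q_value[res2$set_id == "S1"],
                 res2$p_value[res2$set_id == "S1"])

    expect_warning(
        geneAssociation("a", GeneSetCollection(list(GeneSet("S0", "x1"))),
                        degs, net),
        "no testable")
})

test_that("association values are invariant to gene-set order", {
    net <- workedExampleNetwork()
    degs <- c("a", paste0("g", 1:5))
    sets <- list(GeneSet("S1", c("g1", "g2", "g3")),
                 GeneSet("S2", c("g2", "g4", "g5")),
                 GeneSet("S3", c("g1", "g5")))
    res1 <- geneAssociation("a", GeneSetCollection(sets), degs, net)
    res2 <- geneAssociation("a", GeneSetCollection(sets[c(3, 1, 2)]),
                            degs, net)
    res2 <- res2[match(res1$set_id, res2$set_id), ]
    expect_equal(res1$p_value, res2$p_value)
    expect_equal(res1$q_value, res2$q_value)
})

test_that("list-level pair counts reproduce the worked example", {
    L <- paste0("l", 1:7)
    S <- paste0("s", 1:5)
    cross <- data.frame(
        gene_a = c("l1", "l1", "l2", "l3", "l4", "l5"),
        gene_b = c("s1", "s2", "s3", "s1", "s5", "s2"))
    net <- coexpressionNetwork(cross, nodes = c(L, S), threshold = 0.7)
    degs <- c(L, S)
    setA <- GeneSet("SetA", S)
    coll <- GeneSetCollection(list(setA))

    pc <- pairCountsList(L, setA, coll, degs, net)
    expect_equal(pc$m, 6L)
    expect_equal(pc$n, 35L)                      # disjoint: |L| x |S'|

    # list identical to the set: n_g = choose(5, 2)
    setS <- GeneSet("SetS", S)
    pcS <- pairCountsList(S, setS, GeneSetCollection(list(setS)), degs, net)
    expect_equal(pcS$n, 10L)

    # no edges anywhere -> m_g = 0
    bare <- coexpressionNetwork(NULL, nodes = degs, threshold = 0.7)
    expect_equal(pairCountsList(L, setA, coll, degs, bare)$m, 0L)

    expect_error(pairCountsList(character(), setA, coll, degs, net),
                 "empty")
})

test_that("overlapping list and set count shared pairs once", {
    # L = {a, b, c}, S' = {b, c, d}; k = 2
    degs <- c("a", "b", "c", "d")
    net <- coexpressionNetwork(
        data.frame(gene_a = c("b", "a"), gene_b = c("c", "d")),
        nodes = degs, threshold = 0.7)
    setS <- GeneSet("S", c("b", "c", "d"))
    coll <- GeneSetCollection(list(setS))
    pc <- pairCountsList(c("a", "b", "c"), setS, coll, degs, net)
    expect_equal(pc$n, 3L * 3L - 2L - 1L)        # 6 distinct pairs
    # edges b-c (both in L and S) and a-d (a in L, d in S) counted once
    expect_equal(pc$m, 2L)
})

test_that("a one-gene list reduces to the gene-level association", {
    net <- workedExampleNetwork()
    degs <- c("a", paste0("g", 1:5))
    sets <- list(GeneSet("S1", paste0("g", 1:5)),
                 GeneSet("S2", c("g2", "g4")))
    coll <- GeneSetCollection(sets)
    gl <- geneAssociation("a", coll, degs, net)
    ll <- listAssociation("a", coll, degs, net)
    for (col in c("m", "n", "M", "N", "p_value", "q_value")) {
        expect_equal(ll[[col]], gl[[col]])
    }
})

test_that("list association applies BH across the collection", {
    net <- workedExampleNetwork()
    degs <- c("a", paste0("g", 1:5))
    one <- GeneSetCollection(list(GeneSet("S1", paste0("g", 1:3))))
    res <- listAssociation("a", one, degs, net)
    expect_equal(res$q_value, res$p_value)       # K = 1
    expect_equal(res$query_id, "DEG_list")
})

test_that("the full pipeline is deterministic and permutation-invariant", {
    sim <- generateDataset(simulationConfig(
        nGenes = 200, nControl = 4, nCase = 10, nDegs = 30,
        moduleSize = 10, plantedSetOverlap = 8, nSets = 8,
        setSizeRange = c(8, 15), seed = 77))
    cfg <- gsceConfig()

    res1 <- runGsce(sim$dataset, sim$collection, cfg)
    res2 <- runGsce(sim$dataset, sim$collection, cfg)
    d1 <- tempfile(); d2 <- tempfile()
    writeGsceResult(res1, d1); writeGsceResult(res2, d2)
    for (f in c("deg_table.tsv", "network_edges.tsv",
                "list_associations.tsv", "gene_associations.tsv")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }

    # permute gene rows and set order: association tables unchanged
    perm <- sample(nrow(sim$dataset))
    m <- SummarizedExperiment::assay(sim$dataset)[perm, ]
    datasetP <- TwoClassExperiment(m, sampleClasses(sim$dataset))
    collP <- sim$collection[rev(seq_len(length(sim$collection)))]
    resP <- runGsce(datasetP, collP, cfg)
    d3 <- tempfile()
    writeGsceResult(resP, d3)
    for (f in c("list_associations.tsv", "gene_associations.tsv")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d3, f)))
    }
})

test_that("a precomputed query equal to the called DEGs is equivalent", {
    sim <- generateDataset(simulationConfig(
        nGenes = 150, nControl = 4, nCase = 8, nDegs = 25,
        moduleSize = 8, plantedSetOverlap = 6, nSets = 5,
        setSizeRange = c(8, 12), seed = 13))
    auto <- runGsce(sim$dataset, sim$collection)
    called <- degTable(auto)$gene_id[degTable(auto)$is_deg]
    pre <- runGsce(sim$dataset, sim$collection, query = called)
    expect_equal(listResults(pre), listResults(auto))
    geneSort <- function(df) {
        df <- df[order(df$query_id, df$set_id), ]
        rownames(df) <- NULL
        df
    }
    expect_equal(geneSort(geneResults(pre)), geneSort(geneResults(auto)))
})

test_that("class-size minimums gate the run", {
    sim <- generateDataset(simulationConfig(
        nGenes = 60, nControl = 4, nCase = 4, nDegs = 10, moduleSize = 5,
        plantedSetOverlap = 4, nSets = 4, setSizeRange = c(5, 10),
        seed = 3))
    expect_error(runGsce(sim$dataset, sim$collection), "minimum of 3")
    expect_warning(
        res <- runGsce(sim$dataset, sim$collection, strict = FALSE),
        "minimum of 3")
    expect_s4_class(res, "GsceResult")
})

test_that("queryTopK restricts the query list to top DEGs by |log2fc|", {
    sim <- generateDataset(simulationConfig(
        nGenes = 150, nControl = 4, nCase = 8, nDegs = 25,
        moduleSize = 8, plantedSetOverlap = 6, nSets = 5,
        setSizeRange = c(8, 12), seed = 19))
    res <- runGsce(sim$dataset, sim$collection,
                   gsceConfig(queryTopK = 5))
    expect_equal(length(unique(geneResults(res)$query_id)), 5L)
    want <- utils::head(rankDegsByFoldChange(degTable(res)), 5)
    expect_setequal(unique(geneResults(res)$query_id), want)
    expect_equal(res@provenance$query_size, 5L)
})
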