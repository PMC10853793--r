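test_that("two-sample t test matches the pooled formula and t.test", {
    # identical groups
    r <- twoSampleTTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$t_stat, 0)
    expect_equal(r$p_value, 1)

    # hand-evaluated pooled form: x = 1:4, y = c(2,4,6,8)
    x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
    d <- mean(y) - mean(x)
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (4 + 4 - 2)
    tHand <- d / sqrt(sp2 * (1 / 4 + 1 / 4))
    pHand <- 2 * pt(-abs(tHand), 6)
    r <- twoSampleTTest(x, y, equalVariance = TRUE)
    expect_equal(r$t_stat, tHand, tolerance = 1e-12)
    expect_equal(r$p_value, pHand, tolerance = 1e-12)

    # Welch agrees with stats::t.test on random data
    set.seed(3)
    for (i in 1:5) {
        a <- rnorm(5); b <- rnorm(7, 1, 2)
        r <- twoSampleTTest(a, b, equalVariance = FALSE)
        tt <- t.test(b, a)
        expect_equal(r$t_stat, unname(tt$statistic))
        expect_equal(r$p_value, tt$p.value)
    }

    # separation limit: p -> 0 as jitter -> 0
    pPrev <- 1
    for (eps in c(1e-2, 1e-4, 1e-6)) {
        p <- twoSampleTTest(c(0, 0, 0, 0) + rnorm(4, 0, eps),
                            c(1, 1, 1, 1) + rnorm(4, 0, eps))$p_value
        expect_lt(p, pPrev)
        pPrev <- p
    }
    expect_equal(twoSampleTTest(c(0, 0), c(1, 1))$p_value, 0)

    expect_error(twoSampleTTest(1, c(1, 2)), "at least 2")
})

test_that("log2 fold change is case mean minus control mean", {
    expect_equal(log2FoldChange(c(1, 2, 3), c(4, 5, 6)), 3)
    expect_equal(log2FoldChange(c(2, 2), c(2, 2)), 0)
    expect_equal(log2FoldChange(c(4, 4), c(1, 1)), -3)
    expect_error(log2FoldChange(numeric(), 1), "empty")
})

test_that("BH adjustment reproduces the step-up formula", {
    expect_equal(benjaminiHochberg(c(0.005, 0.01, 0.03, 0.04)),
                 c(0.02, 0.02, 0.04, 0.04))
    expect_equal(benjaminiHochberg(0.2), 0.2)
    expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
    expect_error(benjaminiHochberg(c(0.1, 1.2)), "0, 1")
    expect_error(benjaminiHochberg(c(0.1, NA)), "0, 1")
})

test_that("BH output is order-invariant and satisfies q >= p", {
    set.seed(7)
    for (i in 1:10) {
        p <- runif(50)^2
        q <- benjaminiHochberg(p)
        expect_true(all(q >= p))
        perm <- sample(50)
        expect_equal(benjaminiHochberg(p[perm])[order(perm)], q)
    }
})

test_that("per-gene statistics agree with gene-by-gene t.test", {
    tce <- randomDataset(nGenes = 30, nControl = 5, nCase = 7, seed = 11)
    ctrl <- SummarizedExperiment::assay(tce)[, 1:5]
    case <- SummarizedExperiment::assay(tce)[, 6:12]
    for (equalVar in c(TRUE, FALSE)) {
        deg <- selectDegs(tce, degConfig(equalVariance = equalVar))
        for (i in c(1, 13, 30)) {
            tt <- t.test(case[i, ], ctrl[i, ], var.equal = equalVar)
            expect_equal(deg$t_stat[i], unname(tt$statistic))
            expect_equal(deg$p_value[i], tt$p.value)
            expect_equal(deg$log2fc[i], mean(case[i, ]) - mean(ctrl[i, ]))
        }
        expect_equal(deg$q_value, p.adjust(deg$p_value, "BH"))
    }
})

test_that("microarray rule keeps the top-N by |log2fc| among p < cut", {
    # 300 genes, 120 strongly shifted -> more than topN pass p < 0.05
    set.seed(21)
    n <- 300
    m <- matrix(rnorm(n * 20, 7, 1), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n),
                                c(sprintf("c%02d", 1:10),
                                  sprintf("t%02d", 1:10))))
    shift <- runif(120, 1.5, 3)
    m[1:120, 11:20] <- m[1:120, 11:20] + shift
    tce <- TwoClassExperiment(m, rep(c("control", "case"), each = 10))

    deg <- selectDegs(tce, degConfig("microarray_topN", topN = 50))
    expect_gt(sum(deg$p_value < 0.05), 50)        # cap binds
    expect_equal(sum(deg$is_deg), 50L)
    expect_true(all(deg$p_value[deg$is_deg] < 0.05))
    # kept genes dominate dropped eligible genes on |log2fc|
    eligible <- deg[deg$p_value < 0.05, ]
    expect_gte(min(abs(eligible$log2fc[eligible$is_deg])),
               max(abs(eligible$log2fc[!eligible$is_deg])))

    # below the cap every eligible gene is a DEG
    deg2 <- selectDegs(tce, degConfig("microarray_topN", topN = 400))
    expect_equal(sum(deg2$is_deg), sum(deg2$p_value < 0.05))
    expect_lte(sum(deg2$is_deg), 400L)
})

test_that("threshold rule applies inclusive bounds on |log2fc| and q", {
    # noise-free construction: case = control + exactly 1.0 on two genes
    m <- matrix(rep(c(5, 5, 5, 5), each = 4), nrow = 4,
                dimnames = list(paste0("g", 1:4),
                                c("c1", "c2", "t1", "t2")))
    m <- m + matrix(c(0.01, -0.01, 0.02, -0.02), 4, 4, byrow = TRUE)
    m[1, 3:4] <- m[1, 3:4] + 1.0       # lfc exactly 1 -> DEG (inclusive >=)
    m[2, 3:4] <- m[2, 3:4] + 0.99      # below the cut -> not a DEG
    m[3, 3:4] <- m[3, 3:4] + 3
    tce <- TwoClassExperiment(m, c("control", "control", "case", "case"))
    deg <- selectDegs(tce, degConfig("threshold"))
    expect_equal(deg$log2fc[1], 1.0)
    expect_true(deg$is_deg[1])
    expect_false(deg$is_deg[2])
    expect_true(deg$is_deg[3])
    # flag reproduces the rule exactly
    expect_equal(deg$is_deg,
                 abs(deg$log2fc) >= 1 & deg$q_value <= 0.05)
})

test_that("precomputed mode marks the supplied list and rejects strangers", {
    tce <- randomDataset(seed = 5)
    deg <- selectDegs(tce, degConfig("precomputed"),
                      degList = c("g003", "g010"))
    expect_equal(deg$gene_id[deg$is_deg], c("g003", "g010"))
    expect_error(selectDegs(tce, degConfig("precomputed"),
                            degList = c("g003", "nope")), "nope")
    expect_error(selectDegs(tce, degConfig("precomputed")), "degList")
})

test_that("DEGs rank by descending |log2fc| with gene-id tiebreak", {
    rec <- data.frame(gene_id = c("gA", "gB", "gC"),
                      log2fc = c(2, -3, 1),
                      is_deg = TRUE)
    expect_equal(rankDegsByFoldChange(rec), c("gB", "gA", "gC"))
    tie <- data.frame(gene_id = c("G2", "G1"), log2fc = c(2, -2),
                      is_deg = TRUE)
    expect_equal(rankDegsByFoldChange(tie), c("G1", "G2"))
    expect_equal(rankDegsByFoldChange(rec[0, ]), character())
    # non-DEGs never appear
    rec$is_deg <- c(TRUE, FALSE, TRUE)
    expect_equal(rankDegsByFoldChange(rec), c("gA", "gC"))
})

test_that("BH keeps the false-discovery proportion near nominal on null data", {
    # 200 all-null datasets, 500 genes, 10 vs 10
    set.seed(2024)
    nrep <- 200
    fdp <- numeric(nrep)
    for (i in seq_len(nrep)) {
        m <- matrix(rnorm(500 * 20), nrow = 500,
                    dimnames = list(sprintf("g%03d", 1:500),
                                    sprintf("s%02d", 1:20)))
        tce <- TwoClassExperiment(m, rep(c("control", "case"), each = 10))
        deg <- selectDegs(tce, degConfig("threshold", lfcCut = 0))
        R <- sum(deg$q_value <= 0.05)
        fdp[i] <- if (R > 0) R / R else 0   # every discovery is false
    }
    mcse <- sd(fdp) / sqrt(nrep)
    expect_lte(mean(fdp), 0.05 + 2 * mcse)
})
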