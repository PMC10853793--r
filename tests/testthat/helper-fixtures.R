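# fixtures built in code; no files are shipped

# small expression + label TSVs on disk; returns the two paths
writeToyExpressionFiles <- function(dir = tempfile("io")) {
    dir.create(dir)
    ef <- file.path(dir, "expr.tsv")
    lf <- file.path(dir, "labels.tsv")
    writeLines(c("gene\ts1\ts2\ts3\ts4",
                 "G1\t1\t2\t3\t4",
                 "G2\t4\t3\t2\t1",
                 "G3\t0\t0\t1\t1"), ef)
    writeLines(c("s1\tcontrol", "s2\tcontrol", "s3\tcase", "s4\tcase"), lf)
    list(expr = ef, labels = lf)
}

# random two-class experiment with controllable dimensions
randomDataset <- function(nGenes = 20, nControl = 4, nCase = 6, seed = 1) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * (nControl + nCase), 7, 1), nrow = nGenes,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                c(sprintf("c%02d", seq_len(nControl)),
                                  sprintf("t%02d", seq_len(nCase)))))
    TwoClassExperiment(m, rep(c("control", "case"), c(nControl, nCase)))
}

# the hand-drawn example: query DEG "a", gene set of 5 DEGs g1..g5,
# a coexpressed with g1..g3 only
workedExampleNetwork <- function() {
    coexpressionNetwork(
        data.frame(gene_a = "a", gene_b = c("g1", "g2", "g3"),
                   r = c(0.9, 0.8, -0.75)),
        nodes = c("a", paste0("g", 1:5)), threshold = 0.7)
}

# a dataset whose case-sample profiles force a known edge structure:
# each row of `edges` becomes an |r| >= c edge, everything else stays below
datasetWithPlantedEdges <- function(genes, edges, nControl = 4, nCase = 10,
                                    seed = 99) {
    set.seed(seed)
    n <- length(genes)
    m <- matrix(rnorm(n * (nControl + nCase), 7, 1), nrow = n,
                dimnames = list(genes,
                                c(sprintf("c%02d", seq_len(nControl)),
                                  sprintf("t%02d", seq_len(nCase)))))
    caseCols <- nControl + seq_len(nCase)
    for (k in seq_len(nrow(edges))) {
        a <- edges[k, 1]; b <- edges[k, 2]
        m[b, caseCols] <- m[a, caseCols] + rnorm(nCase, 0, 0.05)
    }
    TwoClassExperiment(m, rep(c("control", "case"), c(nControl, nCase)))
}

# exhaustive valid (m, n, M, N) tuples with N <= maxN
allPairCountTuples <- function(maxN = 12) {
    out <- list(); k <- 0L
    for (N in 1:maxN) for (n in 1:N) for (M in 0:N) {
        for (m in 0:min(n, M)) {
            k <- k + 1L
            out[[k]] <- c(m = m, n = n, M = M, N = N)
        }
    }
    do.call(rbind, out)
}
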