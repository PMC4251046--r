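# Small deterministic experiment builders used across pipeline tests.

# two K=3 genes: one an all-strict chain at the base level, one whose
# base pattern carries a forbidden triple but gains a single strict
# outcome (distance 1) at a higher ladder rung
twoGeneExperiment <- function() {
    g1 <- c(1:5, 11:15, 21:25)
    g2 <- c(1, 2, 3, 4, 5, 1, 3.5, 6, 8.5, 11, 6, 7, 8, 9, 10)
    mat <- rbind(chain = g1, bridged = g2)
    colnames(mat) <- paste0(rep(c("A", "B", "C"), each = 5), 1:5)
    design <- data.frame(sample = colnames(mat),
                         group = rep(c("A", "B", "C"), each = 5))
    OrderExperiment(mat, design)
}

test_that("experiment construction validates the design contract", {
    exp <- twoGeneExperiment()
    expect_s4_class(exp, "OrderExperiment")
    expect_identical(groupLabels(exp), c("A", "B", "C"))
    s <- geneSamples(exp, "chain")
    expect_identical(names(s), c("A", "B", "C"))
    expect_equal(unname(s$B), 11:15)
    expect_error(geneSamples(exp, "nope"), "unknown gene")
    # unmapped sample is an error naming the sample
    mat <- matrix(1:8, 2, 4,
                  dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
    expect_error(
        OrderExperiment(mat, data.frame(sample = paste0("s", 1:3),
                                        group = c("x", "x", "y"))),
        "s4")
    # a single-replicate group is rejected
    expect_error(
        OrderExperiment(mat, data.frame(sample = paste0("s", 1:4),
                                        group = c("x", "x", "y", "z"))),
        ">= 2 replicates")
    # duplicate gene identifiers are rejected by name
    mat2 <- matrix(1:8, 2, 4,
                   dimnames = list(c("g1", "g1"), paste0("s", 1:4)))
    expect_error(
        OrderExperiment(mat2, data.frame(sample = paste0("s", 1:4),
                                         group = c("x", "x", "y", "y"))),
        "g1")
})

test_that("experiments round-trip through matrix and design files", {
    exp <- twoGeneExperiment()
    mdir <- withr::local_tempdir()
    mat <- SummarizedExperiment::assay(exp)
    mpath <- file.path(mdir, "matrix.tsv")
    dpath <- file.path(mdir, "design.tsv")
    write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
                mpath, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("sample\tgroup",
                 paste(colnames(mat),
                       rep(c("A", "B", "C"), each = 5), sep = "\t")),
               dpath)
    exp2 <- loadExperiment(mpath, dpath)
    expect_equal(SummarizedExperiment::assay(exp2), mat)
    expect_identical(groupLabels(exp2), c("A", "B", "C"))
    # non-numeric cells are reported by column
    bad <- file.path(mdir, "bad.tsv")
    writeLines(c("gene\ts1\ts2\ts3\ts4", "g1\t1\tx\t3\t4", "g2\t1\t2\t3\t4"),
               bad)
    dd <- file.path(mdir, "d2.tsv")
    writeLines(paste(paste0("s", 1:4), c("a", "a", "b", "b"), sep = "\t"),
               dd)
    expect_error(loadExperiment(bad, dd), "s2")
})

test_that("one-pattern assignment is total, with non-orderable fallback flagged", {
    exp <- twoGeneExperiment()
    asg <- assignPatterns(exp, algoConfig(seed = 1), scheme = "one_pattern")
    expect_identical(asg$gene, c("chain", "bridged"))
    expect_true(all(asg$frequency == 1))
    expect_identical(asg$pattern_code[asg$gene == "chain"], "111")
    expect_true(all(asg$orderable))
    # capping the ladder below the rescue rung forces the fixed-level
    # fallback, flagged non-orderable, so binning stays total
    asgCap <- assignPatterns(exp, algoConfig(alphaMax = 0.1, seed = 1),
                             scheme = "one_pattern")
    row <- asgCap[asgCap$gene == "bridged", ]
    expect_false(row$orderable)
    expect_identical(row$method, "fixed-fallback")
    expect_identical(row$pattern_code, "010")
})

test_that("schemes agree on genes orderable at the base level and multi frequencies are proper", {
    exp <- twoGeneExperiment()
    cfg <- algoConfig(M = 60, seed = 5)
    one <- assignPatterns(exp, cfg, scheme = "one_pattern",
                          genes = "chain")
    multi <- assignPatterns(exp, cfg, scheme = "multi_pattern",
                            genes = "chain")
    expect_identical(one$pattern_code, multi$pattern_code)
    expect_equal(multi$frequency, 1)
    # multi-pattern rows per gene sum to at most 1 (no-pattern mass is
    # the remainder)
    multiAll <- assignPatterns(exp, cfg, scheme = "multi_pattern")
    sums <- tapply(multiAll$frequency, multiAll$gene, sum)
    expect_true(all(sums <= 1 + 1e-9))
    # deterministic under a fixed root seed, and per-gene streams do not
    # depend on which other genes are requested
    multi2 <- assignPatterns(exp, cfg, scheme = "multi_pattern",
                             genes = "bridged")
    expect_equal(multi2,
                 multiAll[multiAll$gene == "bridged", , drop = FALSE][
                     , colnames(multi2)],
                 ignore_attr = TRUE)
    expect_error(assignPatterns(exp, cfg, genes = "ghost"), "ghost")
})

test_that("pattern bins collect genes by code, with multi-membership", {
    asg <- data.frame(
        gene = c("g1", "g2", "g3", "g3"),
        pattern_code = c("110", "110", "110", "101"),
        frequency = c(1, 1, 0.6, 0.4),
        alpha_used = 0.05, orderable = TRUE, method = "varying",
        stringsAsFactors = FALSE)
    cl <- clusterByPattern(asg)
    expect_setequal(names(cl), c("110", "101"))
    expect_setequal(cl[["110"]], c("g1", "g2", "g3"))
    expect_identical(cl[["101"]], "g3")
    # frequency cutoff drops weak memberships
    cl2 <- clusterByPattern(asg, fMin = 0.5)
    expect_identical(cl2[["110"]], c("g1", "g2", "g3"))
    expect_false("101" %in% names(cl2))
    expect_length(clusterByPattern(asg[0, ]), 0L)
})

test_that("summary curves report orderable fractions and the two distance means", {
    exp <- twoGeneExperiment()
    cv <- summaryCurves(exp, c(0.05, 0.5), algoConfig())
    expect_identical(colnames(cv),
                     c("alpha_max", "fraction_orderable", "mu_d1", "mu_d2"))
    # at the base level only the chain gene is orderable
    expect_equal(cv$fraction_orderable[1], 0.5)
    expect_equal(cv$mu_d1[1], 0)
    expect_true(is.na(cv$mu_d2[1]))
    # at 0.5 the bridged gene gains exactly one strict outcome
    expect_equal(cv$fraction_orderable[2], 1)
    expect_equal(cv$mu_d1[2], 0.5)
    expect_equal(cv$mu_d2[2], 1)
    expect_error(summaryCurves(exp, c(0.5, 0.05)), "increasing")
})

test_that("orderable fraction is non-decreasing and distance means are ordered on simulated data", {
    sim <- simulateExperiment(nGenes = 30, delta = 1, seed = 11)
    cv <- summaryCurves(sim$experiment, c(0.05, 0.1, 0.2, 0.5))
    expect_true(all(diff(cv$fraction_orderable) >= 0))
    sub <- !is.na(cv$mu_d2)
    expect_true(all(cv$mu_d2[sub] >= cv$mu_d1[sub]))
    # rescuing a non-orderable gene requires changing at least one outcome
    expect_true(all(cv$mu_d2[sub] >= 1))
})

test_that("hierarchical baseline clusters by correlation of group-mean profiles", {
    reps <- function(mu) rep(mu, each = 2L)
    mat <- rbind(g1 = reps(c(1, 2, 3, 4)),
                 g2 = reps(c(2, 4, 6, 8)),
                 g3 = reps(c(4, 3, 2, 1)))
    colnames(mat) <- paste0("s", 1:8)
    exp <- OrderExperiment(mat,
        data.frame(sample = colnames(mat),
                   group = rep(c("w", "x", "y", "z"), each = 2)))
    cl <- hierarchicalBaseline(exp, 2)
    expect_identical(cl[["g1"]], cl[["g2"]])     # perfectly correlated
    expect_false(cl[["g1"]] == cl[["g3"]])       # anti-correlated
    # the cut-count contract: exactly n clusters come back
    sim <- simulateExperiment(nGenes = 25, delta = 1, seed = 2)
    for (k in c(3, 10, 25))
        expect_identical(length(unique(
            hierarchicalBaseline(sim$experiment, k))), as.integer(k))
    expect_error(hierarchicalBaseline(exp, 10), "exceeds")
    # zero-variance profiles: identical flat genes co-cluster
    mat2 <- rbind(mat, flat1 = rep(5, 8), flat2 = rep(5, 8))
    exp2 <- OrderExperiment(mat2,
        data.frame(sample = colnames(mat),
                   group = rep(c("w", "x", "y", "z"), each = 2)))
    cl2 <- hierarchicalBaseline(exp2, 3)
    expect_identical(cl2[["flat1"]], cl2[["flat2"]])
})

test_that("the command-line interface runs the pipeline end to end, deterministically", {
    dir <- withr::local_tempdir()
    simOut <- file.path(dir, "sim")
    expect_identical(orderpatCLI(c("simulate", "--genes", "12",
        "--K", "4", "--R", "5", "--delta", "3", "--seed", "9",
        "--out", simOut)), 0L)
    expect_true(file.exists(file.path(simOut, "matrix.tsv")))
    expect_true(file.exists(file.path(simOut, "design.tsv")))
    expect_true(file.exists(file.path(simOut, "truth.json")))

    asgOut <- file.path(dir, "asg")
    args <- c("assign", "--matrix", file.path(simOut, "matrix.tsv"),
              "--design", file.path(simOut, "design.tsv"),
              "--seed", "9", "--M", "40", "--out", asgOut)
    expect_identical(orderpatCLI(args), 0L)
    tsv1 <- readLines(file.path(asgOut, "assignments.tsv"))
    expect_identical(orderpatCLI(args), 0L)
    expect_identical(readLines(file.path(asgOut, "assignments.tsv")), tsv1)

    clOut <- file.path(dir, "cl")
    expect_identical(orderpatCLI(c("cluster", "--assignments",
        file.path(asgOut, "assignments.tsv"), "--out", clOut)), 0L)
    clusters <- read.delim(file.path(clOut, "clusters.tsv"),
                           colClasses = "character")
    expect_true(all(c("pattern_code", "gene") %in% colnames(clusters)))

    cvOut <- file.path(dir, "cv")
    expect_identical(orderpatCLI(c("curves",
        "--matrix", file.path(simOut, "matrix.tsv"),
        "--design", file.path(simOut, "design.tsv"),
        "--alpha-grid", "0.05,0.075,0.15,0.5", "--out", cvOut)), 0L)
    cv <- read.delim(file.path(cvOut, "curves.tsv"))
    expect_identical(nrow(cv), 4L)

    blOut <- file.path(dir, "bl")
    expect_identical(orderpatCLI(c("baseline",
        "--matrix", file.path(simOut, "matrix.tsv"),
        "--design", file.path(simOut, "design.tsv"),
        "--n-clusters", "5", "--out", blOut)), 0L)
    bl <- read.delim(file.path(blOut, "baseline_clusters.tsv"))
    expect_identical(length(unique(bl$cluster_id)), 5L)

    # select on the simulated matrix keeps the strongly separated genes
    selOut <- file.path(dir, "sel")
    expect_identical(orderpatCLI(c("select",
        "--matrix", file.path(simOut, "matrix.tsv"),
        "--design", file.path(simOut, "design.tsv"),
        "--out", selOut)), 0L)
    sel <- read.delim(file.path(selOut, "selected_genes.tsv"))
    expect_gt(nrow(sel), 0L)

    # bad usage exits non-zero instead of crashing
    expect_identical(orderpatCLI(c("assign", "--matrix", "missing.tsv")),
                     1L)
    expect_identical(orderpatCLI("frobnicate"), 1L)
    expect_identical(orderpatCLI(character()), 1L)
})
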