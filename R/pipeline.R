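# End-to-end analysis: experiment construction and I/O, per-gene pattern
# assignment over a matrix, pattern-label clustering, summary curves and
# the hierarchical-clustering baseline.

#' Construct an OrderExperiment
#'
#' Binds a gene x sample expression matrix to a design mapping each
#' sample to one of K treatment groups. Group levels keep first-appearance
#' order in the design; the first group is the control by convention.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param design either a data.frame with columns \code{sample} and
#'   \code{group}, or a character vector of group labels named by sample.
#' @return An \linkS4class{OrderExperiment}.
#' @examples
#' m <- matrix(rnorm(24), 3, 8,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
#' design <- data.frame(sample = paste0("s", 1:8),
#'                      group = rep(c("ctrl", "T1", "T2", "T3"), each = 2))
#' OrderExperiment(m, design)
#' @export
OrderExperiment <- function(values, design) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("the expression matrix needs gene rownames and sample colnames")
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene identifiers: ",
             paste(unique(rownames(values)[duplicated(rownames(values))]),
                   collapse = ", "))
    if (is.data.frame(design)) {
        if (!all(c("sample", "group") %in% colnames(design)))
            stop("design needs columns 'sample' and 'group'")
        map <- setNames(as.character(design$group),
                        as.character(design$sample))
    } else {
        map <- design
    }
    missing <- setdiff(colnames(values), names(map))
    if (length(missing))
        stop("sample(s) not mapped to any treatment group: ",
             paste(missing, collapse = ", "))
    grp <- map[colnames(values)]
    grp <- factor(grp, levels = unique(map))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values),
        colData = S4Vectors::DataFrame(group = grp,
                                       row.names = colnames(values)))
    new("OrderExperiment", se)
}

#' Load an experiment from a matrix file and a design file
#'
#' The matrix file is TSV (or CSV for a \code{.csv} extension) with a
#' header row of sample identifiers and gene identifiers in the first
#' column. The design file is a two-column TSV mapping sample to
#' treatment group; a header row \code{sample<TAB>group} is optional.
#'
#' @param matrixPath path to the expression matrix.
#' @param designPath path to the design table.
#' @return An \linkS4class{OrderExperiment}.
#' @export
loadExperiment <- function(matrixPath, designPath) {
    sep <- if (grepl("\\.csv$", matrixPath, ignore.case = TRUE)) "," else "\t"
    tab <- read.delim(matrixPath, sep = sep, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L)
        stop("expression matrix needs a gene-ID column and >= 2 samples")
    genes <- as.character(tab[[1L]])
    vals <- tab[, -1L, drop = FALSE]
    nonnum <- !vapply(vals, is.numeric, logical(1))
    if (any(nonnum))
        stop("non-numeric expression values in column(s): ",
             paste(colnames(vals)[nonnum], collapse = ", "))
    m <- as.matrix(vals)
    rownames(m) <- genes
    des <- read.delim(designPath, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    if (ncol(des) < 2L)
        stop("design table needs two columns: sample, group")
    if (identical(tolower(as.character(des[1L, 1:2])),
                  c("sample", "group")))
        des <- des[-1L, , drop = FALSE]
    design <- data.frame(sample = as.character(des[[1L]]),
                         group = as.character(des[[2L]]),
                         stringsAsFactors = FALSE)
    OrderExperiment(m, design)
}

#' @rdname groupLabels
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' Treatment-group labels of an experiment
#' @param object an \linkS4class{OrderExperiment}.
#' @return character vector of group labels, control first.
#' @aliases groupLabels
#' @export
setMethod("groupLabels", "OrderExperiment", function(object) {
    levels(SummarizedExperiment::colData(object)$group)
})

#' Replicate values of one gene split by treatment group
#'
#' @param experiment an \linkS4class{OrderExperiment}.
#' @param gene gene identifier.
#' @return named list of numeric vectors, one per treatment group in
#'   canonical (control-first) order.
#' @export
geneSamples <- function(experiment, gene) {
    stopifnot(is(experiment, "OrderExperiment"))
    mat <- SummarizedExperiment::assay(experiment)
    if (!gene %in% rownames(mat))
        stop("unknown gene: ", gene)
    grp <- SummarizedExperiment::colData(experiment)$group
    split(mat[gene, ], grp)
}

#' Assign response patterns to every gene of an experiment
#'
#' Under the one-pattern scheme each gene gets the result of the
#' varying-level ladder search; genes for which no orderable pattern
#' exists within \code{alphaMax} fall back to their fixed-level pattern,
#' flagged non-orderable, so downstream binning is total. Under the
#' multi-pattern scheme each gene gets its bootstrap frequency records
#' (frequency >= \code{config@fMin}, "no-pattern" mass excluded from the
#' rows, so per-gene frequencies sum to at most 1). Per-gene RNG streams
#' are derived from \code{config@seed} and the gene's position in the
#' experiment, making results reproducible and independent of gene
#' subsetting.
#'
#' @param experiment an \linkS4class{OrderExperiment}.
#' @param config an \linkS4class{AlgoConfig}.
#' @param scheme \code{"one_pattern"} or \code{"multi_pattern"}.
#' @param genes optional subset of gene identifiers (default all).
#' @return data.frame with one row per (gene, pattern) record: columns
#'   \code{gene}, \code{pattern_code}, \code{frequency},
#'   \code{alpha_used}, \code{orderable}, \code{method}.
#' @examples
#' sim <- simulateExperiment(nGenes = 4, delta = 6, seed = 7)
#' assignPatterns(sim$experiment, algoConfig(seed = 7))
#' @export
assignPatterns <- function(experiment, config = algoConfig(),
                           scheme = c("one_pattern", "multi_pattern"),
                           genes = NULL) {
    stopifnot(is(experiment, "OrderExperiment"), is(config, "AlgoConfig"))
    scheme <- match.arg(scheme)
    labels <- groupLabels(experiment)
    allGenes <- rownames(SummarizedExperiment::assay(experiment))
    if (is.null(genes))
        genes <- allGenes
    idx <- match(genes, allGenes)
    if (anyNA(idx))
        stop("unknown gene(s): ", paste(genes[is.na(idx)], collapse = ", "))
    rows <- vector("list", length(genes))
    for (g in seq_along(genes)) {
        samples <- geneSamples(experiment, genes[g])
        if (scheme == "one_pattern") {
            res <- searchOrderableFromPValues(pairPValues(samples), labels,
                                              config)
            if (is.null(res$pattern)) {
                P <- patternFixedAlpha(samples, config@alpha)
                rows[[g]] <- data.frame(gene = genes[g],
                    pattern_code = patternCode(P), frequency = 1,
                    alpha_used = config@alpha, orderable = FALSE,
                    method = "fixed-fallback", stringsAsFactors = FALSE)
            } else {
                rows[[g]] <- data.frame(gene = genes[g],
                    pattern_code = patternCode(res$pattern), frequency = 1,
                    alpha_used = res$alphaUsed, orderable = TRUE,
                    method = "varying", stringsAsFactors = FALSE)
            }
        } else {
            cfg <- config
            cfg@seed <- deriveSeed(config@seed, idx[g])
            pa <- multiplePatternsBootstrap(samples, cfg, gene = genes[g])
            rec <- patternRecords(pa, minFrequency = config@fMin)
            rec <- rec[!is.na(rec$pattern_code), , drop = FALSE]
            if (nrow(rec))
                rows[[g]] <- data.frame(gene = genes[g], rec,
                                        method = pa@method,
                                        stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(), pattern_code = character(),
                          frequency = numeric(), alpha_used = numeric(),
                          orderable = logical(), method = character(),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Bin genes by pattern label
#'
#' One cluster per distinct pattern code among the assignment records; a
#' gene with several patterns (multi-pattern scheme) is a member of every
#' corresponding bin.
#'
#' @param assignments data.frame from [assignPatterns()].
#' @param fMin drop records below this frequency before binning
#'   (default 0; [assignPatterns()] has usually filtered already).
#' @return named list: pattern code -> character vector of member genes.
#' @export
clusterByPattern <- function(assignments, fMin = 0) {
    rec <- assignments[!is.na(assignments$pattern_code) &
                       assignments$frequency >= fMin, , drop = FALSE]
    if (!nrow(rec))
        return(setNames(list(), character()))
    lapply(split(rec$gene, rec$pattern_code), unique)
}

#' Orderable-fraction and structural-distance summary curves
#'
#' For each cap a_max on the significance ladder, runs the
#' extension-mode ladder search per gene and reports the fraction of
#' genes acquiring a non-trivial orderable pattern, the mean structural
#' distance between each gene's base fixed-level pattern and the pattern
#' found (\code{mu_d1}, over genes with a successful search; 0 for genes
#' already orderable at the base level), and the same mean restricted to
#' genes not orderable at the base level (\code{mu_d2}). The fraction is
#' non-decreasing in a_max, and \code{mu_d2 >= mu_d1} whenever its
#' subset is non-empty; \code{mu_d2} is NA when every gene is orderable
#' at the base level.
#'
#' @param experiment an \linkS4class{OrderExperiment}.
#' @param alphaGrid increasing vector of ladder caps.
#' @param config an \linkS4class{AlgoConfig}; its \code{alpha} is the
#'   base level, its \code{alphaMax} is ignored in favour of the grid.
#' @param genes optional gene subset.
#' @return data.frame with columns \code{alpha_max},
#'   \code{fraction_orderable}, \code{mu_d1}, \code{mu_d2}.
#' @examples
#' sim <- simulateExperiment(nGenes = 6, delta = 2, seed = 3)
#' summaryCurves(sim$experiment, c(0.05, 0.15, 0.5))
#' @export
summaryCurves <- function(experiment, alphaGrid, config = algoConfig(),
                          genes = NULL) {
    stopifnot(is(experiment, "OrderExperiment"), is(config, "AlgoConfig"))
    if (is.unsorted(alphaGrid, strictly = TRUE))
        stop("alphaGrid must be strictly increasing")
    if (is.null(genes))
        genes <- rownames(SummarizedExperiment::assay(experiment))
    labels <- groupLabels(experiment)
    pvs <- lapply(genes, function(g)
        pairPValues(geneSamples(experiment, g)))
    basePats <- lapply(pvs, patternAtAlpha, labels = labels,
                       alpha = config@alpha)
    baseOrd <- vapply(basePats, function(P)
        strictCount(P) >= 1L && isOrderable(P, config@predicate),
        logical(1))
    out <- lapply(alphaGrid, function(aMax) {
        cfg <- config
        cfg@alphaMax <- aMax
        cfg@extensionMode <- TRUE
        found <- logical(length(genes))
        d <- rep(NA_real_, length(genes))
        for (g in seq_along(genes)) {
            res <- searchOrderableFromPValues(pvs[[g]], labels, cfg)
            if (!is.null(res$pattern)) {
                found[g] <- TRUE
                d[g] <- patternDistance(basePats[[g]], res$pattern)
            }
        }
        data.frame(alpha_max = aMax,
                   fraction_orderable = mean(found),
                   mu_d1 = if (any(found)) mean(d[found]) else NA_real_,
                   mu_d2 = if (any(found & !baseOrd))
                       mean(d[found & !baseOrd]) else NA_real_)
    })
    do.call(rbind, out)
}

#' Hierarchical-clustering baseline
#'
#' The conventional comparator: each gene is represented by its vector
#' of K per-group mean expressions, gene-gene distance is 1 - Pearson
#' correlation of these vectors, and an average-linkage agglomerative
#' tree is cut to exactly \code{nClusters} clusters. Genes whose mean
#' vector has zero variance have undefined correlation; such a gene is
#' placed at distance 0 from genes with an identical mean vector and at
#' the maximal distance 2 from all others.
#'
#' @param experiment an \linkS4class{OrderExperiment}.
#' @param nClusters number of clusters to cut the tree into.
#' @return named integer vector: gene -> cluster id (1..nClusters).
#' @export
hierarchicalBaseline <- function(experiment, nClusters) {
    stopifnot(is(experiment, "OrderExperiment"))
    mat <- SummarizedExperiment::assay(experiment)
    if (nClusters > nrow(mat))
        stop("nClusters exceeds the number of genes")
    grp <- SummarizedExperiment::colData(experiment)$group
    means <- t(apply(mat, 1L, function(v) tapply(v, grp, mean)))
    sds <- apply(means, 1L, sd)
    cc <- suppressWarnings(cor(t(means)))
    d <- 1 - cc
    degenerate <- which(sds == 0 | !is.finite(sds))
    if (length(degenerate)) {
        for (i in degenerate) {
            same <- apply(means, 1L, function(v)
                isTRUE(all.equal(v, means[i, ])))
            d[i, ] <- ifelse(same, 0, 2)
            d[, i] <- d[i, ]
        }
    }
    d[!is.finite(d)] <- 2
    diag(d) <- 0
    tree <- hclust(as.dist(d), method = "average")
    cutree(tree, k = nClusters)
}
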