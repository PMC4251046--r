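#' @import methods
#' @importFrom stats wilcox.test kruskal.test p.adjust cor hclust cutree
#'   as.dist rnorm setNames sd
#' @importFrom utils read.delim write.table combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' Pattern: ternary pairwise outcomes over a treatment set
#'
#' A \code{Pattern} assigns one ternary outcome to each of the
#' \eqn{K(K-1)/2} unordered pairs of treatment groups: the first group of
#' the pair responds less (\code{1}), the second responds less (\code{2}),
#' or the two are statistically indistinguishable (\code{0}, a tie).
#' Pairs are enumerated lexicographically by label position:
#' (t1,t2), (t1,t3), ..., (t1,tK), (t2,t3), ...; this fixed order also
#' defines the ternary string representation (see [patternCode()]).
#'
#' @slot labels character vector of K >= 2 distinct treatment labels; by
#'   convention the control group, when present, is the first label.
#' @slot relation integer vector of length \code{choose(K, 2)} with values
#'   in \code{0:2} (0 = tie, 1 = first-of-pair less, 2 = second-of-pair
#'   less), ordered as above.
#'
#' @seealso [Pattern()], [patternFromCode()], [isOrderable()],
#'   [patternDistance()]
#' @exportClass Pattern
setClass("Pattern",
    representation(labels = "character", relation = "integer"))

setValidity("Pattern", function(object) {
    k <- length(object@labels)
    msgs <- character()
    if (k < 2L)
        msgs <- c(msgs, "need at least 2 treatment labels")
    if (anyDuplicated(object@labels))
        msgs <- c(msgs, "treatment labels must be unique")
    np <- (k * (k - 1L)) %/% 2L
    if (length(object@relation) != np)
        msgs <- c(msgs, sprintf("relation must have length K(K-1)/2 = %d", np))
    if (anyNA(object@relation) || !all(object@relation %in% 0:2))
        msgs <- c(msgs, "relation values must be 0 (tie), 1 or 2 (strict)")
    if (length(msgs)) msgs else TRUE
})

#' Expression experiment bound to a treatment-group design
#'
#' \code{OrderExperiment} is a [SummarizedExperiment::SummarizedExperiment]
#' whose columns (samples) are partitioned into K >= 2 treatment groups of
#' at least 2 replicates each, recorded in \code{colData(x)$group}. Group
#' factor levels keep the order in which groups first appear in the design;
#' the first level is taken as the control group by convention.
#'
#' @seealso [OrderExperiment()], [loadExperiment()], [groupLabels()]
#' @exportClass OrderExperiment
setClass("OrderExperiment", contains = "SummarizedExperiment")

setValidity("OrderExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd))
        return("colData must contain a 'group' column")
    grp <- cd$group
    if (!is.factor(grp))
        return("colData 'group' must be a factor")
    if (anyNA(grp))
        return("every sample must be mapped to a treatment group")
    tab <- table(grp)
    if (length(tab) < 2L)
        return("need at least 2 treatment groups")
    if (any(tab < 2L))
        return(sprintf("every group needs >= 2 replicates; too few in: %s",
                       paste(names(tab)[tab < 2L], collapse = ", ")))
    TRUE
})

#' Configuration for the pattern-assignment algorithms
#'
#' Bundles the tuning parameters shared by the fixed-level pattern call,
#' the varying-level orderable-pattern search and the bootstrap
#' multi-pattern assignment.
#'
#' @slot alpha base significance level for pairwise outcomes (default 0.05).
#' @slot alphaMax cap on the candidate significance ladder (default 0.5).
#' @slot M number of bootstrap iterations (default 1000).
#' @slot innerMethod pattern call used inside the bootstrap: \code{"varying"}
#'   (ladder search) or \code{"fixed"} (base alpha).
#' @slot predicate orderability predicate: \code{"tie-consistent"},
#'   \code{"delta-free"} or \code{"weak-order"}.
#' @slot seed integer RNG seed (NA for unseeded).
#' @slot fMin minimum bootstrap frequency for a reported pattern record.
#' @slot extensionMode logical; restrict the ladder search to candidate
#'   levels at or above \code{alpha}, so the result is guaranteed to be an
#'   orderable extension of the base pattern.
#'
#' @seealso [algoConfig()]
#' @exportClass AlgoConfig
setClass("AlgoConfig",
    representation(alpha = "numeric", alphaMax = "numeric", M = "integer",
                   innerMethod = "character", predicate = "character",
                   seed = "integer", fMin = "numeric",
                   extensionMode = "logical"))

setValidity("AlgoConfig", function(object) {
    msgs <- character()
    if (!(object@alpha > 0 && object@alpha < 1))
        msgs <- c(msgs, "alpha must be in (0, 1)")
    if (object@alphaMax < object@alpha)
        msgs <- c(msgs, "alphaMax must be >= alpha")
    if (object@M < 1L)
        msgs <- c(msgs, "M must be >= 1")
    if (!(object@fMin >= 0 && object@fMin < 1))
        msgs <- c(msgs, "fMin must be in [0, 1)")
    if (!object@innerMethod %in% c("fixed", "varying"))
        msgs <- c(msgs, "innerMethod must be 'fixed' or 'varying'")
    if (!object@predicate %in% c("tie-consistent", "delta-free", "weak-order"))
        msgs <- c(msgs,
            "predicate must be 'tie-consistent', 'delta-free' or 'weak-order'")
    if (length(msgs)) msgs else TRUE
})

#' Per-gene pattern assignment with bootstrap frequencies
#'
#' Holds the (pattern, frequency, alpha-used) records produced for one gene,
#' either a single record with frequency 1 (base pattern already orderable,
#' or one-pattern scheme) or the full bootstrap frequency table. Rows whose
#' \code{pattern_code} is \code{NA} record the "no-pattern" mass: iterations
#' whose ladder search found no non-trivial orderable pattern. Frequencies
#' over all rows always sum to 1.
#'
#' @slot gene gene identifier.
#' @slot labels treatment labels the pattern codes refer to.
#' @slot records data.frame with columns \code{pattern_code} (ternary
#'   string or NA), \code{frequency}, \code{alpha_used}, \code{orderable}.
#' @slot method \code{"base"} (orderable short-circuit), \code{"bootstrap"},
#'   \code{"varying"} or \code{"fixed-fallback"}.
#'
#' @seealso [multiplePatternsBootstrap()], [patternRecords()]
#' @exportClass PatternAssignment
setClass("PatternAssignment",
    representation(gene = "character", labels = "character",
                   records = "data.frame", method = "character"))

setValidity("PatternAssignment", function(object) {
    req <- c("pattern_code", "frequency", "alpha_used", "orderable")
    if (!all(req %in% colnames(object@records)))
        return(sprintf("records must have columns: %s",
                       paste(req, collapse = ", ")))
    f <- object@records$frequency
    if (any(f < 0 | f > 1))
        return("frequencies must lie in [0, 1]")
    if (abs(sum(f) - 1) > 1e-9)
        return("frequencies must sum to 1")
    TRUE
})
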