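# Core pattern algebra: constructors, orderability predicates, extensions,
# the structural (Hamming) distance, ternary string codes, enumeration and
# tier extraction.

# canonical pair enumeration: (1,2),(1,3),...,(1,K),(2,3),...
pairIndices <- function(k) {
    stopifnot(k >= 2L)
    t(combn(k, 2L))
}

#' Construct a Pattern
#'
#' @param labels character vector of K >= 2 distinct treatment labels.
#' @param relation integer vector of length \code{choose(K, 2)} giving the
#'   outcome of each unordered pair in canonical order (see
#'   \linkS4class{Pattern}): 0 = tie, 1 = first-of-pair less, 2 =
#'   second-of-pair less.
#' @return A \linkS4class{Pattern}.
#' @examples
#' # A ~ B, A < C, B < C on three treatments
#' Pattern(c("A", "B", "C"), c(0L, 1L, 1L))
#' @export
Pattern <- function(labels, relation) {
    new("Pattern", labels = as.character(labels),
        relation = as.integer(relation))
}

#' Construct a Pattern from named pair outcomes
#'
#' Convenience constructor mirroring the JSON serialisation: outcomes are
#' named \code{"X|Y"} with X before Y in label order, and take values
#' \code{"lt"} (X responds less), \code{"gt"} (Y responds less) or
#' \code{"tie"}. Unnamed pairs default to ties.
#'
#' @param labels treatment labels.
#' @param outcomes named character vector, e.g.
#'   \code{c("A|C" = "lt", "A|B" = "tie")}.
#' @return A \linkS4class{Pattern}.
#' @examples
#' patternFromOutcomes(c("A", "B", "C"), c("A|C" = "lt"))
#' @export
patternFromOutcomes <- function(labels, outcomes = character()) {
    k <- length(labels)
    pi <- pairIndices(k)
    rel <- integer(nrow(pi))
    if (length(outcomes)) {
        if (is.null(names(outcomes)))
            stop("outcomes must be named 'X|Y'")
        keys <- paste(labels[pi[, 1L]], labels[pi[, 2L]], sep = "|")
        revkeys <- paste(labels[pi[, 2L]], labels[pi[, 1L]], sep = "|")
        for (nm in names(outcomes)) {
            i <- match(nm, keys)
            flip <- FALSE
            if (is.na(i)) {
                i <- match(nm, revkeys)
                flip <- TRUE
            }
            if (is.na(i))
                stop("unknown pair: ", nm)
            val <- match.arg(outcomes[[nm]], c("tie", "lt", "gt"))
            code <- c(tie = 0L, lt = 1L, gt = 2L)[[val]]
            if (flip && code != 0L)
                code <- 3L - code
            rel[i] <- code
        }
    }
    Pattern(labels, rel)
}

#' @rdname patternCode
#' @export
setGeneric("patternCode", function(object) standardGeneric("patternCode"))

#' Ternary string code of a Pattern
#'
#' Serialises a pattern as a string of \code{K(K-1)/2} ternary digits in
#' canonical pair order; digit 0 = tie, 1 = first-of-pair responds less,
#' 2 = second-of-pair responds less. \code{patternFromCode()} inverts it.
#'
#' @param object a \linkS4class{Pattern}.
#' @return A single string, e.g. \code{"011110"} for K = 4.
#' @examples
#' p <- patternFromOutcomes(LETTERS[1:4],
#'     c("A|C" = "lt", "A|D" = "lt", "B|C" = "lt", "B|D" = "lt"))
#' patternCode(p)                     # "011110"
#' patternFromCode("011110", LETTERS[1:4])
#' @aliases patternCode
#' @export
setMethod("patternCode", "Pattern", function(object) {
    paste(object@relation, collapse = "")
})

#' @rdname patternCode
#' @param code ternary digit string of length \code{choose(K, 2)}.
#' @param labels treatment labels the code refers to.
#' @export
patternFromCode <- function(code, labels) {
    k <- length(labels)
    np <- (k * (k - 1L)) %/% 2L
    digits <- strsplit(code, "", fixed = TRUE)[[1L]]
    if (length(digits) != np)
        stop(sprintf("code must have %d digits for %d treatments, got %d",
                     np, k, length(digits)))
    rel <- match(digits, c("0", "1", "2")) - 1L
    if (anyNA(rel))
        stop("code may only contain digits 0, 1, 2")
    Pattern(labels, rel)
}

#' @rdname treatmentLabels
#' @export
setGeneric("treatmentLabels",
    function(object) standardGeneric("treatmentLabels"))

#' Treatment labels of a Pattern
#' @param object a \linkS4class{Pattern}.
#' @return Character vector of treatment labels in canonical order.
#' @aliases treatmentLabels
#' @export
setMethod("treatmentLabels", "Pattern", function(object) object@labels)

setMethod("show", "Pattern", function(object) {
    k <- length(object@labels)
    cat(sprintf("Pattern on %d treatments (%s), code %s\n",
                k, paste(object@labels, collapse = ", "),
                patternCode(object)))
    tiers <- patternTiers(object)
    if (is.null(tiers)) {
        cat("  not realizable as a weak order\n")
    } else {
        cat("  tiers (low -> high):",
            paste(vapply(tiers, paste, "", collapse = ","),
                  collapse = " < "), "\n")
    }
})

# K x K signed relation matrix: m[i,j] = 1 iff t_i responds less than t_j.
relationMatrix <- function(P) {
    k <- length(P@labels)
    m <- matrix(0L, k, k)
    pi <- pairIndices(k)
    for (r in seq_len(nrow(pi))) {
        i <- pi[r, 1L]; j <- pi[r, 2L]
        if (P@relation[r] == 1L) {
            m[i, j] <- 1L
        } else if (P@relation[r] == 2L) {
            m[j, i] <- 1L
        }
    }
    m
}

#' Does a pattern contain the forbidden triple?
#'
#' The forbidden triple is the sub-pattern \{x < z, x ~ y, y ~ z\} on three
#' distinct treatments: two ties through a shared middle treatment y
#' bridging a strict outcome. Under the working assumptions (ties reflect
#' true equivalence, and equivalence is transitive) such a sub-pattern
#' cannot be a true response order, so its presence marks the observed
#' pattern as an artifact of insufficient sampling. All role assignments
#' within every triple are checked.
#'
#' @param P a \linkS4class{Pattern}.
#' @return \code{TRUE} if some triple of treatments carries the forbidden
#'   sub-pattern.
#' @examples
#' containsForbiddenTriple(
#'     patternFromOutcomes(c("A", "B", "C"), c("A|C" = "lt")))  # TRUE
#' @export
containsForbiddenTriple <- function(P) {
    stopifnot(is(P, "Pattern"))
    m <- relationMatrix(P)
    k <- nrow(m)
    tie <- m == 0L & t(m) == 0L
    diag(tie) <- FALSE
    for (y in seq_len(k)) {
        mates <- which(tie[y, ])
        if (length(mates) < 2L)
            next
        for (a in seq_len(length(mates) - 1L)) {
            for (b in seq(a + 1L, length(mates))) {
                x <- mates[a]; z <- mates[b]
                if (m[x, z] == 1L || m[z, x] == 1L)
                    return(TRUE)
            }
        }
    }
    FALSE
}

# G(t) = treatments t responds less than; L(t) = treatments responding less
# than t.
greaterSets <- function(m) lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1L))
lesserSets  <- function(m) lapply(seq_len(nrow(m)), function(i) which(m[, i] == 1L))

#' Tied-pair set-consistency orderability
#'
#' A pattern is orderable in the formal sense when every tied pair of
#' treatments (t_i ~ t_j) has identical strictly-greater sets
#' G(t) = \{u : t < u\} and identical strictly-smaller sets
#' L(t) = \{u : u < t\}. Ties then behave as a congruence with respect to
#' the strict outcomes. Note this does not exclude strict cycles (a
#' 3-cycle with no ties passes vacuously); use the \code{"weak-order"}
#' predicate of [isOrderable()] when cycles must be rejected.
#'
#' @param P a \linkS4class{Pattern}.
#' @return logical.
#' @examples
#' isTieConsistent(
#'     patternFromOutcomes(c("A", "B", "C"), c("A|C" = "lt")))  # FALSE
#' @export
isTieConsistent <- function(P) {
    stopifnot(is(P, "Pattern"))
    m <- relationMatrix(P)
    k <- nrow(m)
    G <- greaterSets(m)
    L <- lesserSets(m)
    pi <- pairIndices(k)
    for (r in seq_len(nrow(pi))) {
        if (P@relation[r] == 0L) {
            i <- pi[r, 1L]; j <- pi[r, 2L]
            if (!(setequal(G[[i]], G[[j]]) && setequal(L[[i]], L[[j]])))
                return(FALSE)
        }
    }
    TRUE
}

#' Is a pattern realizable as a weak order?
#'
#' Tests whether an integer ranking r of the treatments exists with
#' t_i < t_j exactly when r(t_i) < r(t_j) and t_i ~ t_j exactly when the
#' ranks are equal — i.e. whether the pattern is an ordered partition
#' (tiers) of the treatments. The candidate ranking r(t) = |L(t)| (the
#' number of treatments strictly below t) is constructed and verified
#' against every pair; for a genuine weak order this ranking is the unique
#' dense tier assignment.
#'
#' @param P a \linkS4class{Pattern}.
#' @return logical.
#' @examples
#' isWeakOrder(patternFromCode("111", c("A", "B", "C")))  # chain: TRUE
#' isWeakOrder(patternFromCode("112", c("A", "B", "C")))  # 3-cycle: FALSE
#' @export
isWeakOrder <- function(P) {
    stopifnot(is(P, "Pattern"))
    !is.null(weakOrderRanks(P))
}

# Integer ranks realizing P as a weak order, or NULL.
weakOrderRanks <- function(P) {
    m <- relationMatrix(P)
    k <- nrow(m)
    r <- vapply(seq_len(k), function(i) sum(m[, i] == 1L), 0L)
    pi <- pairIndices(k)
    for (row in seq_len(nrow(pi))) {
        i <- pi[row, 1L]; j <- pi[row, 2L]
        ok <- switch(as.character(P@relation[row]),
            "0" = r[i] == r[j],
            "1" = r[i] < r[j],
            "2" = r[j] < r[i])
        if (!ok)
            return(NULL)
    }
    r
}

#' Orderability of a pattern
#'
#' Dispatches to one of three predicates, from weakest to strongest:
#' \describe{
#'   \item{\code{"delta-free"}}{no forbidden triple
#'     (![containsForbiddenTriple()]).}
#'   \item{\code{"tie-consistent"}}{the default and the formal definition:
#'     tied treatments share strictly-greater and strictly-smaller sets
#'     ([isTieConsistent()]).}
#'   \item{\code{"weak-order"}}{realizable as ordered tiers
#'     ([isWeakOrder()]).}
#' }
#' Every weak order is tie-consistent and every tie-consistent pattern is
#' delta-free, but neither converse holds: \{A<B, B<C, A~C\} is delta-free
#' yet not tie-consistent, and a strict 3-cycle is tie-consistent
#' (vacuously) yet no weak order.
#'
#' @param P a \linkS4class{Pattern}.
#' @param predicate which predicate to apply.
#' @return logical.
#' @examples
#' p <- patternFromOutcomes(c("A", "B", "C"),
#'                          c("A|B" = "lt", "B|C" = "lt"))
#' isOrderable(p, "delta-free")      # TRUE
#' isOrderable(p)                    # tie-consistent: FALSE
#' @export
isOrderable <- function(P,
        predicate = c("tie-consistent", "delta-free", "weak-order")) {
    predicate <- match.arg(predicate)
    switch(predicate,
        "tie-consistent" = isTieConsistent(P),
        "delta-free" = !containsForbiddenTriple(P),
        "weak-order" = isWeakOrder(P))
}

#' Number of strict outcomes in a pattern
#'
#' A pattern with no strict outcome (all ties) is "trivial": orderable but
#' uninformative, and never returned by the ladder search.
#'
#' @param P a \linkS4class{Pattern}.
#' @return integer count of non-tie pairs.
#' @export
strictCount <- function(P) {
    stopifnot(is(P, "Pattern"))
    sum(P@relation != 0L)
}

#' Is Q an orderable extension of P?
#'
#' Q extends P when Q is orderable (under the chosen predicate) and every
#' strict outcome of P appears in Q with the same direction; Q may resolve
#' ties of P into strict outcomes but may not flip or drop a strict
#' outcome. True response orders of genes whose observed strict outcomes
#' are correct must be orderable extensions of the observed pattern.
#'
#' @param P observed \linkS4class{Pattern}.
#' @param Q candidate extension on the same treatment set.
#' @param predicate orderability predicate applied to Q.
#' @return logical.
#' @examples
#' P <- patternFromOutcomes(c("A", "B", "C"), c("A|C" = "lt"))
#' Q <- patternFromOutcomes(c("A", "B", "C"),
#'                          c("A|C" = "lt", "B|C" = "lt"))
#' isOrderableExtension(P, Q)   # TRUE
#' @export
isOrderableExtension <- function(P, Q,
        predicate = c("tie-consistent", "delta-free", "weak-order")) {
    stopifnot(is(P, "Pattern"), is(Q, "Pattern"))
    if (!identical(P@labels, Q@labels))
        stop("patterns are defined on different treatment sets")
    predicate <- match.arg(predicate)
    if (!isOrderable(Q, predicate))
        return(FALSE)
    strict <- P@relation != 0L
    all(Q@relation[strict] == P@relation[strict])
}

#' Structural distance between two patterns
#'
#' The Hamming count of unordered treatment pairs on which the two
#' patterns disagree. Direction matters: a pair resolved A < B in one
#' pattern and B < A in the other counts as different, as does strict
#' versus tie.
#'
#' @param P,Q \linkS4class{Pattern}s on the same treatment set.
#' @return Non-negative integer.
#' @examples
#' patternDistance(patternFromCode("000", c("A", "B", "C")),
#'                 patternFromCode("110", c("A", "B", "C")))  # 2
#' @export
patternDistance <- function(P, Q) {
    stopifnot(is(P, "Pattern"), is(Q, "Pattern"))
    if (!identical(P@labels, Q@labels))
        stop("patterns are defined on different treatment sets")
    sum(P@relation != Q@relation)
}

#' Enumerate all patterns on a treatment set
#'
#' Yields all \eqn{3^{K(K-1)/2}} patterns exactly once. Guarded to K <= 5
#' (59049 patterns); intended as an exhaustive oracle for the predicate
#' algebra, not for large K.
#'
#' @param labels treatment labels (K <= 5).
#' @return List of \linkS4class{Pattern}s.
#' @examples
#' length(enumeratePatterns(c("A", "B")))   # 3
#' @export
enumeratePatterns <- function(labels) {
    k <- length(labels)
    if (k > 5L)
        stop("enumeration is limited to K <= 5 treatments")
    np <- (k * (k - 1L)) %/% 2L
    n <- 3L^np
    out <- vector("list", n)
    rel <- integer(np)
    for (idx in seq_len(n)) {
        v <- idx - 1L
        for (d in np:1) {
            rel[d] <- v %% 3L
            v <- v %/% 3L
        }
        out[[idx]] <- Pattern(labels, rel)
    }
    out
}

#' Ordered tiers of a weak-order pattern
#'
#' When the pattern is realizable as a weak order, returns its unique
#' ordered partition: a list of tiers (character vectors of tied
#' treatments) from smallest to largest response. For patterns that are
#' not weak orders, returns \code{NULL} rather than erroring, so callers
#' can treat non-orderability as a value.
#'
#' @param P a \linkS4class{Pattern}.
#' @return List of character vectors, or \code{NULL}.
#' @examples
#' patternTiers(patternFromCode("011110", LETTERS[1:4]))
#' # list(c("A","B"), c("C","D"))
#' @export
patternTiers <- function(P) {
    stopifnot(is(P, "Pattern"))
    r <- weakOrderRanks(P)
    if (is.null(r))
        return(NULL)
    lapply(sort(unique(r)), function(v) P@labels[r == v])
}

#' Build the pattern of a planted weak order
#'
#' Inverse of [patternTiers()]: given ordered tiers (smallest response
#' first) over a treatment set, produces the corresponding weak-order
#' pattern.
#'
#' @param tiers list of character vectors partitioning \code{labels}.
#' @param labels treatment labels in canonical order.
#' @return A \linkS4class{Pattern}.
#' @examples
#' tiersToPattern(list(c("A", "B"), c("C", "D")), LETTERS[1:4])
#' @export
tiersToPattern <- function(tiers, labels) {
    rank <- setNames(rep(NA_integer_, length(labels)), labels)
    for (t in seq_along(tiers))
        rank[tiers[[t]]] <- t
    if (anyNA(rank))
        stop("tiers must partition all treatment labels")
    if (sum(lengths(tiers)) != length(labels))
        stop("tiers must partition all treatment labels")
    pi <- pairIndices(length(labels))
    rel <- integer(nrow(pi))
    for (r in seq_len(nrow(pi))) {
        ri <- rank[[pi[r, 1L]]]; rj <- rank[[pi[r, 2L]]]
        rel[r] <- if (ri < rj) 1L else if (ri > rj) 2L else 0L
    }
    Pattern(labels, rel)
}

#' JSON-friendly representation of a pattern
#'
#' @param P a \linkS4class{Pattern}.
#' @return A list with elements \code{labels} and \code{outcomes} (named
#'   \code{"X|Y"} with values \code{"lt"}, \code{"gt"}, \code{"tie"}),
#'   suitable for [jsonlite::toJSON()].
#' @export
patternToList <- function(P) {
    stopifnot(is(P, "Pattern"))
    pi <- pairIndices(length(P@labels))
    keys <- paste(P@labels[pi[, 1L]], P@labels[pi[, 2L]], sep = "|")
    vals <- c("tie", "lt", "gt")[P@relation + 1L]
    list(labels = P@labels, outcomes = as.list(setNames(vals, keys)))
}
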