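# Independent oracles used to cross-check the implementation. These are
# deliberately written against the ternary code string (not the package's
# relation-matrix internals) and by brute force, so they share no code
# path with the functions they verify.

# outcome of pair (i, j), i < j, read straight off the code string:
# 0 tie, 1 i-less, 2 j-less
oracleOutcome <- function(code, k, i, j) {
    stopifnot(i < j)
    pos <- 0L
    for (a in seq_len(k - 1L)) {
        for (b in seq(a + 1L, k)) {
            pos <- pos + 1L
            if (a == i && b == j)
                return(as.integer(substr(code, pos, pos)))
        }
    }
    stop("pair not found")
}

# signed comparison usable for unordered queries: does x respond less
# than z under the pattern?
oracleLess <- function(code, k, x, z) {
    if (x < z) oracleOutcome(code, k, x, z) == 1L
    else oracleOutcome(code, k, z, x) == 2L
}

oracleTied <- function(code, k, x, z) {
    if (x < z) oracleOutcome(code, k, x, z) == 0L
    else oracleOutcome(code, k, z, x) == 0L
}

# naive forbidden-triple scan: all ordered role assignments (x, y, z)
# over all triples
oracleContainsDelta <- function(code, k) {
    for (x in seq_len(k)) for (y in seq_len(k)) for (z in seq_len(k)) {
        if (x == y || y == z || x == z) next
        if (oracleLess(code, k, x, z) && oracleTied(code, k, x, y) &&
            oracleTied(code, k, y, z))
            return(TRUE)
    }
    FALSE
}

# exhaustive ranking search: does any ranking in {1..k}^k realize the
# pattern as a weak order?
oracleWeakOrder <- function(code, k) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    for (r in seq_len(nrow(grid))) {
        rk <- grid[r, ]
        ok <- TRUE
        for (i in seq_len(k - 1L)) {
            for (j in seq(i + 1L, k)) {
                o <- oracleOutcome(code, k, i, j)
                good <- switch(o + 1L, rk[i] == rk[j], rk[i] < rk[j],
                               rk[j] < rk[i])
                if (!good) { ok <- FALSE; break }
            }
            if (!ok) break
        }
        if (ok) return(TRUE)
    }
    FALSE
}

# exact one-sided rank-sum p-value by full enumeration of rank splits:
# P(W_x <= w_obs) over all C(m+n, m) assignments of the pooled ranks to
# group x, for the alternative mu_x < mu_y (small x ranks support it)
oracleWilcoxLess <- function(x, y) {
    m <- length(x)
    pooled <- c(x, y)
    stopifnot(!anyDuplicated(pooled))
    r <- rank(pooled)
    wObs <- sum(r[seq_len(m)])
    splits <- combn(length(pooled), m)
    w <- apply(splits, 2L, function(ix) sum(r[ix]))
    mean(w <= wObs)
}

# ordered-set-partition (Fubini) numbers by the standard recurrence
# a(n) = sum_{k=1..n} C(n,k) a(n-k), a(0) = 1
fubini <- function(n) {
    a <- numeric(n + 1L)
    a[1L] <- 1
    for (m in seq_len(n))
        a[m + 1L] <- sum(choose(m, seq_len(m)) * a[seq(m, 1L)])
    a[n + 1L]
}

# the six directional p-values of the four-treatment worked example, as a
# pair table in canonical order
workedExamplePv <- function() {
    pl <- c(0.45, 0.03, 0.055, 0.03, 0.03, 0.45)
    data.frame(first = c("A", "A", "A", "B", "B", "C"),
               second = c("B", "C", "D", "C", "D", "D"),
               p_less = pl, p_greater = 1 - pl + 0.01,
               stringsAsFactors = FALSE)
}

randomPattern <- function(labels) {
    np <- choose(length(labels), 2L)
    Pattern(labels, sample(0:2, np, replace = TRUE))
}
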