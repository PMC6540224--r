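# Independent brute-force oracles: deliberately naive implementations that
# share no code with the package internals.

# enrichment factor by explicit counting over the top s rows
oracleEf <- function(scores, labels, ids, fraction) {
    ord <- order(-scores, ids, method = "radix")
    n <- length(scores)
    s <- ceiling(fraction * n)
    a <- sum(labels == 1)
    af <- sum(labels[ord][seq_len(s)] == 1)
    (af / s) / (a / n)
}

# AUC by exhaustive pairwise comparison (wins + half ties over A*D pairs)
oracleAuc <- function(scores, labels) {
    act <- scores[labels == 1]
    dec <- scores[labels == 0]
    cmp <- outer(act, dec, function(a, d) (a > d) + 0.5 * (a == d))
    mean(cmp)
}

# quality from explicitly counted active ranks
oracleQuality <- function(scores, labels, ids, C) {
    ord <- order(-scores, ids, method = "radix")
    rk <- which(labels[ord] == 1)
    sum(rk <= C) + (1 - mean(rk) / length(scores))
}

# textbook sample skewness of active rank values
oracleSkewness <- function(scores, labels, ids) {
    ord <- order(-scores, ids, method = "radix")
    rk <- which(labels[ord] == 1)
    m <- mean(rk)
    mean((rk - m)^3) / mean((rk - m)^2)^1.5
}

# small random labeled score table; continuous scores, no ties
randomTable <- function(seed, nMax = 200) {
    set.seed(seed)
    n <- sample(10:nMax, 1)
    a <- sample(seq_len(max(1, floor(n / 3))), 1)
    labels <- integer(n)
    labels[sample.int(n, a)] <- 1L
    scores <- cbind(s1 = stats::rnorm(n), s2 = stats::rnorm(n))
    ScoreTable(sprintf("m%04d", seq_len(n)), labels, scores,
               source = "random fixture")
}

# exhaustive two-orientation check for single-score models
oracleBestOrientation <- function(table, column, C) {
    x <- scoreMatrix(table)[, column]
    z <- (x - mean(x)) / sd(x)
    labels <- activityLabels(table)
    ids <- moleculeIds(table)
    cs <- min(C, nMolecules(table))
    qp <- oracleQuality(z, labels, ids, cs)
    qm <- oracleQuality(-z, labels, ids, cs)
    if (qm > qp) list(coef = -1, q = qm) else list(coef = 1, q = qp)
}

# dense direction grids for brute-force coefficient optima
gridDirections <- function(k, n2 = 360L, n3 = 1000L) {
    if (k == 2) {
        th <- seq(0, 2 * pi, length.out = n2 + 1L)[-(n2 + 1L)]
        rbind(cos(th), sin(th))
    } else {
        i <- seq_len(n3)
        phi <- acos(1 - 2 * (i - 0.5) / n3)
        theta <- pi * (1 + sqrt(5)) * i
        d <- rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
        cbind(d, -d)
    }
}

# brute-force best unit direction for the quality function on standardized
# subset columns (independent of the package optimizer)
gridBestDirection <- function(table, subset, C) {
    x <- scoreMatrix(table)[, subset, drop = FALSE]
    z <- scale(x)
    labels <- activityLabels(table)
    ids <- moleculeIds(table)
    cs <- min(C, nMolecules(table))
    dirs <- gridDirections(length(subset))
    comb <- z %*% dirs
    qs <- vapply(seq_len(ncol(dirs)), function(j) {
        oracleQuality(comb[, j], labels, ids, cs)
    }, numeric(1))
    list(direction = dirs[, which.max(qs)], q = max(qs))
}

absCosine <- function(a, b) {
    abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# scaled-down search settings used for end-to-end screens in tests
testSearchConfig <- function(k, seed, clusterSize = 100) {
    searchConfig(clusterSize = clusterSize, nStarts = 4, maxIter = 400,
                 rmsTol = 0.01, k = k, seed = seed)
}
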