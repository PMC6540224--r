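#' Rank molecules by a combined score
#'
#' Higher combined score = better (energy-like lower-is-better scores are
#' handled upstream by coefficient signs). Ties are broken by lexicographic
#' molecule id (C locale) so that every ranking is reproducible; tie groups
#' are recorded so downstream selections can warn when a tie straddles a
#' selection boundary.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param combinedScore numeric vector, one finite value per molecule.
#' @return A \linkS4class{Ranking}.
#' @export
rankMolecules <- function(table, combinedScore) {
    stopifnot(is(table, "ScoreTable"))
    n <- nMolecules(table)
    if (length(combinedScore) != n) {
        stop("combinedScore length (", length(combinedScore),
             ") != number of molecules (", n, ")")
    }
    if (any(!is.finite(combinedScore))) {
        stop("combined score contains non-finite values")
    }
    ids <- moleculeIds(table)
    ord <- order(-combinedScore, ids, method = "radix")
    tg <- list()
    dupVals <- unique(combinedScore[duplicated(combinedScore)])
    for (v in dupVals) tg[[length(tg) + 1L]] <- sort(ids[combinedScore == v])
    new("Ranking", orderedIds = ids[ord], order = as.integer(ord),
        tieGroups = tg)
}

setMethod("show", "Ranking", function(object) {
    cat("Ranking of", length(object@orderedIds), "molecules;",
        length(object@tieGroups), "tie group(s)\n")
    cat("  top:", paste(utils::head(object@orderedIds, 5L), collapse = ", "), "\n")
})

.rankedLabels <- function(ranking, labels) {
    stopifnot(is(ranking, "Ranking"))
    labels[ranking@order]
}

.checkClasses <- function(labels) {
    if (sum(labels == 1L) < 1L) stop("no actives: metrics are undefined")
    if (sum(labels == 0L) < 1L) stop("no decoys: metrics are undefined")
}

#' Enrichment factor at a ranking fraction
#'
#' EF(f) = (a/s) / (A/N) where s = ceiling(f * N) molecules are selected from
#' the top of the ranking and a of them are active; EF = 1 for a random
#' ranking, and is capped at (min(s, A)/s) * (N/A) for a perfect one. A
#' warning is raised when a tie group straddles the selection boundary, since
#' the count then depends on the lexicographic tie-break.
#'
#' @param ranking a \linkS4class{Ranking}.
#' @param labels 0/1 labels in the original table row order.
#' @param fraction selection fraction in (0, 1].
#' @return A one-row data.frame with \code{fraction}, \code{selected},
#'   \code{actives} and \code{ef}.
#' @export
enrichmentFactor <- function(ranking, labels, fraction) {
    stopifnot(fraction > 0, fraction <= 1)
    labels <- as.integer(labels)
    .checkClasses(labels)
    rl <- .rankedLabels(ranking, labels)
    n <- length(rl)
    a <- sum(labels == 1L)
    s <- as.integer(ceiling(fraction * n))
    if (length(ranking@tieGroups) && s < n) {
        # a tie straddles the boundary if selected and unselected ids share a group
        sel <- ranking@orderedIds[seq_len(s)]
        for (g in ranking@tieGroups) {
            ns <- sum(g %in% sel)
            if (ns > 0L && ns < length(g)) {
                warning("tie group straddles the ", fraction * 100,
                        "% selection boundary; count follows the ",
                        "lexicographic id tie-break")
                break
            }
        }
    }
    af <- sum(rl[seq_len(s)] == 1L)
    data.frame(fraction = fraction, selected = s, actives = af,
               ef = (af / s) / (a / n))
}

#' Enrichment profile at the standard fractions
#'
#' @inheritParams enrichmentFactor
#' @param fractions numeric vector of ranking fractions.
#' @return data.frame with one row per fraction (columns as in
#'   \code{\link{enrichmentFactor}}) and attributes \code{N} and \code{A}.
#' @export
enrichmentProfile <- function(ranking, labels,
                              fractions = c(0.01, 0.02, 0.05, 0.10, 0.20)) {
    out <- do.call(rbind, lapply(fractions, function(f) {
        enrichmentFactor(ranking, labels, f)
    }))
    attr(out, "N") <- length(labels)
    attr(out, "A") <- sum(as.integer(labels) == 1L)
    out
}

#' ROC AUC by the rank-sum statistic
#'
#' Computed as the Mann-Whitney statistic with half credit for ties
#' (equivalent to the trapezoidal area under the ROC curve with tied scores
#' pooled), so it needs no tie-break rule.
#'
#' @param scores numeric combined scores (higher = more likely active), or a
#'   \linkS4class{Ranking} (then positions are used, reversed so that rank 1
#'   scores highest; tie information is lost, so prefer raw scores when ties
#'   matter).
#' @param labels 0/1 labels in the original table row order.
#' @return AUC in [0, 1]; 0.5 = random, 1 = perfect.
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    .checkClasses(labels)
    if (is(scores, "Ranking")) {
        s <- numeric(length(labels))
        s[scores@order] <- rev(seq_along(labels))
    } else {
        s <- as.numeric(scores)
        if (any(!is.finite(s))) stop("scores contain non-finite values")
    }
    a <- sum(labels == 1L)
    d <- length(labels) - a
    r <- rank(s, ties.method = "average")
    (sum(r[labels == 1L]) - a * (a + 1) / 2) / (a * d)
}

#' Active-rank asymmetry diagnostics
#'
#' Summarizes where the actives sit in the ranking: the mean normalized
#' active rank (small = actives concentrated at the top) and the sample
#' skewness of the active rank values (reported only for 3 or more actives;
#' positive = a long tail of poorly ranked actives).
#'
#' @inheritParams enrichmentFactor
#' @return list with \code{meanNormRank} and \code{skewness} (NA when fewer
#'   than 3 actives, or when active ranks have zero spread).
#' @export
rankAsymmetry <- function(ranking, labels) {
    labels <- as.integer(labels)
    if (sum(labels == 1L) < 1L) stop("no actives: asymmetry is undefined")
    rl <- .rankedLabels(ranking, labels)
    rk <- which(rl == 1L)
    n <- length(rl)
    skew <- NA_real_
    if (length(rk) >= 3L) {
        m <- mean(rk)
        m2 <- mean((rk - m)^2)
        if (m2 > 0) skew <- mean((rk - m)^3) / m2^1.5
    }
    list(meanNormRank = mean(rk) / n, skewness = skew)
}

#' Cluster-based quality of a ranking
#'
#' The cost function maximized by the consensus search:
#' Q = a_C + (1 - rbar/N), where a_C is the number of actives among the top C
#' molecules ("the cluster") and rbar the mean active rank. The whole-ranking
#' term lies in [0, 1), so the cluster count dominates lexicographically and
#' the distribution term breaks ties among models with equal early
#' recognition.
#'
#' @inheritParams enrichmentFactor
#' @param clusterSize C, the number of top-ranked molecules counted;
#'   capped at N.
#' @return list with \code{q}, \code{clusterActives} and \code{meanNormRank}.
#' @export
qualityScore <- function(ranking, labels, clusterSize = 100L) {
    labels <- as.integer(labels)
    .checkClasses(labels)
    n <- length(labels)
    cs <- min(as.integer(clusterSize), n)
    if (cs < 1L) stop("clusterSize must be >= 1")
    rl <- .rankedLabels(ranking, labels)
    rk <- which(rl == 1L)
    aC <- sum(rk <= cs)
    rbar <- mean(rk)
    list(q = aC + (1 - rbar / n), clusterActives = aC, meanNormRank = rbar / n)
}
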