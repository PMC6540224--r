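VIF_SENTINEL <- 1e6

#' Variance inflation factors of score columns
#'
#' VIF_i = 1 / (1 - R_i^2), with R_i^2 from an ordinary least-squares fit of
#' standardized column i on the other standardized columns. Perfectly
#' collinear columns get the serializable sentinel value 1e6 instead of
#' infinity. VIF is computed on the whole table: redundancy is a property of
#' the score set, not of a training split.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param columns score columns to assess (default: all); at least 2, none
#'   constant.
#' @return named numeric vector of VIF values.
#' @export
computeVif <- function(table, columns = scoreNames(table)) {
    stopifnot(is(table, "ScoreTable"))
    x <- scoreMatrix(table)[, columns, drop = FALSE]
    if (ncol(x) < 2L) stop("VIF needs at least 2 columns")
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
        stop("constant score column(s): ",
             paste(columns[sds == 0], collapse = ", "))
    }
    z <- scale(x)
    n <- nrow(z)
    vif <- vapply(seq_len(ncol(z)), function(i) {
        fit <- stats::lm.fit(cbind(1, z[, -i, drop = FALSE]), z[, i])
        rss <- sum(fit$residuals^2)
        tss <- n - 1 # standardized response
        r2 <- 1 - rss / tss
        if (r2 >= 1 - 1e-10) VIF_SENTINEL else min(1 / (1 - r2), VIF_SENTINEL)
    }, numeric(1))
    names(vif) <- columns
    vif
}

#' Iteratively remove interrelated score columns by VIF
#'
#' Greedy elimination: while any column has VIF above the threshold, remove
#' the worst one and recompute. Exact VIF ties (e.g. a duplicated pair, both
#' at the collinearity sentinel) are resolved by removing the member with the
#' lower single-score EF5%, then the lexicographically later name, so the
#' removal sequence is reproducible.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param columns candidate score columns.
#' @param threshold VIF above which a column is considered interrelated.
#' @param singleEfs named numeric vector of per-column best single-score EF
#'   at the top 5\% (see \code{\link{effectivenessFilter}}), used only for
#'   tie-breaking.
#' @return list with \code{surviving} (character), \code{removed}
#'   (data.frame: column, vif at removal) and \code{vif} (final VIF values,
#'   or per-column 1.0 when a single column survives).
#' @export
vifFilter <- function(table, columns = scoreNames(table), threshold = 5,
                      singleEfs = NULL) {
    stopifnot(is(table, "ScoreTable"))
    if (is.null(singleEfs)) singleEfs <- singleScoreEf(table, columns)
    keep <- columns
    removed <- data.frame(column = character(), vif = numeric())
    while (length(keep) >= 2L) {
        vif <- computeVif(table, keep)
        worst <- max(vif)
        if (worst <= threshold) break
        cand <- names(vif)[vif >= worst * (1 - 1e-9)]
        if (length(cand) > 1L) {
            efs <- singleEfs[cand]
            cand <- cand[efs <= min(efs) + 1e-12]
            cand <- sort(cand, decreasing = TRUE)
        }
        drop <- cand[1L]
        removed <- rbind(removed, data.frame(column = drop, vif = unname(vif[drop])))
        keep <- setdiff(keep, drop)
    }
    finalVif <- if (length(keep) >= 2L) computeVif(table, keep) else
        stats::setNames(rep(1, length(keep)), keep)
    list(surviving = keep, removed = removed, vif = finalVif)
}

#' Best single-score enrichment factor per column
#'
#' For each column, the EF at the given top fraction is computed ranking by
#' the column itself and by its negation (the orientation of an unfamiliar
#' score is unknown: energy-like functions are better when more negative);
#' the larger of the two is returned.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param columns score columns to evaluate.
#' @param fraction top fraction for the EF (default 5\%).
#' @return named numeric vector of best-orientation EF values.
#' @export
singleScoreEf <- function(table, columns = scoreNames(table), fraction = 0.05) {
    stopifnot(is(table, "ScoreTable"))
    labels <- activityLabels(table)
    x <- scoreMatrix(table)
    vapply(columns, function(cn) {
        efPlus <- suppressWarnings(
            enrichmentFactor(rankMolecules(table, x[, cn]), labels, fraction)$ef)
        efMinus <- suppressWarnings(
            enrichmentFactor(rankMolecules(table, -x[, cn]), labels, fraction)$ef)
        max(efPlus, efMinus)
    }, numeric(1))
}

#' Remove ineffective score columns
#'
#' A column is kept only if its best single-score enrichment factor on the
#' top 5\% of the ranking (max over both orientations) reaches the
#' threshold; scores that cannot beat EF 2.0 on their own contribute mostly
#' noise to the subset search.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param columns candidate score columns.
#' @param minEf minimum acceptable single-score EF.
#' @param fraction top fraction on which the EF is computed.
#' @param singleEfs optional precomputed values from
#'   \code{\link{singleScoreEf}} (must cover \code{columns}).
#' @return list with \code{surviving}, and \code{report} (data.frame:
#'   column, bestEf, kept).
#' @export
effectivenessFilter <- function(table, columns = scoreNames(table),
                                minEf = 2.0, fraction = 0.05,
                                singleEfs = NULL) {
    stopifnot(is(table, "ScoreTable"))
    if (is.null(singleEfs)) {
        singleEfs <- singleScoreEf(table, columns, fraction)
    }
    efs <- singleEfs[columns]
    kept <- efs >= minEf
    list(surviving = columns[kept],
         report = data.frame(column = columns, bestEf = unname(efs),
                             kept = unname(kept)))
}

#' Prefilter a score set for the consensus search
#'
#' Fixed pipeline: per-column best single-score EF5\% first (needed for VIF
#' tie-breaking and reported either way), then greedy VIF elimination of
#' interrelated columns, then removal of ineffective columns. Both filters
#' are idempotent on their own output.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param columns candidate score columns (default all).
#' @param vifMax VIF threshold (default 5).
#' @param minEf5 minimum single-score EF5\% (default 2.0).
#' @return list with \code{surviving}, \code{singleEfs}, \code{vifReport}
#'   and \code{effectivenessReport}.
#' @export
prefilterScores <- function(table, columns = scoreNames(table), vifMax = 5,
                            minEf5 = 2.0) {
    singleEfs <- singleScoreEf(table, columns)
    vr <- vifFilter(table, columns, threshold = vifMax, singleEfs = singleEfs)
    er <- effectivenessFilter(table, vr$surviving, minEf = minEf5,
                              singleEfs = singleEfs)
    list(surviving = er$surviving, singleEfs = singleEfs, vifReport = vr,
         effectivenessReport = er)
}
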