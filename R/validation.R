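#' Repeated stratified train/test splits
#'
#' Each repeat draws a stratified random split: round(testFraction * A)
#' actives and round(testFraction * D) decoys form the test set, so the
#' active fraction of both partitions stays within one molecule of the
#' overall fraction, and every test set contains at least one active and one
#' decoy (an unstratified 20\% draw from a small-active table can contain
#' none, leaving the enrichment factor undefined). Per-repeat seeds are
#' derived as seed + repeat index.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param testFraction fraction of molecules held out (default 0.2).
#' @param repeats number of repeats (default 5).
#' @param seed base seed.
#' @return list of split plans: each a list with \code{repeatIndex},
#'   \code{train}, \code{test} (integer row indices) and \code{seed}.
#' @export
makeSplits <- function(table, testFraction = 0.2, repeats = 5, seed = 1) {
    stopifnot(is(table, "ScoreTable"), testFraction > 0, testFraction < 1)
    labels <- activityLabels(table)
    act <- which(labels == 1L)
    dec <- which(labels == 0L)
    if (length(act) < repeats || length(dec) < repeats) {
        stop("too few actives or decoys (", length(act), "/", length(dec),
             ") for ", repeats, " validation repeats; reduce `repeats`")
    }
    nTestA <- round(testFraction * length(act))
    nTestD <- round(testFraction * length(dec))
    if (nTestA < 1L || nTestD < 1L) {
        stop("test fraction ", testFraction, " yields an empty test class; ",
             "reduce `repeats` or use a larger test fraction")
    }
    lapply(seq_len(repeats), function(r) {
        set.seed(as.integer((as.numeric(seed) + r) %% 2147483629))
        testIdx <- sort(c(sample(act, nTestA), sample(dec, nTestD)))
        list(repeatIndex = r, train = setdiff(seq_along(labels), testIdx),
             test = testIdx, seed = as.integer((as.numeric(seed) + r) %% 2147483629))
    })
}

# memoized hierarchical fit: each subset is warm-started from the best
# fitted model among its (k-1)-sub-subsets
.fitHierarchy <- function(table, subsets, config, rows, splitIndex) {
    memo <- new.env(parent = emptyenv())
    fit <- function(ss) {
        key <- paste(ss, collapse = "+")
        if (!is.null(memo[[key]])) return(memo[[key]])
        warm <- NULL
        if (length(ss) > 1L && config@warmStart) {
            lower <- lapply(utils::combn(ss, length(ss) - 1L, simplify = FALSE), fit)
            qs <- vapply(lower, function(m) m@trainQ, numeric(1))
            warm <- lower[[which.max(qs)]]
        }
        m <- optimizeCoefficients(table, ss, config, warmStart = warm,
                                  rows = rows, splitIndex = splitIndex)
        memo[[key]] <- m
        m
    }
    lapply(subsets, fit)
}

.testMetricsRow <- function(model, table, rows, clusterSize) {
    # the cluster is scaled pro rata so the test metric probes the same
    # ranking depth as the full-data cluster (C = 100 on ~3000 molecules is
    # the top ~3%; unscaled it would cover ~17% of a 20% test split and the
    # active count would saturate for every reasonable model)
    cTest <- max(1L, as.integer(round(clusterSize * length(rows) /
                                      nMolecules(table))))
    app <- applyModel(model, table[rows], clusterSize = cTest)
    prof <- app$profile
    data.frame(ef1 = prof$ef[1], ef2 = prof$ef[2], ef5 = prof$ef[3],
               ef10 = prof$ef[4], ef20 = prof$ef[5],
               q = app$quality$q, auc = app$auc)
}

#' Validate candidate subsets by repeated train/test fitting
#'
#' For every candidate subset and every split, coefficients are fitted on the
#' training rows only (standardization parameters included) and the model is
#' applied to the held-out rows; the per-repeat test metrics are averaged,
#' and the subset with the highest average test quality is selected (ties:
#' higher average test EF1\%, then lexicographically smaller subset). A
#' subset whose optimization fails on any split is flagged and excluded.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param subsets list of character vectors (typically
#'   \code{\link{enumerateSubsets}} over the prefilter survivors).
#' @param splits from \code{\link{makeSplits}}.
#' @param config a \linkS4class{SearchConfig}.
#' @return list with \code{perRepeat} (data.frame), \code{averages}
#'   (data.frame, sorted by decreasing average test q), \code{selected}
#'   (character vector) and \code{failed} (character keys of flagged
#'   subsets).
#' @export
validateSubsets <- function(table, subsets, splits, config = searchConfig()) {
    stopifnot(is(table, "ScoreTable"), length(subsets) >= 1L)
    keys <- vapply(subsets, paste, "", collapse = "+")
    perRepeat <- list()
    failed <- character()
    for (sp in splits) {
        mods <- tryCatch(
            .fitHierarchy(table, subsets, config, rows = sp$train,
                          splitIndex = sp$repeatIndex),
            error = function(e) e)
        if (inherits(mods, "error")) {
            # retry subset-by-subset so one bad subset does not kill the run
            mods <- lapply(subsets, function(ss) {
                tryCatch(.fitHierarchy(table, list(ss), config,
                                       rows = sp$train,
                                       splitIndex = sp$repeatIndex)[[1L]],
                         error = function(e) e)
            })
        }
        for (i in seq_along(subsets)) {
            m <- mods[[i]]
            if (inherits(m, "error")) {
                failed <- union(failed, keys[i])
                next
            }
            row <- suppressWarnings(
                .testMetricsRow(m, table, sp$test, config@clusterSize))
            row <- cbind(data.frame(subset = keys[i],
                                    repeatIndex = sp$repeatIndex), row)
            perRepeat[[length(perRepeat) + 1L]] <- row
        }
    }
    perRepeat <- do.call(rbind, perRepeat)
    keep <- setdiff(keys, failed)
    if (!length(keep)) stop("optimization failed for every candidate subset")
    perRepeat <- perRepeat[perRepeat$subset %in% keep, , drop = FALSE]
    agg <- stats::aggregate(perRepeat[, c("ef1", "ef2", "ef5", "ef10", "ef20",
                                          "q", "auc")],
                            by = list(subset = perRepeat$subset), FUN = mean)
    # selection: max avg test q, then max avg test EF1%, then lexicographic
    ordSel <- order(-agg$q, -agg$ef1, agg$subset, method = "radix")
    agg <- agg[ordSel, , drop = FALSE]
    rownames(agg) <- NULL
    selectedKey <- agg$subset[1L]
    list(perRepeat = perRepeat, averages = agg,
         selected = subsets[[match(selectedKey, keys)]], failed = failed)
}

#' Refit the selected subset on the full table
#'
#' After validation has chosen a subset, its coefficients are refitted on all
#' rows and the full-data metrics are reported next to the validation
#' averages, exposing any train/test performance mismatch.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param subset the selected score columns.
#' @param config a \linkS4class{SearchConfig}.
#' @return list with \code{model}, \code{profile}, \code{auc} and
#'   \code{quality} on the full table.
#' @export
finalizeModel <- function(table, subset, config = searchConfig()) {
    mod <- .fitHierarchy(table, list(subset), config,
                         rows = seq_len(nMolecules(table)), splitIndex = 0L)[[1L]]
    app <- suppressWarnings(applyModel(mod, table))
    list(model = mod, profile = app$profile, auc = app$auc,
         quality = app$quality)
}

#' End-to-end consensus screen of a score table
#'
#' The full pipeline: per-column single-score EF5\%, greedy VIF filtering of
#' interrelated scores, removal of ineffective scores, exhaustive
#' enumeration of k-subsets of the survivors, repeated stratified
#' train/test validation of every subset, selection by average test quality,
#' and a final full-data refit of the winner.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param config a \linkS4class{SearchConfig}; \code{config@k} is the model
#'   size.
#' @param vifMax VIF threshold for the interrelation filter.
#' @param minEf5 minimum single-score EF5\% for the effectiveness filter.
#' @param testFraction held-out fraction per validation repeat.
#' @param repeats validation repeats.
#' @return A \linkS4class{ValidationReport}.
#' @export
efoScreen <- function(table, config = searchConfig(), vifMax = 5,
                      minEf5 = 2.0, testFraction = 0.2, repeats = 5) {
    stopifnot(is(table, "ScoreTable"), is(config, "SearchConfig"))
    pf <- prefilterScores(table, vifMax = vifMax, minEf5 = minEf5)
    if (length(pf$surviving) < config@k) {
        stop("only ", length(pf$surviving), " score column(s) survive the ",
             "prefilter; cannot build k = ", config@k, " models")
    }
    subsets <- enumerateSubsets(pf$surviving, config@k)
    splits <- makeSplits(table, testFraction = testFraction, repeats = repeats,
                         seed = config@seed)
    val <- validateSubsets(table, subsets, splits, config)
    fin <- finalizeModel(table, val$selected, config)
    new("ValidationReport", perRepeat = val$perRepeat, averages = val$averages,
        selected = val$selected, finalModel = fin$model,
        finalProfile = fin$profile, finalAuc = fin$auc,
        finalQ = fin$quality$q, splits = splits, config = config,
        filterReports = pf)
}

setMethod("show", "ValidationReport", function(object) {
    cat("ValidationReport:", nrow(object@averages), "candidate subset(s),",
        length(object@splits), "repeat(s)\n")
    cat("  selected:", paste(object@selected, collapse = " + "), "\n")
    cat(sprintf("  avg test Q = %.4f | full-data Q = %.4f | full-data AUC = %.4f\n",
                object@averages$q[1L], object@finalQ, object@finalAuc))
    cat("  full-data EF:",
        paste(sprintf("%g%%=%.2f", object@finalProfile$fraction * 100,
                      object@finalProfile$ef), collapse = "  "), "\n")
})

#' @rdname ValidationReport-accessors
#' @param x a \linkS4class{ValidationReport}.
#' @return \code{selectedSubset}: character; \code{finalModel}: the
#'   full-data \linkS4class{ConsensusModel}; \code{validationAverages}:
#'   data.frame of across-repeat test metric means.
#' @export
setMethod("selectedSubset", "ValidationReport", function(x) x@selected)

#' @rdname ValidationReport-accessors
#' @export
setMethod("finalModel", "ValidationReport", function(x) x@finalModel)

#' @rdname ValidationReport-accessors
#' @export
setMethod("validationAverages", "ValidationReport", function(x) x@averages)
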