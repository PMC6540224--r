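#' Construct search settings
#'
#' @param clusterSize quality-cluster size C (top-ranked molecules whose
#'   active count the cost function maximizes).
#' @param nStarts random unit starting vectors per subset.
#' @param maxIter maximum pattern-search proposals per start.
#' @param rmsTol convergence tolerance: a start stops when sigma * sqrt(k)
#'   falls below it.
#' @param sigma0 initial Gaussian step size on the unit sphere.
#' @param rejectLimit consecutive rejections before halving sigma.
#' @param k subset size (1, 2 or 3).
#' @param seed base seed; every random draw of a search derives from it.
#' @param warmStart also seed each subset with the best lower-order model.
#' @return A \linkS4class{SearchConfig}.
#' @export
searchConfig <- function(clusterSize = 100, nStarts = 12, maxIter = 5000,
                         rmsTol = 0.001, sigma0 = 0.5, rejectLimit = 100,
                         k = 2, seed = 1, warmStart = TRUE) {
    new("SearchConfig", clusterSize = as.integer(clusterSize),
        nStarts = as.integer(nStarts), maxIter = as.integer(maxIter),
        rmsTol = as.numeric(rmsTol), sigma0 = as.numeric(sigma0),
        rejectLimit = as.integer(rejectLimit), k = as.integer(k),
        seed = as.integer(seed), warmStart = isTRUE(warmStart))
}

setMethod("show", "SearchConfig", function(object) {
    cat("SearchConfig: k =", object@k, "| cluster size =", object@clusterSize,
        "| starts =", object@nStarts, "| maxIter =", object@maxIter,
        "| rmsTol =", object@rmsTol, "| seed =", object@seed,
        "| warm start =", object@warmStart, "\n")
})

#' Standardize score columns on a fitting set
#'
#' z = (x - mean) / sd with mean and sd estimated on the fitting rows only;
#' the parameters are returned so a fitted model can apply the identical
#' transform to held-out molecules (no test-set leakage).
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param subset score column names.
#' @param rows fitting row indices (default: all rows).
#' @return list with \code{z} (matrix over \code{rows}), \code{center} and
#'   \code{scale} (named numeric vectors).
#' @export
standardizeScores <- function(table, subset, rows = seq_len(nMolecules(table))) {
    stopifnot(is(table, "ScoreTable"))
    miss <- setdiff(subset, scoreNames(table))
    if (length(miss)) stop("missing score column(s): ", paste(miss, collapse = ", "))
    x <- scoreMatrix(table)[rows, subset, drop = FALSE]
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    if (any(scl == 0)) {
        stop("zero-variance column(s) on the fitting rows: ",
             paste(subset[scl == 0], collapse = ", "))
    }
    z <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
    list(z = z, center = ctr, scale = scl)
}

#' Enumerate score subsets of size k
#'
#' All C(n, k) subsets in deterministic lexicographic order (columns in their
#' given order; subsets ordered by position).
#'
#' @param columns character vector of score column names.
#' @param k subset size.
#' @return list of character vectors.
#' @export
enumerateSubsets <- function(columns, k) {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > length(columns)) {
        stop("k (", k, ") exceeds the number of available columns (",
             length(columns), ")")
    }
    cmb <- utils::combn(columns, k, simplify = FALSE)
    cmb
}

# deterministic per-call seed: mixes the base seed, a split index and the
# subset names; independent of any molecule data so fitted models cannot
# depend on test rows through the RNG.
.derivedSeed <- function(seed, splitIndex, subset) {
    h <- 0
    for (ch in utf8ToInt(paste(subset, collapse = "/"))) {
        h <- (h * 131 + ch) %% 9999991
    }
    as.integer((as.numeric(seed) * 7919 + splitIndex * 104729 + h) %% 2147483629 + 1)
}

.newModel <- function(subset, w, stz, q, clusterSize, seed) {
    new("ConsensusModel", subset = subset, coefficients = as.numeric(w),
        center = unname(stz$center), scale = unname(stz$scale),
        trainQ = q$q, trainClusterActives = as.numeric(q$clusterActives),
        trainMeanRank = q$meanNormRank, clusterSize = as.integer(clusterSize),
        seed = as.integer(seed))
}

#' Fit combination coefficients for one score subset
#'
#' For k = 1 the fit is exact: the two orientations +1 and -1 are evaluated
#' and the better one returned. For k >= 2, \code{nStarts} seeded random unit
#' vectors (plus warm starts, when supplied) are each refined by an
#' accept-if-better Gaussian pattern search on the unit sphere: propose
#' w' = normalize(w + sigma * g) with g ~ N(0, I), accept only strict quality
#' improvements, halve sigma after \code{rejectLimit} consecutive rejections,
#' and stop a start when sigma * sqrt(k) < \code{rmsTol} or after
#' \code{maxIter} proposals. The quality function is rank-based and piecewise
#' constant, so a derivative-free search with step shrinking is used rather
#' than a gradient or simplex method.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param subset score column names (length 1 to 3).
#' @param config a \linkS4class{SearchConfig}.
#' @param warmStart optional \linkS4class{ConsensusModel} (or list of models)
#'   on sub-subsets of \code{subset}; each is padded with zero coefficients
#'   to the full subset and added as an extra start, which guarantees the
#'   returned quality is at least the warm start's.
#' @param rows fitting row indices (default: all). Standardization and
#'   quality use these rows only.
#' @param splitIndex integer mixed into the derived seed so repeated splits
#'   get independent random starts.
#' @return A \linkS4class{ConsensusModel} with canonical (unit-norm)
#'   coefficients and its training quality.
#' @export
optimizeCoefficients <- function(table, subset, config = searchConfig(k = length(subset)),
                                 warmStart = NULL,
                                 rows = seq_len(nMolecules(table)),
                                 splitIndex = 0L) {
    stopifnot(is(table, "ScoreTable"), is(config, "SearchConfig"))
    k <- length(subset)
    if (!k %in% 1:3) stop("subset size must be 1, 2 or 3")
    labels <- activityLabels(table)[rows]
    if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L) {
        stop("fitting rows must contain at least one active and one decoy")
    }
    stz <- standardizeScores(table, subset, rows)
    sub <- table[rows]
    seed <- .derivedSeed(config@seed, splitIndex, subset)
    cs <- min(config@clusterSize, length(rows))

    qOf <- function(w) {
        qualityScore(rankMolecules(sub, as.numeric(stz$z %*% w)), labels, cs)
    }
    if (k == 1L) {
        qp <- qOf(1)
        qm <- qOf(-1)
        if (qm$q > qp$q) {
            return(.newModel(subset, -1, stz, qm, cs, seed))
        }
        return(.newModel(subset, 1, stz, qp, cs, seed))
    }

    set.seed(seed)
    starts <- matrix(stats::rnorm(k * config@nStarts), nrow = k)
    starts <- apply(starts, 2L, function(v) v / sqrt(sum(v^2)))
    if (!is.null(warmStart)) {
        if (is(warmStart, "ConsensusModel")) warmStart <- list(warmStart)
        for (wm in warmStart) {
            if (!all(wm@subset %in% subset)) {
                stop("warm start subset is not contained in the target subset")
            }
            w0 <- numeric(k)
            w0[match(wm@subset, subset)] <- wm@coefficients
            starts <- cbind(starts, w0)
        }
    }
    res <- .patternSearchCpp(as.matrix(stz$z), as.integer(labels), cs,
                             starts, config@maxIter, config@rmsTol,
                             config@sigma0, config@rejectLimit)
    w <- res$coefficients
    if (any(!is.finite(w)) || !is.finite(res$q)) {
        stop("optimization produced a non-finite result for subset ",
             paste(subset, collapse = "+"))
    }
    q <- qOf(w) # canonical quality (lexicographic-id tie-break)
    .newModel(subset, w, stz, q, cs, seed)
}

#' Apply a consensus model to a score table
#'
#' Standardizes the subset columns with the model's stored fitting-set
#' parameters, combines them linearly, ranks, and computes the enrichment
#' profile, ROC AUC and quality.
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param table a \linkS4class{ScoreTable} containing all subset columns.
#' @param clusterSize quality-cluster size (default: the model's own).
#' @return list with \code{combined} (numeric vector), \code{ranking},
#'   \code{profile} (enrichment profile data.frame), \code{auc} and
#'   \code{quality} (list from \code{\link{qualityScore}}).
#' @export
applyModel <- function(model, table, clusterSize = model@clusterSize) {
    stopifnot(is(model, "ConsensusModel"), is(table, "ScoreTable"))
    miss <- setdiff(model@subset, scoreNames(table))
    if (length(miss)) {
        stop("table lacks score column(s): ", paste(miss, collapse = ", "))
    }
    x <- scoreMatrix(table)[, model@subset, drop = FALSE]
    z <- sweep(sweep(x, 2L, model@center, "-"), 2L, model@scale, "/")
    combined <- as.numeric(z %*% model@coefficients)
    ranking <- rankMolecules(table, combined)
    labels <- activityLabels(table)
    list(combined = combined, ranking = ranking,
         profile = enrichmentProfile(ranking, labels),
         auc = rocAuc(combined, labels),
         quality = qualityScore(ranking, labels,
                                min(clusterSize, nMolecules(table))))
}

#' Exhaustive consensus search over score subsets
#'
#' Enumerates all subsets of sizes 1 .. \code{config@k} over the given
#' columns and fits each independently; level k subsets are warm-started
#' from the best fitted model among their (k-1)-sub-subsets (padded with a
#' zero coefficient), which guarantees that the best training quality is
#' monotone non-decreasing in k. The global best at each level is the
#' maximum over subsets.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param config a \linkS4class{SearchConfig}; \code{config@k} is the top
#'   subset size searched.
#' @param columns candidate score columns (typically the prefilter
#'   survivors).
#' @param rows fitting row indices.
#' @param splitIndex integer mixed into derived seeds.
#' @return list with \code{models} (per level: named list of
#'   \linkS4class{ConsensusModel}), \code{best} (per level: the best model)
#'   and \code{bestQ} (numeric per level).
#' @export
efoSearch <- function(table, config = searchConfig(),
                      columns = scoreNames(table),
                      rows = seq_len(nMolecules(table)), splitIndex = 0L) {
    stopifnot(is(config, "SearchConfig"))
    if (config@k > length(columns)) {
        stop("k (", config@k, ") exceeds the number of candidate columns (",
             length(columns), ")")
    }
    levels <- vector("list", config@k)
    best <- vector("list", config@k)
    for (kk in seq_len(config@k)) {
        subs <- enumerateSubsets(columns, kk)
        mods <- vector("list", length(subs))
        names(mods) <- vapply(subs, paste, "", collapse = "+")
        for (i in seq_along(subs)) {
            ss <- subs[[i]]
            warm <- NULL
            if (kk > 1L && config@warmStart) {
                lower <- levels[[kk - 1L]]
                subKeys <- vapply(utils::combn(ss, kk - 1L, simplify = FALSE),
                                  paste, "", collapse = "+")
                cand <- lower[intersect(subKeys, names(lower))]
                if (length(cand)) {
                    qs <- vapply(cand, function(m) m@trainQ, numeric(1))
                    warm <- cand[[which.max(qs)]]
                }
            }
            mods[[i]] <- optimizeCoefficients(table, ss, config, warmStart = warm,
                                              rows = rows, splitIndex = splitIndex)
        }
        levels[[kk]] <- mods
        qs <- vapply(mods, function(m) m@trainQ, numeric(1))
        best[[kk]] <- mods[[which.max(qs)]]
    }
    list(models = levels, best = best,
         bestQ = vapply(best, function(m) m@trainQ, numeric(1)))
}

setMethod("show", "ConsensusModel", function(object) {
    eq <- paste(sprintf("%+.4f*z(%s)", object@coefficients, object@subset),
                collapse = " ")
    cat("ConsensusModel (k =", length(object@subset), ")\n")
    cat("  combined =", eq, "\n")
    cat(sprintf("  train Q = %.4f (cluster actives %d of top %d)\n",
                object@trainQ, as.integer(object@trainClusterActives),
                object@clusterSize))
})

#' @rdname ConsensusModel-accessors
#' @param x a \linkS4class{ConsensusModel}.
#' @return \code{modelSubset}: character; \code{modelCoefficients}: named
#'   numeric; \code{trainQuality}: numeric Q on the fitting rows.
#' @export
setMethod("modelSubset", "ConsensusModel", function(x) x@subset)

#' @rdname ConsensusModel-accessors
#' @export
setMethod("modelCoefficients", "ConsensusModel", function(x) {
    stats::setNames(x@coefficients, x@subset)
})

#' @rdname ConsensusModel-accessors
#' @export
setMethod("trainQuality", "ConsensusModel", function(x) x@trainQ)

#' Serialize / restore a consensus model
#'
#' Models are stored as a structured JSON record carrying the subset,
#' coefficients, standardization parameters, cluster size, training quality
#' and the derived seed, plus the package version for audit.
#'
#' @param model a \linkS4class{ConsensusModel}.
#' @param path output (input) file path.
#' @return \code{writeConsensusModel}: invisibly \code{path};
#'   \code{readConsensusModel}: a \linkS4class{ConsensusModel}.
#' @export
writeConsensusModel <- function(model, path) {
    stopifnot(is(model, "ConsensusModel"))
    rec <- list(
        tool = "efoscreen", version = as.character(utils::packageVersion("efoscreen")),
        subset = model@subset, coefficients = model@coefficients,
        center = model@center, scale = model@scale,
        clusterSize = model@clusterSize, seed = model@seed,
        trainQ = model@trainQ, trainClusterActives = model@trainClusterActives,
        trainMeanRank = model@trainMeanRank)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    invisible(path)
}

#' @rdname writeConsensusModel
#' @export
readConsensusModel <- function(path) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("ConsensusModel", subset = rec$subset,
        coefficients = as.numeric(rec$coefficients),
        center = as.numeric(rec$center), scale = as.numeric(rec$scale),
        trainQ = rec$trainQ, trainClusterActives = rec$trainClusterActives,
        trainMeanRank = rec$trainMeanRank,
        clusterSize = as.integer(rec$clusterSize), seed = as.integer(rec$seed))
}
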