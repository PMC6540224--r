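#' @import methods
NULL

#' ScoreTable: labeled molecules by named docking/rescoring scores
#'
#' The universal input of the consensus pipeline: one row per molecule with a
#' binary activity label (1 = active, 0 = decoy), a numeric score matrix with
#' named columns (docking and rescoring scores, higher or lower = better is
#' irrelevant here: orientation is carried by model coefficient signs), and
#' optional positive molecular-property columns (molecular weight in Da,
#' heavy-atom count) used only for score normalization.
#'
#' @slot moleculeIds character, unique molecule identifiers (row order is
#'   preserved from the source file or generator).
#' @slot labels integer, 0/1 activity labels; at least one active and one
#'   decoy are required.
#' @slot scores numeric matrix, molecules x named score columns; no missing
#'   values are allowed.
#' @slot properties numeric matrix, molecules x named positive property
#'   columns; may have zero columns.
#' @slot source character, free-text provenance.
#' @exportClass ScoreTable
setClass("ScoreTable",
    representation(
        moleculeIds = "character",
        labels = "integer",
        scores = "matrix",
        properties = "matrix",
        source = "character"
    )
)

setValidity("ScoreTable", function(object) {
    n <- length(object@moleculeIds)
    msg <- character()
    if (n < 2L) msg <- c(msg, "at least 2 molecules are required")
    dup <- unique(object@moleculeIds[duplicated(object@moleculeIds)])
    if (length(dup)) {
        msg <- c(msg, paste0("duplicated molecule id(s): ",
            paste(utils::head(dup, 5L), collapse = ", ")))
    }
    if (length(object@labels) != n) msg <- c(msg, "labels length != number of molecules")
    if (!all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
    a <- sum(object@labels == 1L)
    if (a < 1L) msg <- c(msg, "at least one active (label 1) is required")
    if (n - a < 1L) msg <- c(msg, "at least one decoy (label 0) is required")
    if (nrow(object@scores) != n) msg <- c(msg, "score matrix rows != number of molecules")
    if (!is.numeric(object@scores)) msg <- c(msg, "scores must be numeric")
    if (anyNA(object@scores) || any(!is.finite(object@scores))) {
        msg <- c(msg, "scores contain missing or non-finite values")
    }
    if (ncol(object@scores) > 0L) {
        cn <- colnames(object@scores)
        if (is.null(cn) || anyNA(cn) || any(cn == "")) {
            msg <- c(msg, "all score columns must be named")
        } else if (anyDuplicated(cn)) msg <- c(msg, "score column names must be unique")
    }
    if (nrow(object@properties) != n && ncol(object@properties) > 0L) {
        msg <- c(msg, "property matrix rows != number of molecules")
    }
    if (ncol(object@properties) > 0L) {
        pn <- colnames(object@properties)
        if (is.null(pn) || anyDuplicated(pn)) msg <- c(msg, "property columns must be uniquely named")
        if (anyNA(object@properties)) msg <- c(msg, "properties contain missing values")
    }
    if (length(msg)) msg else TRUE
})

#' Ranking of a score table by a combined score
#'
#' @slot orderedIds character, molecule ids from best (rank 1) to worst.
#' @slot order integer, permutation of row indices producing orderedIds.
#' @slot tieGroups list of character vectors, groups of ids sharing an
#'   identical combined score (only groups of size >= 2 are recorded).
#' @exportClass Ranking
setClass("Ranking",
    representation(orderedIds = "character", order = "integer",
                   tieGroups = "list")
)

#' Search settings for coefficient optimization
#'
#' Defaults follow the tool's standard operating settings: quality-cluster
#' size 100 molecules, 12 random starting vectors per subset, up to 5000
#' pattern-search proposals per start, and step-size convergence tolerance
#' (RMS) 0.001 on the unit sphere.
#'
#' @slot clusterSize integer, number of top-ranked molecules over which the
#'   quality function counts actives.
#' @slot nStarts integer, random unit starting vectors per score subset.
#' @slot maxIter integer, maximum proposals per start.
#' @slot rmsTol numeric, stop a start when sigma * sqrt(k) falls below this.
#' @slot sigma0 numeric, initial Gaussian step size on the unit sphere.
#' @slot rejectLimit integer, consecutive rejections before halving sigma.
#' @slot k integer, subset size (1, 2 or 3).
#' @slot seed integer, base seed; all randomness derives from it.
#' @slot warmStart logical, seed each k-subset with the best (k-1)-sub-subset
#'   model padded with a zero coefficient (guarantees monotone training
#'   quality in k).
#' @exportClass SearchConfig
setClass("SearchConfig",
    representation(
        clusterSize = "integer", nStarts = "integer", maxIter = "integer",
        rmsTol = "numeric", sigma0 = "numeric", rejectLimit = "integer",
        k = "integer", seed = "integer", warmStart = "logical"
    )
)

setValidity("SearchConfig", function(object) {
    msg <- character()
    for (sl in c("clusterSize", "nStarts", "maxIter", "rejectLimit", "k", "seed")) {
        v <- slot(object, sl)
        if (length(v) != 1L || is.na(v) || v < 1L) {
            msg <- c(msg, paste0(sl, " must be a positive integer"))
        }
    }
    if (object@rmsTol <= 0) msg <- c(msg, "rmsTol must be positive")
    if (object@sigma0 <= 0) msg <- c(msg, "sigma0 must be positive")
    if (!object@k %in% 1:3) msg <- c(msg, "k must be 1, 2 or 3")
    if (length(msg)) msg else TRUE
})

#' Consensus scoring model: a score subset with fitted combination weights
#'
#' Combined score = sum_j coefficients[j] * (score_j - center[j]) / scale[j],
#' higher = better. Coefficients have unit L2 norm; their signs carry score
#' orientation (energy-like lower-is-better scores get negative weights).
#'
#' @slot subset character, ordered names of the combined score columns.
#' @slot coefficients numeric, unit-L2-norm combination weights.
#' @slot center,scale numeric, per-column standardization parameters estimated
#'   on the fitting rows.
#' @slot trainQ numeric, quality value on the fitting rows.
#' @slot trainClusterActives numeric, actives in the top cluster on the
#'   fitting rows.
#' @slot trainMeanRank numeric, mean active rank on the fitting rows.
#' @slot clusterSize integer, cluster size the model was fitted with.
#' @slot seed integer, derived seed used for this fit.
#' @exportClass ConsensusModel
setClass("ConsensusModel",
    representation(
        subset = "character", coefficients = "numeric",
        center = "numeric", scale = "numeric",
        trainQ = "numeric", trainClusterActives = "numeric",
        trainMeanRank = "numeric", clusterSize = "integer", seed = "integer"
    )
)

setValidity("ConsensusModel", function(object) {
    msg <- character()
    k <- length(object@subset)
    if (!k %in% 1:3) msg <- c(msg, "subset size must be 1, 2 or 3")
    if (length(object@coefficients) != k) msg <- c(msg, "coefficients length != subset size")
    if (length(object@center) != k || length(object@scale) != k) {
        msg <- c(msg, "standardization parameter length != subset size")
    }
    if (any(object@scale <= 0)) msg <- c(msg, "standardization scales must be positive")
    nrm <- sqrt(sum(object@coefficients^2))
    if (abs(nrm - 1) > 1e-8) msg <- c(msg, "coefficients must have unit L2 norm")
    if (length(msg)) msg else TRUE
})

#' Generator settings for DUD-like synthetic benchmark tables
#'
#' A single latent binding-propensity variable t ~ N(0,1) + delta * label is
#' observed through K score columns score_j = loading_j * t + noiseSd_j * eps.
#' Negative loadings give the energy convention (more negative = better).
#'
#' @slot nMolecules integer, table size (DUD datasets average ~3000).
#' @slot nActive integer, actives (decoys are >95 percent of the table).
#' @slot nScores integer, score columns before optional extras.
#' @slot loadings numeric, per-column latent loadings.
#' @slot delta numeric, latent mean shift of actives in latent SD units.
#' @slot noiseSd numeric, per-column noise SD (recycled if scalar).
#' @slot includeDuplicate logical, append a near-copy (r >= 0.999) of column 1.
#' @slot includeNull logical, append a zero-loading pure-noise column.
#' @slot mwRange numeric length 2, uniform molecular-weight range (Da).
#' @slot heavyRange numeric length 2, uniform heavy-atom-count range.
#' @slot seed integer.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(
        nMolecules = "integer", nActive = "integer", nScores = "integer",
        loadings = "numeric", delta = "numeric", noiseSd = "numeric",
        includeDuplicate = "logical", includeNull = "logical",
        mwRange = "numeric", heavyRange = "numeric", seed = "integer"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nMolecules < 2L) msg <- c(msg, "nMolecules must be >= 2")
    if (object@nActive < 1L || object@nActive >= object@nMolecules) {
        msg <- c(msg, "nActive must satisfy 1 <= nActive < nMolecules")
    }
    if (object@nScores < 1L) msg <- c(msg, "nScores must be >= 1")
    if (length(object@loadings) != object@nScores) {
        msg <- c(msg, "loadings length must equal nScores")
    }
    if (!length(object@noiseSd) %in% c(1L, object@nScores)) {
        msg <- c(msg, "noiseSd must be scalar or one value per score")
    }
    if (any(object@noiseSd < 0)) msg <- c(msg, "noiseSd must be >= 0")
    if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
    if (object@mwRange[1] <= 0 || diff(object@mwRange) < 0) {
        msg <- c(msg, "mwRange must be positive and non-decreasing")
    }
    if (object@heavyRange[1] <= 0 || diff(object@heavyRange) < 0) {
        msg <- c(msg, "heavyRange must be positive and non-decreasing")
    }
    if (length(msg)) msg else TRUE
})

#' Validation report of a consensus screen
#'
#' @slot perRepeat data.frame, one row per candidate subset and repeat with
#'   the test-set metrics (EF at 1/2/5/10/20 percent, quality Q, AUC).
#' @slot averages data.frame, one row per subset with the across-repeat
#'   means, sorted by decreasing average test quality.
#' @slot selected character, the winning subset.
#' @slot finalModel ConsensusModel refitted on all rows.
#' @slot finalProfile data.frame, full-data enrichment profile of finalModel.
#' @slot finalAuc numeric, full-data ROC AUC of finalModel.
#' @slot finalQ numeric, full-data quality of finalModel.
#' @slot splits list of SplitPlan-like lists used for validation.
#' @slot config SearchConfig used.
#' @slot filterReports list, VIF and effectiveness reports when produced by
#'   \code{efoScreen}.
#' @exportClass ValidationReport
setClass("ValidationReport",
    representation(
        perRepeat = "data.frame", averages = "data.frame",
        selected = "character", finalModel = "ConsensusModel",
        finalProfile = "data.frame", finalAuc = "numeric", finalQ = "numeric",
        splits = "list", config = "SearchConfig", filterReports = "list"
    )
)
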