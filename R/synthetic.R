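# canonical 11-score set emulated by the default generator: PLANTS scoring
# functions, force-field terms, lipophilicity/contact scores and X-Score
.DEFAULT_SCORE_NAMES <- c("chemplp", "plp", "plp95", "xscore", "mlp_inter",
                          "contacts", "lj_charmm", "lj_cvff", "lj_sp4",
                          "elec_eps1", "elec_ddd")

# default loadings: partially redundant, none perfect; energy convention
# (negative loading = more negative is better) everywhere except the two
# bigger-is-better scores (contacts count, X-Score)
.DEFAULT_LOADINGS <- c(chemplp = -0.85, plp = -0.75, plp95 = -0.65,
                       xscore = 0.55, mlp_inter = -0.50, contacts = 0.45,
                       lj_charmm = -0.40, lj_cvff = -0.30, lj_sp4 = -0.25,
                       elec_eps1 = -0.20, elec_ddd = -0.15)

#' Generator settings for DUD-like benchmark tables
#'
#' Defaults emulate the structure of a DUD dataset after docking and
#' rescoring: ~3000 molecules of which >95\% are decoys (80 actives), 11
#' inter-correlated score columns observed through a single latent binding
#' propensity, an effect size of 2 latent SD between actives and decoys, and
#' unit per-column noise.
#'
#' @param nMolecules,nActive,nScores table dimensions.
#' @param loadings per-column latent loadings; default: a graded,
#'   mostly-energy-convention profile over the standard 11-score set.
#' @param delta latent mean shift of actives (in latent SD units).
#' @param noiseSd per-column noise SD (scalar recycled).
#' @param includeDuplicate append a near-copy of column 1 (r >= 0.999),
#'   named \code{"<col1>_dup"}.
#' @param includeNull append a zero-loading noise column \code{noise_score}.
#' @param mwRange,heavyRange uniform drug-like property ranges (Da; atoms).
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nMolecules = 3000, nActive = 80, nScores = 11,
                            loadings = NULL, delta = 2.0, noiseSd = 1.0,
                            includeDuplicate = FALSE, includeNull = FALSE,
                            mwRange = c(200, 600), heavyRange = c(15, 45),
                            seed = 1) {
    if (is.null(loadings)) {
        loadings <- if (nScores == 11L) .DEFAULT_LOADINGS else {
            sgn <- rep(c(-1, -1, 1), length.out = nScores)
            stats::setNames(sgn * seq(0.85, 0.15, length.out = nScores),
                            sprintf("score_%02d", seq_len(nScores)))
        }
    }
    if (is.null(names(loadings))) {
        names(loadings) <- if (length(loadings) == 11L) .DEFAULT_SCORE_NAMES
                           else sprintf("score_%02d", seq_along(loadings))
    }
    new("SyntheticConfig", nMolecules = as.integer(nMolecules),
        nActive = as.integer(nActive), nScores = as.integer(nScores),
        loadings = loadings, delta = as.numeric(delta),
        noiseSd = as.numeric(noiseSd),
        includeDuplicate = isTRUE(includeDuplicate),
        includeNull = isTRUE(includeNull), mwRange = as.numeric(mwRange),
        heavyRange = as.numeric(heavyRange), seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nMolecules, "molecules,", object@nActive,
        "actives,", object@nScores, "scores | delta =", object@delta,
        "| seed =", object@seed, "\n")
})

#' Generate a DUD-like labeled score table
#'
#' A latent binding propensity t ~ N(0, 1) + delta * label is observed
#' through every score column as score_j = loading_j * t + noiseSd_j * eps,
#' so the score set is partially redundant and none of the columns is a
#' perfect classifier. Optional extras plant a near-duplicate of column 1
#' (exercising the VIF filter) and a pure-noise column (exercising the
#' effectiveness filter). Properties (molecular weight, heavy-atom count)
#' are drawn uniformly from drug-like ranges and are independent of
#' activity.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{table} (a \linkS4class{ScoreTable}) and
#'   \code{truth}: the ground-truth record (loadings, noise SDs, delta,
#'   active ids, names of the planted duplicate/null columns, seed).
#' @export
generateScoreTable <- function(config = syntheticConfig()) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nMolecules
    ids <- sprintf("mol_%05d", seq_len(n))
    labels <- integer(n)
    labels[sample.int(n, config@nActive)] <- 1L
    t <- stats::rnorm(n) + config@delta * labels
    noise <- rep_len(config@noiseSd, config@nScores)
    scores <- vapply(seq_len(config@nScores), function(j) {
        config@loadings[j] * t + noise[j] * stats::rnorm(n)
    }, numeric(n))
    colnames(scores) <- names(config@loadings)
    dupName <- nullName <- NA_character_
    if (config@includeDuplicate) {
        base <- scores[, 1L]
        # relative noise 0.02 gives sample correlation >= 0.999
        dup <- base + 0.02 * stats::sd(base) * stats::rnorm(n)
        dupName <- paste0(colnames(scores)[1L], "_dup")
        scores <- cbind(scores, dup)
        colnames(scores)[ncol(scores)] <- dupName
    }
    if (config@includeNull) {
        nullName <- "noise_score"
        scores <- cbind(scores, noise_score = stats::rnorm(n))
    }
    props <- cbind(mw = stats::runif(n, config@mwRange[1], config@mwRange[2]),
                   heavy_atoms = round(stats::runif(n, config@heavyRange[1],
                                                    config@heavyRange[2])))
    table <- ScoreTable(ids, labels, scores, props,
                        source = sprintf("synthetic DUD-like (seed %d)",
                                         config@seed))
    truth <- list(loadings = config@loadings, noiseSd = noise,
                  delta = config@delta, activeIds = ids[labels == 1L],
                  duplicateColumn = dupName, nullColumn = nullName,
                  seed = config@seed)
    list(table = table, truth = truth)
}

#' Ground-truth best subset and implied coefficient direction
#'
#' The k base columns with the largest signal-to-noise ratio
#' |loading| / noiseSd (planted duplicate and null columns excluded;
#' exact ties broken lexicographically by column name), together with the
#' Fisher-discriminant direction on standardized columns implied by the
#' generative model: w proportional to solve(SigmaW, muDiff) where SigmaW is
#' the within-class covariance of the standardized scores and muDiff the
#' standardized active-decoy mean difference.
#'
#' @param truth the ground-truth record from
#'   \code{\link{generateScoreTable}}.
#' @param k subset size.
#' @return list with \code{subset} (column names, in signal order) and
#'   \code{direction} (unit-norm numeric vector aligned with \code{subset};
#'   positive entries mean higher raw score = more active).
#' @export
theoreticalBestSubset <- function(truth, k = 2) {
    l <- truth$loadings
    noise <- rep_len(truth$noiseSd, length(l))
    snr <- abs(l) / ifelse(noise == 0, .Machine$double.eps, noise)
    ord <- order(-snr, names(l), method = "radix")
    sel <- ord[seq_len(k)]
    lS <- l[sel]
    nS <- noise[sel]
    # Fisher direction under the generative model, expressed per within-class
    # column SD (within-class latent variance is 1). The pipeline standardizes
    # by the marginal SD, which differs from the within-class SD only by the
    # small label-mixture term delta^2*p*(1-p); the induced rotation of the
    # direction is negligible at DUD-like active fractions.
    sdTot <- sqrt(lS^2 + nS^2)
    muDiff <- lS * truth$delta / sdTot
    sigmaW <- outer(lS / sdTot, lS / sdTot) + diag(nS^2 / sdTot^2, nrow = k)
    w <- solve(sigmaW, muDiff)
    w <- w / sqrt(sum(w^2))
    list(subset = names(l)[sel], direction = unname(w))
}

#' Planted-recovery benchmark configuration
#'
#' The canned low-noise fixture used for end-to-end parameter-recovery
#' checks: three genuinely informative score columns with a graded
#' signal-to-noise ladder (loadings -0.315, -0.310, -0.221; noise SD 1;
#' latent shift delta = 7) and eight near-null fillers that the
#' effectiveness filter should remove. The ladder is calibrated so that the
#' planted best pair and triple are identifiable by the validation protocol:
#' between-subset separation saturates once the best model separates actives
#' by more than about three within-class SDs, and each table's realized
#' column-label noise (about 1/sqrt(n_active) SD) is shared by every split
#' of that table, so the gaps cannot be made arbitrarily wide by raising the
#' signal.
#'
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticRecoveryConfig <- function(seed = 1) {
    syntheticConfig(
        loadings = -c(0.315, 0.310, 0.221, rep(0.001, 8)),
        noiseSd = 1, delta = 7, seed = seed)
}
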