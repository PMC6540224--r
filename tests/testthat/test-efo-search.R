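test_that("standardization is exact and reusable on held-out rows", {
    tab <- ScoreTable(c("a", "b", "c"), c(1, 0, 0), cbind(s = c(1, 2, 3)))
    stz <- standardizeScores(tab, "s")
    expect_equal(unname(stz$center), 2)
    expect_equal(unname(stz$scale), 1)
    expect_equal(unname(stz$z[, 1]), c(-1, 0, 1))

    gen <- generateScoreTable(syntheticConfig(nMolecules = 100, nActive = 10,
                                              nScores = 2, seed = 2))
    tab <- gen$table
    fit <- 1:70
    held <- 71:100
    stz <- standardizeScores(tab, scoreNames(tab), rows = fit)
    x <- scoreMatrix(tab)[held, ]
    manual <- sweep(sweep(x, 2, stz$center, "-"), 2, stz$scale, "/")
    model <- optimizeCoefficients(tab, scoreNames(tab)[1],
                                  searchConfig(k = 1, seed = 1), rows = fit)
    app <- applyModel(model, tab[held])
    expect_equal(app$combined,
                 unname(manual[, 1] * model@coefficients / 1))
    expect_error(standardizeScores(tab, "nope"), "missing score column")
    const <- ScoreTable(c("a", "b"), c(1, 0), cbind(s = c(1, 1)))
    expect_error(standardizeScores(const, "s"), "zero-variance")
})

test_that("subset enumeration is exhaustive and lexicographic", {
    cols <- paste0("s", sprintf("%02d", 1:11))
    expect_length(enumerateSubsets(cols, 2), 55L)
    expect_length(enumerateSubsets(cols, 3), 165L)
    expect_length(enumerateSubsets(cols[1:10], 2), 45L)
    subs <- enumerateSubsets(cols[1:4], 2)
    expect_identical(subs[[1]], c("s01", "s02"))
    expect_identical(subs[[6]], c("s03", "s04"))
    expect_error(enumerateSubsets(cols[1:2], 3), "exceeds")
})

test_that("single-score fits are exact two-orientation exhaustions", {
    # energy-oriented column: all actives most negative
    n <- 200
    labels <- integer(n); labels[1:20] <- 1L
    energy <- c(rnorm(20, -60, 2), rnorm(180, -40, 5))
    tab <- ScoreTable(sprintf("m%03d", 1:n), labels, cbind(e = energy))
    model <- optimizeCoefficients(tab, "e", searchConfig(k = 1, seed = 1))
    expect_equal(unname(model@coefficients), -1)
    want <- oracleBestOrientation(tab, "e", 100)
    expect_equal(trainQuality(model), want$q)

    for (seed in 1:20) {
        rt <- randomTable(seed)
        for (col in scoreNames(rt)) {
            m <- optimizeCoefficients(rt, col, searchConfig(k = 1, seed = 1))
            want <- oracleBestOrientation(rt, col, 100)
            expect_equal(unname(m@coefficients), want$coef)
            expect_equal(trainQuality(m), want$q)
        }
    }
})

test_that("a zero-noise planted separator reaches the quality ceiling", {
    set.seed(4)
    n <- 500
    z1 <- rnorm(n); z2 <- rnorm(n)
    sep <- 0.6 * z1 + 0.8 * z2
    labels <- as.integer(rank(-sep) <= 25) # top 25 by the separator are active
    tab <- ScoreTable(sprintf("m%03d", 1:n), labels,
                      cbind(s1 = z1, s2 = z2))
    model <- optimizeCoefficients(tab, c("s1", "s2"),
                                  searchConfig(k = 2, nStarts = 6,
                                               maxIter = 1500, rmsTol = 1e-3,
                                               clusterSize = 100, seed = 9))
    ceiling <- 25 + (1 - 13 / n) # all actives ranked 1..25, mean rank 13
    expect_equal(trainQuality(model), ceiling)
    expect_gte(absCosine(model@coefficients, c(0.6, 0.8)), 0.99)
})

test_that("small-noise planted coefficients are recovered against a 1-degree grid", {
    set.seed(5)
    n <- 1500
    z1 <- rnorm(n); z2 <- rnorm(n)
    labels <- integer(n)
    sep <- 0.6 * z1 + 0.8 * z2 + rnorm(n, sd = 0.35)
    labels[rank(-sep) <= 40] <- 1L
    tab <- ScoreTable(sprintf("m%04d", 1:n), labels, cbind(s1 = z1, s2 = z2))
    model <- optimizeCoefficients(tab, c("s1", "s2"),
                                  searchConfig(k = 2, nStarts = 6,
                                               maxIter = 1500, rmsTol = 1e-3,
                                               seed = 10))
    grid <- gridBestDirection(tab, c("s1", "s2"), 100)
    expect_gte(absCosine(model@coefficients, grid$direction), 0.95)
    expect_gte(absCosine(model@coefficients, c(0.6, 0.8)), 0.95)
    expect_gte(trainQuality(model), 0.995 * grid$q)
})

test_that("identical seeds give bit-identical models", {
    gen <- generateScoreTable(syntheticConfig(nMolecules = 400, nActive = 20,
                                              nScores = 3, seed = 6))
    cfg <- searchConfig(k = 2, nStarts = 3, maxIter = 200, rmsTol = 0.01,
                        seed = 77)
    m1 <- optimizeCoefficients(gen$table, c("score_01", "score_02"), cfg)
    m2 <- optimizeCoefficients(gen$table, c("score_01", "score_02"), cfg)
    expect_identical(m1@coefficients, m2@coefficients)
    expect_identical(trainQuality(m1), trainQuality(m2))
    m3 <- optimizeCoefficients(gen$table, c("score_01", "score_02"),
                               searchConfig(k = 2, nStarts = 3, maxIter = 200,
                                            rmsTol = 0.01, seed = 78))
    expect_false(identical(m1@coefficients, m3@coefficients))
})

test_that("coefficients stay on the unit sphere and warm starts pad with zero", {
    gen <- generateScoreTable(syntheticConfig(nMolecules = 300, nActive = 15,
                                              nScores = 3, seed = 12))
    res <- efoSearch(gen$table, searchConfig(k = 3, nStarts = 3, maxIter = 150,
                                             rmsTol = 0.01, seed = 5))
    for (kk in 1:3) {
        for (m in res$models[[kk]]) {
            expect_equal(sqrt(sum(m@coefficients^2)), 1, tolerance = 1e-9)
        }
    }
    # monotone capacity: best training Q never decreases with k
    expect_true(all(diff(res$bestQ) >= 0))
})

test_that("applying a model reproduces its training quality and metrics", {
    gen <- generateScoreTable(syntheticConfig(nMolecules = 600, nActive = 30,
                                              nScores = 3, seed = 13))
    tab <- gen$table
    model <- optimizeCoefficients(tab, c("score_01", "score_02"),
                                  searchConfig(k = 2, nStarts = 3,
                                               maxIter = 200, rmsTol = 0.01,
                                               seed = 3))
    app <- applyModel(model, tab)
    expect_identical(app$quality$q, trainQuality(model))

    # a one-column model with coefficient +1 reproduces the raw column ranking
    m1 <- new("ConsensusModel", subset = "score_03", coefficients = 1,
              center = 0, scale = 1, trainQ = 0, trainClusterActives = 0,
              trainMeanRank = 0, clusterSize = 100L, seed = 1L)
    app1 <- applyModel(m1, tab)
    expect_identical(app1$ranking@orderedIds,
                     rankMolecules(tab, scoreMatrix(tab)[, "score_03"])@orderedIds)

    # metrics agree with the independent oracles on the exported scores
    labels <- activityLabels(tab)
    ids <- moleculeIds(tab)
    expect_equal(app$auc, oracleAuc(app$combined, labels))
    expect_equal(app$profile$ef[1],
                 oracleEf(app$combined, labels, ids, 0.01))
    expect_equal(app$quality$q,
                 oracleQuality(app$combined, labels, ids, 100))

    missing <- ScoreTable(c("x", "y"), c(1, 0), cbind(other = c(1, 2)))
    expect_error(applyModel(model, missing), "score_01")
})

test_that("models serialize to JSON and restore exactly", {
    gen <- generateScoreTable(syntheticConfig(nMolecules = 200, nActive = 10,
                                              nScores = 2, seed = 14))
    model <- optimizeCoefficients(gen$table, scoreNames(gen$table),
                                  searchConfig(k = 2, nStarts = 2,
                                               maxIter = 100, rmsTol = 0.01,
                                               seed = 4))
    path <- withr::local_tempfile(fileext = ".json")
    writeConsensusModel(model, path)
    back <- readConsensusModel(path)
    expect_identical(back@coefficients, model@coefficients)
    expect_identical(back@center, model@center)
    expect_identical(back@scale, model@scale)
    expect_identical(back@subset, model@subset)
    expect_identical(trainQuality(back), trainQuality(model))
})
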