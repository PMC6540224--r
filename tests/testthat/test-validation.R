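test_that("stratified splits have the documented arithmetic", {
    gen <- generateScoreTable(syntheticConfig(seed = 17))
    splits <- makeSplits(gen$table, testFraction = 0.2, repeats = 5, seed = 1)
    labels <- activityLabels(gen$table)
    expect_length(splits, 5L)
    for (sp in splits) {
        expect_length(sp$test, 600L)
        expect_length(sp$train, 2400L)
        expect_equal(sum(labels[sp$test]), 16L)
        expect_equal(sum(labels[sp$train]), 64L)
    }
})

test_that("splits are deterministic, disjoint and stratified within one molecule", {
    for (seed in 1:20) {
        gen <- generateScoreTable(syntheticConfig(nMolecules = 200 + 17 * seed,
                                                  nActive = 9 + seed,
                                                  nScores = 2, seed = seed))
        tab <- gen$table
        labels <- activityLabels(tab)
        n <- nMolecules(tab)
        s1 <- makeSplits(tab, repeats = 3, seed = seed)
        s2 <- makeSplits(tab, repeats = 3, seed = seed)
        expect_identical(s1, s2)
        frac <- sum(labels) / n
        for (sp in s1) {
            expect_identical(sort(c(sp$train, sp$test)), seq_len(n))
            expect_length(intersect(sp$train, sp$test), 0L)
            expect_gte(sum(labels[sp$test]), 1L)
            expect_gte(sum(labels[sp$test] == 0), 1L)
            # stratification: class balance within one molecule of overall
            expect_lte(abs(sum(labels[sp$test]) - frac * length(sp$test)), 1)
            expect_lte(abs(sum(labels[sp$train]) - frac * length(sp$train)), 1)
        }
    }
    small <- ScoreTable(sprintf("m%02d", 1:20), c(rep(1, 3), rep(0, 17)),
                        cbind(s = rnorm(20)))
    expect_error(makeSplits(small, repeats = 5), "repeats")
})

test_that("validation selects the planted subset and averages are exact", {
    set.seed(30)
    n <- 800
    labels <- integer(n)
    t <- rnorm(n)
    labels[rank(-(t + rnorm(n, sd = 0.25))) <= 40] <- 1L
    tab <- ScoreTable(sprintf("m%04d", 1:n), labels,
                      cbind(sig1 = -t + rnorm(n, sd = 0.6),
                            sig2 = -t + rnorm(n, sd = 0.8),
                            junk1 = rnorm(n), junk2 = rnorm(n)))
    cfg <- searchConfig(k = 2, nStarts = 3, maxIter = 200, rmsTol = 0.01,
                        seed = 5)
    splits <- makeSplits(tab, repeats = 3, seed = 5)
    subsets <- enumerateSubsets(scoreNames(tab), 2)
    val <- validateSubsets(tab, subsets, splits, cfg)
    expect_identical(sort(val$selected), c("sig1", "sig2"))

    # reported averages equal manual recomputation from per-repeat rows
    for (key in unique(val$perRepeat$subset)) {
        rows <- val$perRepeat[val$perRepeat$subset == key, ]
        avg <- val$averages[val$averages$subset == key, ]
        for (col in c("ef1", "ef2", "ef5", "ef10", "ef20", "q", "auc")) {
            expect_equal(avg[[col]], mean(rows[[col]]))
        }
    }
    # the selected subset has the maximal average test quality
    expect_equal(val$averages$q[1], max(val$averages$q))

    # with a single repeat the average equals that repeat's value
    val1 <- validateSubsets(tab, subsets[1], splits[1], cfg)
    expect_equal(val1$averages$q, val1$perRepeat$q)
})

test_that("fitted models never depend on test rows", {
    gen <- generateScoreTable(syntheticConfig(nMolecules = 500, nActive = 25,
                                              nScores = 3, seed = 31))
    tab <- gen$table
    cfg <- searchConfig(k = 2, nStarts = 2, maxIter = 150, rmsTol = 0.01,
                        seed = 11)
    sp <- makeSplits(tab, repeats = 1, seed = 11)[[1]]
    subset <- c("score_01", "score_02")
    m1 <- optimizeCoefficients(tab, subset, cfg, rows = sp$train,
                               splitIndex = 1L)
    # perturb every test-row score wildly and refit
    scores <- scoreMatrix(tab)
    scores[sp$test, ] <- scores[sp$test, ] * 100 + 7
    tab2 <- ScoreTable(moleculeIds(tab), activityLabels(tab), scores)
    m2 <- optimizeCoefficients(tab2, subset, cfg, rows = sp$train,
                               splitIndex = 1L)
    expect_identical(m1@coefficients, m2@coefficients)
    expect_identical(m1@center, m2@center)
    expect_identical(m1@scale, m2@scale)
})

test_that("a failing subset is flagged and the run continues", {
    n <- 300
    set.seed(40)
    labels <- integer(n); labels[1:15] <- 1L
    tab <- ScoreTable(sprintf("m%03d", 1:n), labels,
                      cbind(good = -labels * 3 + rnorm(n),
                            flat = rep(1, n))) # zero variance: cannot fit
    cfg <- searchConfig(k = 1, nStarts = 2, maxIter = 50, rmsTol = 0.01,
                        seed = 2)
    splits <- makeSplits(tab, repeats = 2, seed = 2)
    val <- validateSubsets(tab, list("good", "flat"), splits, cfg)
    expect_identical(val$failed, "flat")
    expect_identical(val$selected, "good")
})

test_that("full-data refits match the metric oracles and the EF ceiling", {
    set.seed(41)
    n <- 1000
    z1 <- rnorm(n); z2 <- rnorm(n)
    labels <- as.integer(rank(-(0.6 * z1 + 0.8 * z2)) <= 30) # zero noise
    tab <- ScoreTable(sprintf("m%04d", 1:n), labels,
                      cbind(s1 = z1, s2 = z2))
    cfg <- searchConfig(k = 2, nStarts = 6, maxIter = 1000, rmsTol = 1e-3,
                        seed = 6)
    fin <- finalizeModel(tab, c("s1", "s2"), cfg)
    # perfect separation: EF1% hits the ceiling min(s,A)/s * (N/A)
    s <- ceiling(0.01 * n)
    expect_equal(fin$profile$ef[1], (min(s, 30) / s) * (n / 30))
    app <- applyModel(fin$model, tab)
    expect_equal(fin$auc, oracleAuc(app$combined, labels))
    expect_equal(fin$profile$ef,
                 vapply(c(0.01, 0.02, 0.05, 0.1, 0.2), function(f) {
                     oracleEf(app$combined, labels, moleculeIds(tab), f)
                 }, numeric(1)))
})

test_that("the end-to-end screen returns a coherent report", {
    gen <- generateScoreTable(syntheticConfig(nMolecules = 600, nActive = 30,
                                              nScores = 4, seed = 55))
    rep <- efoScreen(gen$table, searchConfig(k = 2, nStarts = 2, maxIter = 150,
                                             rmsTol = 0.01, seed = 9),
                     repeats = 3)
    expect_s4_class(rep, "ValidationReport")
    expect_identical(sort(modelSubset(finalModel(rep))), sort(rep@selected))
    expect_true(all(rep@averages$q[1] >= rep@averages$q))
    expect_equal(nrow(rep@finalProfile), 5L)
    expect_error(
        efoScreen(gen$table, searchConfig(k = 3, seed = 1), minEf5 = 1e9),
        "survive")
})
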