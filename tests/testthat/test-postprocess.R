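test_that("similarity matrix matches hand-enumerated co-clustering", {
    # 4 subjects, 2 iterations: {12|34} then {13|24}
    alloc <- rbind(c(1L, 1L, 2L, 2L),
                   c(1L, 2L, 1L, 2L))
    S <- similarityMatrix(alloc)
    expect_equal(diag(S), rep(1, 4))
    expect_equal(S[1, 2], 0.5)
    expect_equal(S[3, 4], 0.5)
    expect_equal(S[1, 3], 0.5)
    expect_equal(S[2, 4], 0.5)
    expect_equal(S[1, 4], 0)
    expect_equal(S[2, 3], 0)
    expect_identical(S, t(S))
    # all subjects together every iteration
    expect_equal(similarityMatrix(rbind(rep(1L, 3), rep(2L, 3))),
                 matrix(1, 3, 3))
})

test_that("similarity matrix is invariant to cluster relabelling", {
    set.seed(31)
    alloc <- matrix(sample(1:4, 200, replace = TRUE), 20, 10)
    perm <- rbind(c(4L, 2L, 1L, 3L))[rep(1, 20), ]
    relabelled <- matrix(perm[cbind(rep(1:20, 10), as.vector(alloc))],
                         20, 10)
    expect_equal(similarityMatrix(alloc), similarityMatrix(relabelled))
})

test_that("best partition recovers exact block structure", {
    S <- matrix(0, 6, 6)
    S[1:3, 1:3] <- 1
    S[4:6, 4:6] <- 1
    bp <- bestPartition(S, gRange = 1:4)
    expect_identical(sort(groupSizes(bp)), c(3L, 3L))
    expect_equal(bp@score, 0)
    expect_identical(groupLabels(bp)[1], groupLabels(bp)[2])
    expect_false(groupLabels(bp)[1] == groupLabels(bp)[4])
    # a similarity matrix of all ones collapses to a single group
    expect_identical(length(groupSizes(bestPartition(matrix(1, 5, 5),
                                                     gRange = 1:4))), 1L)
    expect_error(bestPartition(S, gRange = integer(0)), "range")
})

test_that("exhaustive best partition equals an independent brute force", {
    set.seed(32)
    for (i in 1:10) {
        n <- sample(4:7, 1)
        S <- randomSimilarity(n)
        bp <- bestPartition(S, gRange = 1:3, method = "exhaustive")
        expect_equal(bp@score, oracleBestScore(S, 3))
    }
})

test_that("pam route matches the optimum on clean two-block matrices", {
    set.seed(33)
    blocks <- rep(1:2, c(5, 4))
    S <- outer(blocks, blocks, "==") * 0.9 + 0.05
    diag(S) <- 1
    bp <- bestPartition(S, gRange = 1:4, method = "pam")
    expect_equal(bp@score, oracleBestScore(S, 4))
    expect_identical(sort(groupSizes(bp)), c(4L, 5L))
})

test_that("group risk draws average member risks per iteration", {
    # hand-built 2-iteration, 3-subject trace
    risk <- rbind(c(0.1, 0.2, 0.6),
                  c(0.3, 0.4, 0.5))
    fit <- new("ProfileRegressionFit",
               risk = risk,
               allocations = rbind(c(1L, 1L, 2L), c(1L, 1L, 2L)),
               imputed = matrix(integer(), 2, 0),
               missIndex = matrix(integer(), 0, 2),
               kOccupied = c(2L, 2L), alpha = c(1, 1), logLik = c(0, 0),
               acceptance = list(), mode = "plain",
               beta = matrix(numeric(), 2, 0),
               settings = list(), data = tinyDataset()[, 1:3])
    gd <- groupRiskDraws(fit, c(1L, 1L, 2L))
    expect_equal(unname(gd$groups[, 1]), c(0.15, 0.35))
    expect_equal(unname(gd$groups[, 2]), c(0.6, 0.5))
    expect_equal(gd$overall, c(0.3, 0.4))
    # single-group partition: group draw equals the overall average
    gd1 <- groupRiskDraws(fit, c(1L, 1L, 1L))
    expect_equal(unname(gd1$groups[, 1]), gd1$overall)
    expect_error(groupRiskDraws(fit, c(1L, 1L, 3L)), "empty")
})

test_that("exceedance probabilities use strict inequalities", {
    draws <- list(groups = cbind(c(0.2, 0.4), c(0.4, 0.5)),
                  overall = c(0.3, 0.4))
    ex <- exceedanceProbs(draws)
    # group 1 ties the overall at iteration 2: the tie counts to no side
    expect_equal(ex$pAbove[1], 0)
    expect_equal(ex$pBelow[1], 0.5)
    expect_equal(ex$pAbove[2], 1)
})

test_that("posterior odds ratio follows the defining formula", {
    expect_equal(posteriorOR(rep(0.5, 4), rep(0.5, 4))$mean, 1)
    orp <- posteriorOR(rep(0.15, 10), rep(0.09, 10))
    expect_equal(orp$mean, (0.15 * 0.91) / (0.09 * 0.85), tolerance = 1e-12)
    expect_equal(unname(orp$ci), rep(orp$mean, 2))
    expect_error(posteriorOR(c(0.5, 1), c(0.5, 0.5)), "degenerate")
    # monotone in the group draws, reference fixed
    set.seed(34)
    ref <- runif(50, 0.05, 0.2)
    g1 <- runif(50, 0.2, 0.4)
    expect_true(all(posteriorOR(g1 + 0.1, ref)$or > posteriorOR(g1, ref)$or))
})

test_that("profile deviations vanish for the whole-sample group", {
    sim <- syntheticPreset("separable", n = 80, seed = 35)
    fit <- profileRegression(sim$data, nIter = 200, burnIn = 100, thin = 2,
                             truncation = 6, seed = 35)
    dev <- profileDeviations(fit, rep(1L, 80))
    expect_true(all(abs(dev$mean) < 1e-12))
    expect_true(all(dev$class == "zero"))
})

test_that("profile deviation intervals match order statistics by hand", {
    sp <- binarySpecs(1)
    X <- cbind(f1 = c(0L, 1L, NA))
    pd <- ProfileDataset(X, c(1L, 0L, 0L), sp)
    fit <- new("ProfileRegressionFit",
               risk = matrix(0.2, 2, 3),
               allocations = matrix(1L, 2, 3),
               imputed = rbind(0L, 1L),
               missIndex = cbind(3L, 1L),
               kOccupied = c(1L, 1L), alpha = c(1, 1), logLik = c(0, 0),
               acceptance = list(), mode = "plain",
               beta = matrix(numeric(), 2, 0),
               settings = list(), data = pd)
    dev <- profileDeviations(fit, c(1L, 1L, 2L))
    # group 1 = subjects 1,2 (one of each category, constant);
    # group 2 = subject 3, imputed 0 then 1
    g2cat0 <- dev[dev$group == 2 & dev$category == 0, ]
    # iteration 1: freq 1 vs overall 2/3; iteration 2: 0 vs 1/3
    expect_equal(g2cat0$lower, quantile(c(1 - 2 / 3, 0 - 1 / 3), 0.025,
                                        names = FALSE))
    expect_equal(g2cat0$upper, quantile(c(1 / 3, -1 / 3), 0.975,
                                        names = FALSE))
})

test_that("squared-residual score behaves as a fit criterion", {
    y <- rep(c(1, 0), c(63, 482))
    expect_equal(residualFitScore(y, y), 0)
    expect_equal(residualFitScore(rep(0.5, 10), rep(1, 10)), 10 / 4)
    p <- rep(63 / 545, 545)
    expect_equal(residualFitScore(p, y), 545 * (63 / 545) * (482 / 545),
                 tolerance = 1e-12)
})
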