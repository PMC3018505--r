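test_that("threshold-induced ordinal probabilities follow the normal CDF", {
    expect_equal(ordinalProbs(0), c(0.5, 0.5))
    expect_equal(ordinalProbs(c(-1, 1)),
                 c(pnorm(-1), pnorm(1) - pnorm(-1), 1 - pnorm(1)))
    expect_error(ordinalProbs(c(1, 0)), "increasing")
    # telescoping: sums to 1 for arbitrary valid thresholds
    set.seed(1)
    for (i in 1:20) {
        th <- sort(rnorm(sample(1:5, 1), sd = 2))
        th <- th + seq_along(th) * 1e-6  # enforce strictness under ties
        expect_equal(sum(ordinalProbs(th)), 1, tolerance = 1e-12)
    }
})

test_that("probability-to-threshold map is the exact inverse", {
    expect_equal(probsToThresholds(c(0.5, 0.5)), 0)
    expect_equal(probsToThresholds(rep(0.25, 4)),
                 c(qnorm(0.25), 0, qnorm(0.75)))
    expect_error(probsToThresholds(c(0.5, 0, 0.5)), "zero-probability")
    set.seed(2)
    for (i in 1:50) {
        M <- sample(2:6, 1)
        p <- as.numeric(samplePhiPosterior(rep(0, M), prior = 1))
        expect_equal(ordinalProbs(probsToThresholds(p)), p,
                     tolerance = 1e-10)
    }
})

test_that("profile log-likelihood composes covariates and skips missing", {
    sp <- data.frame(kind = c("nominal", "ordinal"),
                     nCategories = c(2L, 2L), stringsAsFactors = FALSE)
    params <- list(list(probs = c(0.8, 0.2)), list(thresholds = 0))
    expect_equal(profileLogLik(c(0L, 1L), params, sp), log(0.8) + log(0.5))
    expect_equal(profileLogLik(c(NA, NA), params, sp), 0)
    expect_equal(profileLogLik(c(0L, NA), params, sp), log(0.8))
    expect_error(profileLogLik(c(2L, 0L), params, sp), "outside")
    # permutation invariance over covariate order
    sp3 <- data.frame(kind = c("nominal", "ordinal", "nominal"),
                      nCategories = c(2L, 3L, 3L), stringsAsFactors = FALSE)
    par3 <- list(list(probs = c(0.7, 0.3)),
                 list(thresholds = c(-0.5, 0.7)),
                 list(probs = c(0.2, 0.3, 0.5)))
    x <- c(1L, 2L, 0L)
    perm <- c(3L, 1L, 2L)
    expect_equal(profileLogLik(x, par3, sp3),
                 profileLogLik(x[perm], par3[perm],
                               sp3[perm, , drop = FALSE]))
})

test_that("Dirichlet posterior draws have the conjugate mean", {
    set.seed(3)
    draws <- t(replicate(10000, samplePhiPosterior(c(0, 0), prior = 1)))
    expect_lt(max(abs(colMeans(draws) - 0.5)), 0.01)
    draws <- t(replicate(10000, samplePhiPosterior(c(98, 2), prior = 1)))
    expect_lt(max(abs(colMeans(draws) - c(99, 3) / 102)), 0.01)
    set.seed(7)
    a <- samplePhiPosterior(c(3, 1, 4), prior = 1)
    set.seed(7)
    expect_identical(samplePhiPosterior(c(3, 1, 4), prior = 1), a)
})

test_that("threshold chain with no data samples the prior on the simplex", {
    # prior on induced probabilities is uniform on the simplex; the chain
    # run on zero counts must reproduce its category-probability means
    set.seed(4)
    M <- 3L
    th <- probsToThresholds(rep(1 / M, M))
    acc <- 0
    probs <- matrix(NA_real_, 20000, M)
    for (i in seq_len(20000)) {
        up <- updateThresholds(th, counts = rep(0, M), proposalScale = 0.8)
        th <- up$thresholds
        probs[i, ] <- ordinalProbs(th)
        acc <- acc + mean(up$accepted)
    }
    direct <- t(replicate(20000, samplePhiPosterior(rep(0, M), prior = 1)))
    expect_lt(max(abs(colMeans(probs) - colMeans(direct))), 0.02)
})

test_that("threshold posterior concentrates correctly with balanced data", {
    set.seed(5)
    th <- 0.3
    keep <- numeric(4000)
    for (i in seq_len(4000)) {
        th <- updateThresholds(th, counts = c(1000, 1000),
                               proposalScale = 0.05)$thresholds
        keep[i] <- pnorm(th)
    }
    ci <- quantile(keep[-(1:500)], c(0.025, 0.975))
    expect_lt(ci[1], 0.5)
    expect_gt(ci[2], 0.5)
    expect_lt(diff(ci), 0.1)
})

test_that("zero proposal scale leaves thresholds unchanged and accepted", {
    up <- updateThresholds(c(-0.5, 0.5), counts = c(3, 4, 5),
                           proposalScale = 0)
    expect_identical(up$thresholds, c(-0.5, 0.5))
    expect_true(all(up$accepted))
})

test_that("binary ordinal model matches the Beta conjugate oracle", {
    # with M=2 the ordered-threshold model is a reparameterised Bernoulli:
    # the sampled Phi(lambda) must follow Beta(1+k1, 1+k2)
    set.seed(6)
    counts <- c(18, 42)
    th <- 0
    draws <- numeric(20000)
    for (i in seq_len(40000)) {
        th <- updateThresholds(th, counts = counts,
                               proposalScale = 0.25)$thresholds
        if (i > 20000) draws[i - 20000] <- pnorm(th)
    }
    oracle <- rbeta(20000, 1 + counts[1], 1 + counts[2])
    ks <- suppressWarnings(stats::ks.test(draws, oracle)$statistic)
    expect_lt(unname(ks), 0.05)
})
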