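# Small builders shared across test files. Everything is generated in code;
# no fixture files.

binarySpecs <- function(P, names = paste0("f", seq_len(P))) {
    data.frame(name = names, kind = "nominal", nCategories = 2L,
               stringsAsFactors = FALSE)
}

# A tiny complete dataset with known codes.
tinyDataset <- function() {
    sp <- data.frame(name = c("exposure", "dose"),
                     kind = c("nominal", "ordinal"),
                     nCategories = c(2L, 3L),
                     stringsAsFactors = FALSE)
    X <- cbind(exposure = c(0L, 1L, 1L, 0L, 1L, 0L),
               dose = c(0L, 2L, 1L, 0L, 2L, 1L))
    ProfileDataset(X, y = c(1, 0, 0, 1, 0, 0), specs = sp)
}

# A dataset with exactly the given case/control counts and covariates drawn
# from one population cluster (no risk structure).
countedDataset <- function(nCases, nControls, seed = 1) {
    set.seed(seed)
    n <- nCases + nControls
    sp <- data.frame(name = c("a", "b"),
                     kind = c("nominal", "ordinal"),
                     nCategories = c(2L, 3L),
                     stringsAsFactors = FALSE)
    X <- cbind(a = rbinom(n, 1L, 0.3),
               b = sample(0:2, n, replace = TRUE))
    y <- rep(c(1L, 0L), c(nCases, nControls))
    ProfileDataset(X, y, sp)
}

# Brute-force best partition: enumerate every set partition of n items with
# at most maxG blocks recursively (independent of the package's iterative
# enumerator) and return the minimal least-squares score.
oracleBestScore <- function(S, maxG) {
    n <- nrow(S)
    best <- Inf
    recurse <- function(labels, i, used) {
        if (i > n) {
            A <- outer(labels, labels, "==")
            ut <- upper.tri(S)
            sc <- sum((S[ut] - A[ut])^2)
            if (sc < best) best <<- sc
            return(invisible(NULL))
        }
        for (g in seq_len(min(used + 1L, maxG))) {
            labels[i] <- g
            recurse(labels, i + 1L, max(used, g))
        }
    }
    recurse(integer(n), 1L, 0L)
    best
}

# Random symmetric similarity-like matrix in [0,1] with unit diagonal.
randomSimilarity <- function(n) {
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    S
}

# Effective-sample-size-aware z-score between the means of two draw vectors.
# The second vector may be autocorrelated (batch-means standard error).
momentZ <- function(iid, chain, nBatch = 50) {
    bm <- function(x) {
        nb <- min(nBatch, floor(length(x) / 2))
        b <- floor(length(x) / nb)
        means <- vapply(seq_len(nb), function(i)
            mean(x[((i - 1) * b + 1):(i * b)]), 1)
        stats::sd(means) / sqrt(nb)
    }
    se <- sqrt(stats::sd(iid)^2 / length(iid) + bm(chain)^2)
    (mean(iid) - mean(chain)) / se
}
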