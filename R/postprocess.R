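#' Posterior similarity matrix
#'
#' The n x n matrix whose (i, j) cell is the fraction of retained iterations
#' in which subjects i and j share a cluster. It estimates the posterior
#' co-clustering probability and is invariant to cluster relabelling and to
#' the varying number of clusters across iterations.
#'
#' @param fit a [ProfileRegressionFit-class] (or an iterations x subjects
#'   allocation matrix).
#' @return a symmetric numeric matrix with unit diagonal.
#' @export
similarityMatrix <- function(fit) {
    alloc <- if (is(fit, "ProfileRegressionFit")) fit@allocations
             else as.matrix(fit)
    TT <- nrow(alloc)
    if (!TT) stop("no retained iterations")
    n <- ncol(alloc)
    maxK <- max(alloc)
    # one sparse subject x (iteration, cluster) indicator; its cross-product
    # counts co-clustering events across all iterations at once
    j <- as.integer(t(alloc)) + rep(seq_len(TT) - 1L, each = n) * maxK
    Z <- Matrix::sparseMatrix(i = rep_len(seq_len(n), n * TT), j = j,
                              x = 1, dims = c(n, TT * maxK))
    S <- as.matrix(Matrix::tcrossprod(Z)) / TT
    dimnames(S) <- NULL
    diag(S) <- 1
    S
}

.partitionScore <- function(S, labels) {
    A <- outer(labels, labels, "==")
    ut <- upper.tri(S)
    sum((S[ut] - A[ut])^2)
}

.relabelBySize <- function(labels) {
    sz <- table(labels)
    ord <- order(-as.integer(sz), as.integer(names(sz)))
    match(labels, as.integer(names(sz))[ord])
}

# Enumerate set partitions of n items with at most maxG blocks (restricted
# growth strings), calling f(labels) on each.
.forEachPartition <- function(n, maxG, f) {
    if (n == 1L) {
        f(1L)
        return(invisible(NULL))
    }
    a <- rep(1L, n)
    b <- rep(1L, n)        # b[i] = max(a[1..i-1]) + 1
    repeat {
        for (j in 2L:n) b[j] <- max(b[j - 1L], a[j - 1L] + 1L)
        f(a)
        # next restricted growth string
        i <- n
        while (i > 1L && (a[i] >= b[i] || a[i] >= maxG)) i <- i - 1L
        if (i == 1L) break
        a[i] <- a[i] + 1L
        if (i < n) a[(i + 1L):n] <- 1L
    }
    invisible(NULL)
}

#' Deterministic best partition matching the similarity matrix
#'
#' Finds a single representative clustering that most closely matches the
#' posterior similarity matrix, scoring a candidate partition by the
#' least-squares discrepancy \eqn{\sum_{i<j} (S_{ij} - A_{ij})^2} where
#' \eqn{A_{ij} = 1} when subjects i and j share a group. For each group count
#' in `gRange` a partitioning-around-medoids clustering of the dissimilarity
#' `1 - S` is computed (deterministic BUILD initialisation plus SWAP); the
#' best-scoring partition over the range is returned. For small problems
#' (`n <= 8`) all set partitions with at most `max(gRange)` groups are
#' enumerated instead, guaranteeing the global optimum.
#'
#' @param S a similarity matrix from [similarityMatrix()].
#' @param gRange integer vector of candidate group counts (default `1:10`).
#' @param method `"auto"` (exhaustive when `n <= 8`, else PAM),
#'   `"pam"`, or `"exhaustive"`.
#' @return a [BestPartition-class]; labels are renumbered by decreasing group
#'   size.
#' @export
bestPartition <- function(S, gRange = 1:10, method = c("auto", "pam",
                                                       "exhaustive")) {
    method <- match.arg(method)
    S <- as.matrix(S)
    n <- nrow(S)
    if (!length(gRange)) stop("empty group-count range")
    gRange <- sort(unique(as.integer(gRange)))
    gRange <- gRange[gRange >= 1L & gRange <= n]
    if (!length(gRange)) stop("no feasible group count in range")
    if (method == "auto") method <- if (n <= 8L) "exhaustive" else "pam"
    if (method == "exhaustive") {
        if (n > 12L) stop("exhaustive enumeration is limited to n <= 12")
        best <- NULL
        bestScore <- Inf
        .forEachPartition(n, max(gRange), function(a) {
            if (!(length(unique(a)) %in% gRange)) return(invisible(NULL))
            sc <- .partitionScore(S, a)
            if (sc < bestScore) {
                bestScore <<- sc
                best <<- a
            }
        })
        labels <- best
        score <- bestScore
    } else {
        d <- stats::as.dist(1 - S)
        best <- NULL
        score <- Inf
        for (G in gRange) {
            labels <- if (G == 1L) rep(1L, n)
                      else if (G == n) seq_len(n)
                      else cluster::pam(d, k = G, diss = TRUE,
                                        do.swap = TRUE,
                                        cluster.only = TRUE)
            sc <- .partitionScore(S, labels)
            if (sc < score - 1e-12) {
                score <- sc
                best <- labels
            }
        }
        labels <- best
    }
    labels <- .relabelBySize(labels)
    new("BestPartition", labels = as.integer(labels),
        groupSizes = as.integer(table(labels)),
        score = score, method = method)
}

.labelsOf <- function(partition, n) {
    labels <- if (is(partition, "BestPartition")) partition@labels
              else as.integer(partition)
    if (length(labels) != n)
        stop("partition labels must cover all subjects in the trace")
    if (any(tabulate(labels, max(labels)) == 0L))
        stop("empty group in partition")
    labels
}

#' Per-group posterior risk draws
#'
#' For each retained iteration the group risk is the average of the
#' per-subject risks of the group's members at that iteration, and the
#' whole-sample average risk is the same average over all subjects. A group
#' whose members are usually co-clustered yields a narrow posterior; a group
#' the sampler usually splits yields a wide one.
#'
#' @param fit a [ProfileRegressionFit-class].
#' @param partition a [BestPartition-class] or an integer label vector.
#' @return a list with `groups` (iterations x G matrix of group risk draws)
#'   and `overall` (the per-iteration whole-sample average risk).
#' @export
groupRiskDraws <- function(fit, partition) {
    r <- riskDraws(fit)
    labels <- .labelsOf(partition, ncol(r))
    G <- max(labels)
    sizes <- tabulate(labels, G)
    draws <- r %*% outer(labels, seq_len(G), "==")
    draws <- sweep(draws, 2L, sizes, "/")
    colnames(draws) <- paste0("group", seq_len(G))
    list(groups = draws, overall = rowMeans(r))
}

#' Exceedance probabilities against the whole-sample average risk
#'
#' The posterior probability that a group's risk lies above (below) the
#' whole-sample average risk, computed from the per-iteration draws. A value
#' of `pAbove` close to 1 (above 0.9, say) is strong evidence of a high-risk
#' group; similarly `pBelow` for a low-risk group. Ties count to neither
#' side.
#'
#' @param draws the list returned by [groupRiskDraws()].
#' @return a data.frame with columns `group`, `pAbove`, `pBelow`.
#' @export
exceedanceProbs <- function(draws) {
    gg <- draws$groups
    ov <- draws$overall
    stopifnot(nrow(gg) == length(ov))
    data.frame(group = seq_len(ncol(gg)),
               pAbove = colMeans(gg > ov),
               pBelow = colMeans(gg < ov))
}

#' Posterior odds ratio between two groups
#'
#' At each retained iteration the odds ratio
#' \eqn{OR = \theta_g (1 - \theta_{ref}) / (\theta_{ref} (1 - \theta_g))}
#' compares the group's odds of disease with a reference group (typically the
#' lowest-risk group). The posterior is summarised by its mean, an
#' equal-tailed 95% credible interval, and the probability that the OR
#' exceeds 1.
#'
#' @param groupDraws,referenceDraws numeric vectors of per-iteration risk
#'   draws on the probability scale, strictly inside (0, 1).
#' @return a list with `mean`, `ci` (length 2), `pGreater1` and the raw `or`
#'   draws.
#' @export
posteriorOR <- function(groupDraws, referenceDraws) {
    stopifnot(length(groupDraws) == length(referenceDraws))
    if (any(c(groupDraws, referenceDraws) <= 0) ||
        any(c(groupDraws, referenceDraws) >= 1))
        stop("risk draws at 0 or 1 give degenerate odds")
    or <- (groupDraws * (1 - referenceDraws)) /
        (referenceDraws * (1 - groupDraws))
    list(mean = mean(or),
         ci = unname(quantile(or, c(0.025, 0.975))),
         pGreater1 = mean(or > 1),
         or = or)
}

#' Per-covariate profile deviations of each group from the population
#'
#' For every group, covariate and category, the equal-tailed 95% credible
#' interval of the difference between the group's category probability and
#' the whole-sample average probability at the same iteration. Probabilities
#' are the per-iteration empirical category frequencies of the
#' imputation-completed covariates of the group's members (well defined even
#' when a best-partition group spans several sampler clusters within an
#' iteration). A positive interval excluding zero marks an attribute more
#' common in the group than in the population, a negative one less common.
#' Across-iteration variability stems from the imputed entries: for a fully
#' observed covariate the interval degenerates to a point, so interpret the
#' `class` column together with the size of `mean`.
#'
#' @param fit a [ProfileRegressionFit-class].
#' @param partition a [BestPartition-class] or integer label vector.
#' @param level credible level (default 0.95).
#' @return a data.frame with columns `group`, `covariate`, `category`,
#'   `mean`, `lower`, `upper` and `class`
#'   (`"positive"`/`"negative"`/`"zero"`).
#' @export
profileDeviations <- function(fit, partition, level = 0.95) {
    data <- fit@data
    X0 <- covariateMatrix(data)
    specs <- covariateSpecs(data)
    n <- nrow(X0); P <- ncol(X0)
    labels <- .labelsOf(partition, n)
    G <- max(labels)
    sizes <- tabulate(labels, G)
    TT <- nrow(fit@risk)
    a <- (1 - level) / 2
    miss <- fit@missIndex
    out <- vector("list", P)
    for (p in seq_len(P)) {
        M <- specs$nCategories[p]
        obs <- which(!is.na(X0[, p]))
        base <- matrix(0, G, M)   # constant counts from observed entries
        if (length(obs)) {
            tb <- tabulate(labels[obs] + G * X0[obs, p], G * M)
            base <- matrix(tb, G, M)
        }
        mi <- which(miss[, 2L] == p)
        if (length(mi)) {
            gMiss <- labels[miss[mi, 1L]]
            imp <- fit@imputed[, mi, drop = FALSE]
            # per-iteration group x category counts of the imputed entries
            freqG <- array(0, c(TT, G, M))
            for (t in seq_len(TT)) {
                tb <- tabulate(gMiss + G * imp[t, ], G * M)
                freqG[t, , ] <- base + matrix(tb, G, M)
            }
        } else {
            freqG <- array(rep(base, each = TT), c(TT, G, M))
        }
        freqG <- sweep(freqG, 2L, sizes, "/")
        overall <- apply(sweep(freqG, 2L, sizes, "*"), c(1, 3), sum) / n
        rows <- vector("list", G * M)
        for (g in seq_len(G)) for (m in seq_len(M)) {
            d <- freqG[, g, m] - overall[, m]
            qs <- quantile(d, c(a, 1 - a), names = FALSE)
            cls <- if (qs[1] > 0) "positive"
                   else if (qs[2] < 0) "negative" else "zero"
            rows[[(g - 1L) * M + m]] <- data.frame(
                group = g, covariate = specs$name[p], category = m - 1L,
                mean = mean(d), lower = qs[1], upper = qs[2], class = cls,
                stringsAsFactors = FALSE)
        }
        out[[p]] <- do.call(rbind, rows)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Squared-residual model-fit score
#'
#' Sum of squared differences between the observed binary outcomes and the
#' fitted outcome probabilities, \eqn{\sum_i (y_i - \hat p_i)^2} — a
#' logistic-regression-type residual criterion comparable across models
#' fitted to the same subjects (lower is better). For a profile regression
#' fit the posterior mean per-subject risk [subjectRisk()] is the natural
#' `p`.
#'
#' @param p fitted outcome probabilities.
#' @param y binary outcomes.
#' @export
residualFitScore <- function(p, y) {
    stopifnot(length(p) == length(y))
    sum((y - p)^2)
}

#' Summarise the groups of a best partition
#'
#' Combines [groupRiskDraws()], [exceedanceProbs()] and [posteriorOR()] into
#' one table: per group its size, posterior mean risk with 95% credible
#' interval, exceedance probabilities against the whole-sample average risk,
#' and the posterior odds ratio (with credible interval and `P(OR > 1)`)
#' against the reference group. The reference is the group with the lowest
#' posterior mean risk by default; its OR against itself is exactly 1.
#'
#' @param fit a [ProfileRegressionFit-class].
#' @param partition a [BestPartition-class] or integer label vector.
#' @param reference `"lowest"` or an explicit group number.
#' @return a data.frame, one row per group.
#' @export
groupSummary <- function(fit, partition, reference = "lowest") {
    draws <- groupRiskDraws(fit, partition)
    G <- ncol(draws$groups)
    means <- colMeans(draws$groups)
    ref <- if (identical(reference, "lowest")) which.min(means)
           else as.integer(reference)
    stopifnot(ref >= 1L, ref <= G)
    ex <- exceedanceProbs(draws)
    rows <- lapply(seq_len(G), function(g) {
        orp <- posteriorOR(draws$groups[, g], draws$groups[, ref])
        ci <- quantile(draws$groups[, g], c(0.025, 0.975), names = FALSE)
        data.frame(group = g,
                   size = sum(.labelsOf(partition,
                                        ncol(fit@risk)) == g),
                   risk = means[g], riskLower = ci[1], riskUpper = ci[2],
                   pAbove = ex$pAbove[g], pBelow = ex$pBelow[g],
                   or = if (g == ref) 1 else orp$mean,
                   orLower = if (g == ref) 1 else orp$ci[1],
                   orUpper = if (g == ref) 1 else orp$ci[2],
                   pOrGreater1 = if (g == ref) NA_real_ else orp$pGreater1,
                   reference = g == ref)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
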