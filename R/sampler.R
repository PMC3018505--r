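# Blocked Gibbs sampler for the truncated stick-breaking Dirichlet process
# mixture. Internal state is a plain list; the exported surface is
# profileRegression(). Sweep order per iteration: allocations -> stick
# weights/concentration -> cluster profile parameters (phi, thresholds) ->
# disease parameters (theta, beta) -> imputation of missing covariates.

.prepData <- function(data) {
    X0 <- covariateMatrix(data)
    specs <- covariateSpecs(data)
    miss <- which(is.na(X0), arr.ind = TRUE)
    list(X1 = X0 + 1L,                       # 1-based codes, NA at missing
         y = outcome(data),
         W = confounders(data),
         M = specs$nCategories,
         kind = specs$kind,
         names = specs$name,
         missIdx = miss,
         n = nrow(X0), P = ncol(X0), Q = ncol(confounders(data)))
}

.defaultSettings <- function() {
    list(truncation = 50L, initClusters = 10L,
         alphaPrior = c(2, 1),
         thetaBetaPrior = c(1, 1),
         thetaNormalPrior = c(0, 10),
         betaNormalPrior = c(0, 10),
         thresholdScale = 0.25, thetaScale = 0.4, betaScale = 0.1,
         tailWarn = 1e-4)
}

.marginalFreq <- function(x1, M, n) {
    f <- tabulate(x1[!is.na(x1)], M)
    f <- pmax(f, 0.5) # keep strictly positive for threshold conversion
    f / sum(f)
}

.initState <- function(dat, settings, mode) {
    K <- settings$truncation
    n <- dat$n
    Xc <- dat$X1
    phi <- vector("list", dat$P)
    lambda <- vector("list", dat$P)
    lamScale <- vector("list", dat$P)
    for (p in seq_len(dat$P)) {
        M <- dat$M[p]
        f <- .marginalFreq(dat$X1[, p], M, n)
        if (any(is.na(Xc[, p]))) {
            idx <- which(is.na(Xc[, p]))
            Xc[idx, p] <- sample.int(M, length(idx), replace = TRUE, prob = f)
        }
        phi[[p]] <- matrix(f, K, M, byrow = TRUE)
        if (dat$kind[p] == "ordinal") {
            lambda[[p]] <- matrix(probsToThresholds(f), K, M - 1L,
                                  byrow = TRUE)
            lamScale[[p]] <- matrix(settings$thresholdScale, K, M - 1L)
        }
    }
    prev <- min(max(mean(dat$y), 0.02), 0.98)
    theta <- if (mode == "plain") rep(prev, K) else rep(qlogis(prev), K)
    state <- list(
        K = K,
        z = sample.int(min(settings$initClusters, K), n, replace = TRUE),
        v = rep(0.5, K - 1L), w = rep(1 / K, K),
        alpha = 1,
        phi = phi, lambda = lambda, lamScale = lamScale,
        theta = theta, beta = rep(0, dat$Q),
        thetaScale = rep(settings$thetaScale, K),
        Xc = Xc, mode = mode, logLik = NA_real_,
        accLambda = c(0, 0), accTheta = c(0, 0), accBeta = c(0, 0))
    .updateWeightsAlpha(state, settings)
}

.updateAllocations <- function(state, dat) {
    n <- dat$n; K <- state$K
    L <- matrix(log(state$w), n, K, byrow = TRUE)
    for (p in seq_len(dat$P)) {
        lp <- t(log(pmax(state$phi[[p]], 1e-300)))   # M x K
        L <- L + lp[state$Xc[, p], , drop = FALSE]
    }
    y <- dat$y
    if (state$mode == "plain") {
        L <- L + outer(y, log(state$theta)) +
            outer(1 - y, log1p(-state$theta))
    } else {
        off <- if (dat$Q) drop(dat$W %*% state$beta) else 0
        eta <- outer(if (dat$Q) off else rep(0, n), state$theta, "+")
        L <- L + y * plogis(eta, log.p = TRUE) +
            (1 - y) * plogis(-eta, log.p = TRUE)
    }
    gum <- -log(-log(matrix(runif(n * K), n, K)))
    state$z <- max.col(L + gum, ties.method = "first")
    # complete-data log-likelihood at the chosen allocations (diagnostic)
    state$logLik <- sum(L[cbind(seq_len(n), state$z)])
    state
}

.updateWeightsAlpha <- function(state, settings) {
    K <- state$K
    nk <- tabulate(state$z, K)
    nGt <- rev(cumsum(rev(nk)))          # n in clusters >= k
    tailK <- c(nGt[-1L], 0L)             # n in clusters > k
    v <- rbeta(K - 1L, 1 + nk[-K], state$alpha + tailK[-K])
    v <- pmin(pmax(v, 1e-12), 1 - 1e-12)
    state$v <- v
    state$w <- c(v, 1) * cumprod(c(1, 1 - v))
    a0 <- settings$alphaPrior[1]; b0 <- settings$alphaPrior[2]
    state$alpha <- rgamma(1L, a0 + K - 1L, b0 - sum(log1p(-v)))
    state
}

.xlogy <- function(x, y) ifelse(x == 0, 0, x * log(pmax(y, 1e-300)))

.updateClusterParams <- function(state, dat, adapt = FALSE, adaptRate = 0.05) {
    K <- state$K
    for (p in seq_len(dat$P)) {
        M <- dat$M[p]
        counts <- matrix(tabulate(state$z + K * (state$Xc[, p] - 1L), K * M),
                         K, M)
        if (dat$kind[p] == "nominal") {
            g <- matrix(rgamma(K * M, shape = counts + 1), K, M)
            state$phi[[p]] <- g / rowSums(g)
        } else {
            lam <- state$lambda[[p]]
            sc <- state$lamScale[[p]]
            for (j in seq_len(M - 1L)) {
                prop <- lam[, j] + rnorm(K, 0, sc[, j])
                lo <- if (j == 1L) rep(-Inf, K) else lam[, j - 1L]
                hi <- if (j == M - 1L) rep(Inf, K) else lam[, j + 1L]
                ok <- prop > lo & prop < hi
                phiLo <- if (j == 1L) 0 else pnorm(lam[, j - 1L])
                phiHi <- if (j == M - 1L) 1 else pnorm(lam[, j + 1L])
                phiCur <- pnorm(lam[, j]); phiProp <- pnorm(prop)
                dCur <- .xlogy(counts[, j], phiCur - phiLo) +
                    .xlogy(counts[, j + 1L], phiHi - phiCur) +
                    dnorm(lam[, j], log = TRUE)
                dProp <- .xlogy(counts[, j], phiProp - phiLo) +
                    .xlogy(counts[, j + 1L], phiHi - phiProp) +
                    dnorm(prop, log = TRUE)
                acc <- ok & (log(runif(K)) < dProp - dCur)
                lam[acc, j] <- prop[acc]
                state$accLambda <- state$accLambda + c(sum(acc), K)
                if (adapt) {
                    sc[, j] <- sc[, j] *
                        exp(adaptRate * (as.numeric(acc) - 0.44))
                    state$lamScale[[p]] <- sc
                }
            }
            state$lambda[[p]] <- lam
            Phi <- pnorm(lam)
            if (!is.matrix(Phi)) Phi <- matrix(Phi, K, M - 1L)
            state$phi[[p]] <- cbind(Phi, 1) - cbind(0, Phi)
        }
    }
    state
}

.updateDisease <- function(state, dat, settings, adapt = FALSE,
                           adaptRate = 0.05) {
    K <- state$K
    if (state$mode == "plain") {
        nk <- tabulate(state$z, K)
        cases <- tabulate(state$z[dat$y == 1L], K)
        a <- settings$thetaBetaPrior[1]; b <- settings$thetaBetaPrior[2]
        th <- rbeta(K, a + cases, b + nk - cases)
        state$theta <- pmin(pmax(th, 1e-12), 1 - 1e-12)
    } else {
        upd <- updateThetaBetaLogistic(
            state$theta, state$beta, state$z, dat$y, dat$W,
            scales = list(theta = state$thetaScale, beta = settings$betaScale),
            priorSD = list(theta = settings$thetaNormalPrior[2],
                           beta = settings$betaNormalPrior[2]),
            priorMean = list(theta = settings$thetaNormalPrior[1],
                             beta = settings$betaNormalPrior[1]))
        state$theta <- upd$theta
        state$beta <- upd$beta
        moved <- !is.na(upd$acceptedTheta)
        state$accTheta <- state$accTheta +
            c(sum(upd$acceptedTheta[moved]), sum(moved))
        state$accBeta <- state$accBeta +
            c(sum(upd$acceptedBeta), length(upd$acceptedBeta))
        if (adapt && any(moved))
            state$thetaScale[moved] <- state$thetaScale[moved] *
                exp(adaptRate * (as.numeric(upd$acceptedTheta[moved]) - 0.3))
    }
    state
}

.imputeMissing <- function(state, dat) {
    miss <- dat$missIdx
    if (!nrow(miss)) return(state)
    for (p in unique(miss[, 2L])) {
        idx <- miss[miss[, 2L] == p, 1L]
        M <- dat$M[p]
        pr <- state$phi[[p]][state$z[idx], , drop = FALSE]
        cs <- pr %*% upper.tri(diag(M), diag = TRUE)
        u <- runif(length(idx))
        state$Xc[idx, p] <- as.integer(pmin.int(1L + rowSums(cs < u), M))
    }
    state
}

.gibbsSweep <- function(state, dat, settings, adapt = FALSE) {
    state <- .updateAllocations(state, dat)
    state <- .updateWeightsAlpha(state, settings)
    state <- .updateClusterParams(state, dat, adapt = adapt)
    state <- .updateDisease(state, dat, settings, adapt = adapt)
    .imputeMissing(state, dat)
}

.subjectRisk <- function(state) {
    if (state$mode == "plain") state$theta[state$z]
    else plogis(state$theta[state$z])
}

#' Fit a Bayesian profile regression model by MCMC
#'
#' Runs the blocked Gibbs sampler for the joint assignment/disease model. The
#' number of clusters is not fixed: a Dirichlet process mixture, represented
#' by truncated stick-breaking weights, lets the occupied cluster count adapt
#' to the structure of the data, with the outcome informing cluster
#' membership alongside the covariate profiles. Each sweep resamples, in
#' order: the allocations `z`; the stick weights and the concentration
#' parameter `alpha` (Gamma hyperprior, conjugate update); the per-cluster
#' category probabilities (Dirichlet conjugate for nominal covariates,
#' ordered-threshold Metropolis for ordinal ones); the disease parameters
#' (Beta conjugate in plain mode, Metropolis on log-odds and confounder
#' coefficients in logistic mode); and the missing covariate entries, each
#' imputed from its cluster's category distribution as part of the joint
#' posterior simulation.
#'
#' Proposal scales for the Metropolis moves adapt toward standard acceptance
#' targets during burn-in and are frozen afterwards, so the retained draws
#' come from a fixed-kernel chain.
#'
#' @param data a [ProfileDataset-class].
#' @param nIter,burnIn,thin total sweeps, discarded sweeps, and thinning
#'   interval; `floor((nIter - burnIn) / thin)` draws are retained.
#' @param truncation stick-breaking truncation level (maximum number of
#'   cluster slots). A message is emitted when posterior mass at the
#'   truncation tail exceeds `1e-4`, suggesting a higher level.
#' @param mode `"auto"` (plain when no confounders are declared, logistic
#'   otherwise), `"plain"` or `"logistic"`.
#' @param seed integer seed; the run is fully reproducible given it.
#' @param settings optional list overriding individual defaults (priors and
#'   proposal scales; see the methods vignette): `alphaPrior` (Gamma shape,
#'   rate for the concentration), `thetaBetaPrior` (Beta pseudo-counts, plain
#'   mode), `thetaNormalPrior`/`betaNormalPrior` (Normal mean, sd on the
#'   log-odds scale), `thresholdScale`, `thetaScale`, `betaScale`,
#'   `initClusters`.
#' @param verbose print progress every 1000 sweeps.
#' @return a [ProfileRegressionFit-class].
#' @examples
#' sim <- syntheticPreset("separable", n = 150, seed = 7)
#' fit <- profileRegression(sim$data, nIter = 600, burnIn = 200, thin = 2,
#'                          truncation = 15, seed = 7)
#' fit
#' @export
profileRegression <- function(data, nIter = 30000L, burnIn = 10000L,
                              thin = 10L, truncation = 50L,
                              mode = c("auto", "plain", "logistic"),
                              seed = NULL, settings = list(),
                              verbose = FALSE) {
    stopifnot(is(data, "ProfileDataset"), nIter > burnIn, thin >= 1L)
    mode <- match.arg(mode)
    dat <- .prepData(data)
    if (mode == "auto") mode <- if (dat$Q) "logistic" else "plain"
    if (mode == "plain" && dat$Q)
        stop("plain mode requires a dataset without confounders")
    s <- .defaultSettings()
    s[names(settings)] <- settings
    s$truncation <- as.integer(truncation)
    if (!is.null(seed)) set.seed(seed)
    state <- .initState(dat, s, mode)

    nKeep <- (nIter - burnIn) %/% thin
    n <- dat$n
    risk <- matrix(NA_real_, nKeep, n)
    alloc <- matrix(NA_integer_, nKeep, n)
    nMiss <- nrow(dat$missIdx)
    imputed <- matrix(NA_integer_, nKeep, nMiss)
    kOcc <- integer(nKeep)
    betaTr <- matrix(NA_real_, nKeep, dat$Q)
    alphaTr <- logLikTr <- numeric(nKeep)
    tailMass <- 0
    t <- 0L
    for (iter in seq_len(nIter)) {
        state <- .gibbsSweep(state, dat, s, adapt = iter <= burnIn)
        if (iter > burnIn && (iter - burnIn) %% thin == 0L) {
            t <- t + 1L
            risk[t, ] <- .subjectRisk(state)
            alloc[t, ] <- state$z
            if (nMiss)
                imputed[t, ] <- state$Xc[dat$missIdx] - 1L
            kOcc[t] <- length(unique(state$z))
            if (dat$Q) betaTr[t, ] <- state$beta
            alphaTr[t] <- state$alpha
            logLikTr[t] <- state$logLik
            tailMass <- tailMass + state$w[state$K]
        }
        if (verbose && iter %% 1000L == 0L)
            message(sprintf("sweep %d/%d  K=%d  alpha=%.2f",
                            iter, nIter, length(unique(state$z)),
                            state$alpha))
    }
    if (nKeep > 0 && tailMass / nKeep > s$tailWarn)
        message(sprintf(
            "mean stick-tail mass %.2g exceeds %.0e; consider a higher truncation",
            tailMass / nKeep, s$tailWarn))
    rate <- function(a) if (a[2] > 0) a[1] / a[2] else NA_real_
    new("ProfileRegressionFit",
        risk = risk, allocations = alloc,
        imputed = imputed, missIndex = dat$missIdx,
        kOccupied = kOcc, alpha = alphaTr, logLik = logLikTr,
        acceptance = list(thresholds = rate(state$accLambda),
                          theta = rate(state$accTheta),
                          beta = rate(state$accBeta)),
        mode = mode, beta = betaTr,
        settings = c(s, list(nIter = nIter, burnIn = burnIn, thin = thin,
                             seed = seed, mode = mode)),
        data = data)
}
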