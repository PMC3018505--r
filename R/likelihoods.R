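#' Log-likelihood of one covariate profile under a cluster's parameters
#'
#' The assignment submodel gives each cluster a prototypical profile through
#' per-covariate category probabilities \eqn{\phi_k^p(x)}: a
#' Dirichlet-multinomial probability vector for nominal covariates and
#' threshold-induced probabilities ([ordinalProbs()]) for ordinal ones. The
#' profile log-likelihood is the sum of \eqn{\log \phi_k^p(x_p)} over the
#' non-missing entries of the profile; missing entries contribute zero
#' (during sampling they are handled by imputation, and this marginal
#' evaluation is used for diagnostics).
#'
#' @param x integer profile of 0-based codes, `NA` at missing entries.
#' @param params list with one element per covariate: for nominal covariates a
#'   probability vector `probs`; for ordinal covariates either `probs` or a
#'   `thresholds` vector (a list with either element is accepted, as is a bare
#'   numeric vector taken as `probs`).
#' @param specs covariate metadata as returned by [covariateSpecs()] (columns
#'   `kind`, `nCategories`).
#' @return the profile log-likelihood (0 for an all-missing profile).
#' @examples
#' sp <- data.frame(kind = c("nominal", "ordinal"), nCategories = c(2L, 2L))
#' profileLogLik(c(0L, 1L),
#'               list(list(probs = c(0.8, 0.2)), list(thresholds = 0)),
#'               sp)  # log 0.8 + log 0.5
#' @export
profileLogLik <- function(x, params, specs) {
    P <- nrow(specs)
    stopifnot(length(x) == P, length(params) == P)
    ll <- 0
    for (p in seq_len(P)) {
        if (is.na(x[p])) next
        M <- specs$nCategories[p]
        if (x[p] < 0 || x[p] >= M)
            stop(sprintf("covariate %d: category %d outside 0..%d",
                         p, x[p], M - 1L))
        par <- params[[p]]
        pr <- if (is.list(par)) {
            if (!is.null(par$probs)) par$probs
            else ordinalProbs(par$thresholds)
        } else as.numeric(par)
        if (length(pr) != M)
            stop(sprintf("covariate %d: expected %d category probabilities",
                         p, M))
        ll <- ll + log(pr[x[p] + 1L])
    }
    ll
}

#' Outcome log-likelihood of the disease submodel
#'
#' In the plain formulation the disease probability is the cluster risk
#' \eqn{\theta_k} itself. With confounders a logistic formulation is used,
#' \eqn{\mathrm{logit}\, P(y=1) = \beta w + \theta_k}, where \eqn{\theta_k} is
#' the baseline log-odds of disease in cluster `k` (the log-odds when all
#' confounders sit at their reference value 0).
#'
#' @param y binary outcome (scalar or vector).
#' @param theta cluster risk on the probability scale (`mode = "plain"`) or
#'   baseline log-odds (`mode = "logistic"`).
#' @param w confounder values (vector, or matrix with subjects in rows);
#'   ignored in plain mode.
#' @param beta confounder log-odds coefficients.
#' @param mode `"plain"` or `"logistic"`.
#' @return the summed Bernoulli log-likelihood.
#' @examples
#' outcomeLogLik(1, 0.5)                       # log 0.5
#' outcomeLogLik(1, qlogis(0.15), mode = "logistic")  # log 0.15
#' @export
outcomeLogLik <- function(y, theta, w = NULL, beta = NULL,
                          mode = c("plain", "logistic")) {
    mode <- match.arg(mode)
    if (mode == "plain") {
        if (any(theta <= 0 | theta >= 1))
            stop("plain-mode theta must lie strictly in (0,1)")
        return(sum(y * log(theta) + (1 - y) * log1p(-theta)))
    }
    off <- 0
    if (!is.null(w) && length(beta)) {
        w <- if (is.matrix(w)) w else matrix(w, nrow = length(y),
                                             byrow = TRUE,
                                             ncol = length(beta))
        off <- drop(w %*% beta)
    }
    pr <- plogis(theta + off)
    sum(dbinom(y, 1L, pr, log = TRUE))
}

#' Conjugate posterior draws for the nominal submodel and the plain disease
#' submodel
#'
#' `samplePhiPosterior()` draws a category-probability vector from
#' `Dirichlet(prior + counts)`, the full conditional of a nominal covariate's
#' \eqn{\phi_k^p} under a Dirichlet prior. `sampleThetaPlain()` draws a
#' cluster risk from `Beta(a + cases, b + total - cases)`, the full
#' conditional of \eqn{\theta_k} in plain mode under a `Beta(a, b)` prior.
#' With zero counts both sample the (noninformative, by default) prior, which
#' is what empty clusters do inside the sampler.
#'
#' @param counts non-negative integer category counts.
#' @param prior positive Dirichlet pseudo-counts (recycled), default all 1.
#' @param cases,total case count and cluster size, `0 <= cases <= total`.
#' @param betaPrior length-2 positive Beta pseudo-counts, default `c(1, 1)`.
#' @return `samplePhiPosterior`: a probability vector; `sampleThetaPlain`: a
#'   risk in (0,1).
#' @export
samplePhiPosterior <- function(counts, prior = 1) {
    stopifnot(all(counts >= 0), all(prior > 0))
    shape <- counts + rep_len(prior, length(counts))
    g <- rgamma(length(shape), shape = shape, rate = 1)
    g / sum(g)
}

#' @rdname samplePhiPosterior
#' @export
sampleThetaPlain <- function(cases, total, betaPrior = c(1, 1)) {
    stopifnot(cases >= 0, cases <= total, all(betaPrior > 0))
    rbeta(1L, betaPrior[1] + cases, betaPrior[2] + total - cases)
}

#' Metropolis update of the logistic disease submodel
#'
#' One random-walk Metropolis-Hastings sweep over the per-cluster baseline
#' log-odds \eqn{\theta_k} and the confounder coefficients \eqn{\beta_q},
#' under independent Normal priors. Each parameter is updated one at a time
#' with a Gaussian proposal; a zero proposal scale leaves the parameter
#' unchanged.
#'
#' @param theta numeric vector of baseline log-odds, one per cluster slot.
#' @param beta numeric vector of confounder coefficients (possibly empty).
#' @param z integer allocations of subjects to cluster slots.
#' @param y binary outcome vector.
#' @param W confounder matrix (subjects x Q; Q = 0 allowed).
#' @param scales list with elements `theta` and `beta`, proposal standard
#'   deviations (recycled over clusters/coefficients).
#' @param priorSD list with elements `theta` and `beta`, Normal prior standard
#'   deviations (default 10: weakly informative on the log-odds scale, wide
#'   enough to be effectively flat over epidemiologically plausible odds while
#'   preventing separation blow-ups).
#' @param priorMean list with elements `theta` and `beta` (default 0).
#' @return a list with updated `theta`, `beta`, and logical `acceptedTheta`
#'   (occupied clusters only get Metropolis moves; empty-cluster slots are
#'   redrawn from the prior) and `acceptedBeta`.
#' @export
updateThetaBetaLogistic <- function(theta, beta, z, y, W,
                                    scales = list(theta = 0.4, beta = 0.1),
                                    priorSD = list(theta = 10, beta = 10),
                                    priorMean = list(theta = 0, beta = 0)) {
    K <- length(theta)
    Q <- length(beta)
    if (is.null(W) || !Q) W <- matrix(0, length(y), 0L)
    off <- if (Q) drop(W %*% beta) else rep(0, length(y))
    thScale <- rep_len(scales$theta, K)
    accTheta <- rep(NA, K)
    occ <- tabulate(z, K) > 0L
    for (k in seq_len(K)) {
        if (!occ[k]) {
            theta[k] <- rnorm(1L, priorMean$theta, priorSD$theta)
            next
        }
        idx <- which(z == k)
        cur <- theta[k]
        prop <- cur + rnorm(1L, 0, thScale[k])
        llCur <- sum(dbinom(y[idx], 1L, plogis(cur + off[idx]), log = TRUE)) +
            dnorm(cur, priorMean$theta, priorSD$theta, log = TRUE)
        llProp <- sum(dbinom(y[idx], 1L, plogis(prop + off[idx]),
                             log = TRUE)) +
            dnorm(prop, priorMean$theta, priorSD$theta, log = TRUE)
        accTheta[k] <- log(runif(1L)) < llProp - llCur
        if (accTheta[k]) theta[k] <- prop
    }
    accBeta <- logical(Q)
    if (Q) {
        thetaSubj <- theta[z]
        bScale <- rep_len(scales$beta, Q)
        for (q in seq_len(Q)) {
            cur <- beta[q]
            prop <- cur + rnorm(1L, 0, bScale[q])
            offCur <- drop(W %*% beta)
            betaProp <- beta
            betaProp[q] <- prop
            offProp <- drop(W %*% betaProp)
            llCur <- sum(dbinom(y, 1L, plogis(thetaSubj + offCur),
                                log = TRUE)) +
                dnorm(cur, priorMean$beta, priorSD$beta, log = TRUE)
            llProp <- sum(dbinom(y, 1L, plogis(thetaSubj + offProp),
                                 log = TRUE)) +
                dnorm(prop, priorMean$beta, priorSD$beta, log = TRUE)
            accBeta[q] <- log(runif(1L)) < llProp - llCur
            if (accBeta[q]) beta <- betaProp
        }
    }
    list(theta = theta, beta = beta,
         acceptedTheta = accTheta, acceptedBeta = accBeta)
}
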