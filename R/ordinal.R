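#' Ordered-threshold probit parameterisation of ordinal category
#' probabilities
#'
#' An ordinal covariate with `M` ordered categories is modelled through
#' `M - 1` strictly increasing thresholds \eqn{\lambda_1 < \dots <
#' \lambda_{M-1}} on an underlying standard normal scale, with implicit
#' \eqn{\lambda_0 = -\infty} and \eqn{\lambda_M = +\infty}. The probability of
#' category `j` (0-based) is \eqn{\Phi(\lambda_{j+1}) - \Phi(\lambda_j)}.
#' Beyond the ordering of the categories no relation between them is imposed:
#' any interior point of the probability simplex is reachable.
#'
#' `ordinalProbs()` maps thresholds to category probabilities;
#' `probsToThresholds()` is its exact inverse on the interior of the simplex,
#' \eqn{\lambda_j = \Phi^{-1}(p_0 + \dots + p_{j-1})}.
#'
#' @param thresholds strictly increasing numeric vector of length `M - 1`.
#' @param p strictly positive probability vector summing to 1.
#' @return `ordinalProbs`: a probability vector of length `M` summing to 1;
#'   `probsToThresholds`: the threshold vector of length `M - 1`.
#' @examples
#' ordinalProbs(0)              # (0.5, 0.5)
#' ordinalProbs(c(-1, 1))       # approx (0.159, 0.683, 0.159)
#' probsToThresholds(c(0.25, 0.25, 0.25, 0.25))
#' @export
ordinalProbs <- function(thresholds) {
    thresholds <- as.numeric(thresholds)
    if (length(thresholds) < 1L)
        stop("at least one threshold is required (M >= 2)")
    if (any(diff(thresholds) <= 0))
        stop("thresholds must be strictly increasing")
    diff(c(0, pnorm(thresholds), 1))
}

#' @rdname ordinalProbs
#' @export
probsToThresholds <- function(p) {
    p <- as.numeric(p)
    if (length(p) < 2L)
        stop("need at least two categories")
    if (any(p <= 0))
        stop("zero-probability categories give coincident thresholds")
    if (abs(sum(p) - 1) > 1e-8)
        stop("probabilities must sum to 1")
    qnorm(cumsum(p)[-length(p)])
}

# Log posterior of a threshold vector under multinomial category counts and
# the uniform-on-simplex prior on induced probabilities. In threshold space
# that prior has density proportional to prod_j dnorm(lambda_j) (the Jacobian
# of the simplex -> threshold map).
.thresholdLogPost <- function(thresholds, counts) {
    pr <- diff(c(0, pnorm(thresholds), 1))
    if (any(pr <= 0)) return(-Inf)
    sum(counts * log(pr)) + sum(dnorm(thresholds, log = TRUE))
}

#' One Metropolis sweep over the thresholds of an ordinal covariate
#'
#' Random-walk Metropolis-Hastings on one interior threshold at a time,
#' targeting the posterior of the thresholds under the multinomial likelihood
#' induced by [ordinalProbs()] and a uniform prior on the induced category
#' probabilities (density proportional to
#' \eqn{\prod_j \phi(\lambda_j)} in threshold space). Proposals breaking the
#' strict ordering are rejected, which preserves detailed balance for the
#' order-constrained target.
#'
#' @param thresholds current strictly increasing threshold vector.
#' @param counts integer category counts of length `length(thresholds) + 1`
#'   from the subjects currently assigned to the cluster (all zero for an
#'   empty cluster, in which case the chain samples the prior).
#' @param proposalScale standard deviation(s) of the Gaussian random walk,
#'   recycled over thresholds. A scale of 0 proposes the current state, which
#'   is always accepted.
#' @return a list with the updated `thresholds` and a logical `accepted`
#'   vector, one entry per threshold.
#' @export
updateThresholds <- function(thresholds, counts, proposalScale = 0.2) {
    thresholds <- as.numeric(thresholds)
    Mm1 <- length(thresholds)
    if (length(counts) != Mm1 + 1L)
        stop("counts must have one entry per category")
    if (any(diff(thresholds) <= 0))
        stop("thresholds must be strictly increasing")
    scales <- rep_len(proposalScale, Mm1)
    accepted <- logical(Mm1)
    lp <- .thresholdLogPost(thresholds, counts)
    for (j in seq_len(Mm1)) {
        prop <- thresholds
        prop[j] <- thresholds[j] + rnorm(1L, 0, scales[j])
        ok <- (j == 1L || prop[j] > thresholds[j - 1L]) &&
              (j == Mm1 || prop[j] < thresholds[j + 1L])
        if (!ok) next
        lpProp <- .thresholdLogPost(prop, counts)
        if (log(runif(1L)) < lpProp - lp) {
            thresholds <- prop
            lp <- lpProp
            accepted[j] <- TRUE
        }
    }
    list(thresholds = thresholds, accepted = accepted)
}
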