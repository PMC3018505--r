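# Synthetic case-control generators with planted cluster structure. These
# emulate the generative model the sampler assumes: cluster labels from
# mixing weights, covariates from cluster-specific category probabilities,
# outcome from cluster-specific risks, and MCAR missingness applied last.

.sampleCategories <- function(probRows) {
    M <- ncol(probRows)
    cs <- probRows %*% upper.tri(diag(M), diag = TRUE)
    as.integer(pmin.int(1L + rowSums(cs < runif(nrow(probRows))), M) - 1L)
}

#' Generate a synthetic case-control dataset with planted clusters
#'
#' Subjects receive cluster labels from `weights`; each covariate is drawn
#' from its cluster's category probabilities (ordinal covariates are
#' parameterised by probabilities here, converted through
#' [probsToThresholds()] when the model needs thresholds); the outcome is
#' Bernoulli with the cluster's risk, optionally shifted on the log-odds
#' scale by confounder effects; missingness is applied completely at random
#' per covariate. The planted truth is returned for recovery tests.
#'
#' The outcome (and, when requested, the missingness mask and covariates) is
#' redrawn in whole in the rare event that a draw yields no cases, no
#' controls, or an all-missing covariate, so the returned object is always a
#' valid [ProfileDataset-class].
#'
#' @param n number of subjects.
#' @param weights cluster mixing probabilities (sum to 1).
#' @param theta per-cluster disease risks in (0, 1).
#' @param specs covariate metadata `data.frame` (columns `name`, `kind`,
#'   `nCategories`).
#' @param phi list with one element per covariate: a `K x nCategories` matrix
#'   of per-cluster category probabilities (rows sum to 1).
#' @param missingRate per-covariate MCAR missingness probability (recycled).
#' @param beta optional confounder log-odds effects; when given, `length(beta)`
#'   standard-normal confounders are generated and the outcome uses
#'   `plogis(qlogis(theta) + W beta)`.
#' @param seed integer seed.
#' @return a list with `data` (a [ProfileDataset-class]), `labels` (planted
#'   cluster labels) and `params` (the planted parameters).
#' @examples
#' sim <- syntheticPreset("separable", n = 300, seed = 1)
#' table(sim$labels, outcome(sim$data))
#' @export
syntheticProfiles <- function(n, weights, theta, specs, phi,
                              missingRate = 0, beta = NULL, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    K <- length(weights)
    stopifnot(abs(sum(weights) - 1) < 1e-8, length(theta) == K,
              all(theta > 0 & theta < 1), length(phi) == nrow(specs))
    for (p in seq_along(phi)) {
        stopifnot(nrow(phi[[p]]) == K,
                  ncol(phi[[p]]) == specs$nCategories[p],
                  all(abs(rowSums(phi[[p]]) - 1) < 1e-8))
    }
    missingRate <- rep_len(missingRate, nrow(specs))
    P <- nrow(specs)
    labels <- sample.int(K, n, replace = TRUE, prob = weights)
    X <- matrix(NA_integer_, n, P, dimnames = list(NULL, specs$name))
    for (p in seq_len(P))
        X[, p] <- .sampleCategories(phi[[p]][labels, , drop = FALSE])
    W <- NULL
    for (attempt in seq_len(100L)) {
        if (is.null(beta)) {
            y <- rbinom(n, 1L, theta[labels])
        } else {
            W <- matrix(rnorm(n * length(beta)), n, length(beta),
                        dimnames = list(NULL,
                                        paste0("w", seq_along(beta))))
            y <- rbinom(n, 1L, plogis(qlogis(theta[labels]) +
                                      drop(W %*% beta)))
        }
        if (any(y == 1L) && any(y == 0L)) break
    }
    Xm <- X
    for (p in seq_len(P)) {
        if (missingRate[p] <= 0) next
        for (attempt in seq_len(100L)) {
            mask <- runif(n) < missingRate[p]
            if (!all(mask)) break
        }
        Xm[mask, p] <- NA_integer_
    }
    list(data = ProfileDataset(Xm, y, specs, W = W),
         labels = labels,
         params = list(weights = weights, theta = theta, phi = phi,
                       beta = beta))
}

.presetFile <- function(name) {
    f <- system.file("extdata", "presets", paste0(name, ".yaml"),
                     package = "profilereg")
    if (!nzchar(f))
        stop(sprintf("unknown preset '%s'", name))
    f
}

#' Shipped synthetic-data scenarios
#'
#' Named scenario files (YAML under `extdata/presets/`) defining the planted
#' structure of standard test datasets:
#' * `"paper_shape"` — 829 subjects shaped like a nested case-control air
#'   pollution study: nine covariates (three binary, four 3-level, two
#'   4-level), three clusters of relative size 96/112/621 with risks
#'   0.15/0.12/0.09, 34% missingness on the 4-level ordinal exposure and 6%
#'   on a 3-level one.
#' * `"null"` — a single cluster with risk 0.1 over the same nine covariates:
#'   no structure to find.
#' * `"separable"` — three equally weighted, well-separated clusters with
#'   risks 0.05/0.10/0.25 (planted high-vs-low odds ratio about 6.3).
#' * `"xor_pair"` — outcome driven purely by the interaction of two binary
#'   factors with null marginals (see [makeMdrSynthetic()]).
#'
#' @param name preset name.
#' @param n number of subjects (default: the preset's own).
#' @param seed integer seed.
#' @param ... further arguments passed to the generator.
#' @return as [syntheticProfiles()] (for `"xor_pair"`, as
#'   [makeMdrSynthetic()]).
#' @export
syntheticPreset <- function(name, n = NULL, seed = NULL, ...) {
    cfg <- yaml::read_yaml(.presetFile(name))
    if (is.null(n)) n <- cfg$n_subjects
    if (identical(cfg$generator, "xor_pair"))
        return(makeMdrSynthetic(n = n, effect = cfg$effect,
                                nNoise = cfg$n_noise, seed = seed, ...))
    specs <- data.frame(
        name = vapply(cfg$covariates, `[[`, "", "name"),
        kind = vapply(cfg$covariates, `[[`, "", "kind"),
        nCategories = vapply(cfg$covariates, function(x)
            as.integer(x$n_categories), 1L),
        stringsAsFactors = FALSE)
    phi <- lapply(cfg$covariates, function(x)
        do.call(rbind, lapply(x$phi, as.numeric)))
    miss <- vapply(cfg$covariates, function(x)
        if (is.null(x$missing_rate)) 0 else as.numeric(x$missing_rate), 1)
    syntheticProfiles(n = n, weights = as.numeric(cfg$weights),
                      theta = as.numeric(cfg$theta), specs = specs,
                      phi = phi, missingRate = miss, seed = seed, ...)
}

#' Synthetic data with a purely interacting factor pair
#'
#' Two designated binary factors drive the outcome only through their
#' interaction: the disease probability is `baseRate + effect` when the
#' factors disagree (exclusive or) and `baseRate - effect` when they agree,
#' so each factor's marginal association with the outcome is null. Additional
#' independent binary noise factors are appended. This is the planted-truth
#' scenario for MDR recovery tests, where marginal methods see nothing but
#' the pair is detectable jointly.
#'
#' @param n number of subjects (at least 100).
#' @param effect risk shift of the interaction, in `[0, min(baseRate,
#'   1 - baseRate))`; 0 gives a fully null dataset.
#' @param nNoise number of extra null binary factors.
#' @param baseRate baseline disease probability.
#' @param seed integer seed.
#' @return a list with `data` (a [ProfileDataset-class], all covariates
#'   nominal binary), `pair` (indices of the interacting factors) and
#'   `params`.
#' @export
makeMdrSynthetic <- function(n, effect = 0.25, nNoise = 4L, baseRate = 0.5,
                             seed = NULL) {
    stopifnot(n >= 100L, effect >= 0,
              baseRate + effect < 1, baseRate - effect > 0)
    if (!is.null(seed)) set.seed(seed)
    P <- 2L + nNoise
    X <- matrix(rbinom(n * P, 1L, 0.5), n, P,
                dimnames = list(NULL, c("fA", "fB",
                                        if (nNoise)
                                            paste0("noise",
                                                   seq_len(nNoise)))))
    pr <- ifelse(xor(X[, 1L] == 1L, X[, 2L] == 1L),
                 baseRate + effect, baseRate - effect)
    for (attempt in seq_len(100L)) {
        y <- rbinom(n, 1L, pr)
        if (any(y == 1L) && any(y == 0L)) break
    }
    specs <- data.frame(name = colnames(X),
                        kind = "nominal",
                        nCategories = 2L,
                        stringsAsFactors = FALSE)
    list(data = ProfileDataset(X, y, specs),
         pair = c(1L, 2L),
         params = list(effect = effect, baseRate = baseRate))
}
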