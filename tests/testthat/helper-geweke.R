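# Joint-correctness machinery: compare forward simulation from the prior
# (parameters then data) with a successive-conditional chain that alternates
# one Gibbs sweep on the parameters with regeneration of the data given the
# parameters. If the sampler's conditionals are correct both schemes target
# the same joint distribution, so label-invariant functionals must agree.

gewekePriorState <- function(dat, settings) {
    K <- settings$truncation
    alpha <- rgamma(1, settings$alphaPrior[1], settings$alphaPrior[2])
    v <- pmin(pmax(rbeta(K - 1, 1, alpha), 1e-12), 1 - 1e-12)
    w <- c(v, 1) * cumprod(c(1, 1 - v))
    phi <- lapply(seq_len(dat$P), function(p) {
        g <- matrix(rgamma(K * dat$M[p], 1), K, dat$M[p])
        g / rowSums(g)
    })
    list(K = K,
         z = sample.int(K, dat$n, replace = TRUE, prob = w),
         v = v, w = w, alpha = alpha,
         phi = phi, lambda = vector("list", dat$P),
         lamScale = vector("list", dat$P),
         theta = rbeta(K, settings$thetaBetaPrior[1],
                       settings$thetaBetaPrior[2]),
         beta = numeric(0),
         thetaScale = rep(settings$thetaScale, K),
         Xc = matrix(1L, dat$n, dat$P),
         mode = "plain", logLik = NA_real_,
         accLambda = c(0, 0), accTheta = c(0, 0), accBeta = c(0, 0))
}

gewekeRegenerate <- function(state, dat) {
    for (p in seq_len(dat$P)) {
        pr <- state$phi[[p]][state$z, , drop = FALSE]
        cs <- pr %*% upper.tri(diag(dat$M[p]), diag = TRUE)
        dat$X1[, p] <- as.integer(pmin(1L + rowSums(cs < runif(dat$n)),
                                       dat$M[p]))
    }
    state$Xc <- dat$X1
    dat$y <- rbinom(dat$n, 1L, state$theta[state$z])
    list(state = state, dat = dat)
}

gewekeFunctionals <- function(state, dat) {
    c(yBar = mean(dat$y),
      xBar = mean(state$Xc - 1L),
      risk1 = state$theta[state$z[1L]],
      kOcc = length(unique(state$z)))
}
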