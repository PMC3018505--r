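# Multifactor dimensionality reduction comparator. Cells are combinations of
# the levels of a chosen factor set; each cell is labelled high or low risk
# by its case:control ratio on training data and the labels are used to
# classify held-out subjects.

.cellIds <- function(X, factors, M) {
    id <- rep(0L, nrow(X))
    mult <- 1L
    for (p in factors) {
        id <- id + X[, p] * mult
        mult <- mult * M[p]
    }
    id + 1L   # 1-based cell index
}

#' Label the cells of a factor combination as high or low risk
#'
#' Every observed combination of levels of the chosen factors forms a cell; a
#' cell is labelled high risk when its ratio of cases to controls exceeds
#' `threshold` (default 1). A non-empty cell with no controls is labelled
#' high; a cell with no cases is low. Cells unseen in the training data are
#' predicted low (the majority class when prevalence is below one half) —
#' a deterministic convention for the sparse-cell situations MDR handles
#' poorly.
#'
#' @param data a [ProfileDataset-class] without missing entries, or a
#'   complete 0-based integer covariate matrix.
#' @param y binary outcome (ignored when `data` is a ProfileDataset).
#' @param factors integer indices of the covariates forming the combination.
#' @param threshold case:control ratio above which a cell is high risk.
#' @return a data.frame with one row per observed cell: the factor levels,
#'   `cases`, `controls` and `label`.
#' @export
mdrLabelCells <- function(data, y = NULL, factors, threshold = 1) {
    if (is(data, "ProfileDataset")) {
        y <- outcome(data)
        X <- covariateMatrix(data)
    } else X <- data
    if (anyNA(X[, factors, drop = FALSE]))
        stop("MDR requires complete data for the chosen factors")
    stopifnot(length(factors) >= 1L, threshold > 0)
    M <- apply(X[, factors, drop = FALSE], 2L, max) + 1L
    key <- interaction(as.data.frame(X[, factors, drop = FALSE]),
                       drop = TRUE, lex.order = TRUE)
    cases <- tapply(y, key, sum)
    totals <- tapply(y, key, length)
    controls <- totals - cases
    lab <- ifelse(controls == 0L, "high",
                  ifelse(cases / controls > threshold, "high", "low"))
    lev <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
    res <- as.data.frame(lev, stringsAsFactors = FALSE)
    names(res) <- if (!is.null(colnames(X))) colnames(X)[factors]
                  else paste0("f", factors)
    res$cases <- as.integer(cases)
    res$controls <- as.integer(controls)
    res$label <- as.character(as.vector(lab))
    res
}

# internal fast path: high/low label per training cell id, then class
# predictions for test cell ids (unseen cells -> low)
.mdrTrainLabels <- function(cellId, y, nCells, threshold) {
    cases <- tabulate(cellId[y == 1L], nCells)
    controls <- tabulate(cellId[y == 0L], nCells)
    high <- (controls == 0L & cases > 0L) |
        (controls > 0L & cases / controls > threshold)
    high
}

.mdrAccuracy <- function(high, cellId, y) {
    pred <- as.integer(high[cellId])
    mean(pred == y)
}

.stratifiedFolds <- function(y, folds) {
    fold <- integer(length(y))
    for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
}

#' Cross-validated prediction accuracy of one factor combination
#'
#' The data are split into `folds` (default 10) outcome-stratified parts.
#' For each fold the cells are labelled on the remaining data and predictions
#' are made for the held-out part; the proportion of correct predictions is
#' averaged over folds. Stratification keeps cases in every fold of a
#' low-prevalence sample; a fold that still ends up without cases is kept
#' with a warning.
#'
#' @inheritParams mdrLabelCells
#' @param folds number of cross-validation folds.
#' @param seed integer seed fixing the fold assignment.
#' @return a list with `accuracy` (mean over folds) and `foldAccuracy`.
#' @export
mdrCrossValidate <- function(data, y = NULL, factors, threshold = 1,
                             folds = 10L, seed = NULL) {
    if (is(data, "ProfileDataset")) {
        y <- outcome(data)
        X <- covariateMatrix(data)
    } else X <- data
    if (anyNA(X))
        stop("MDR requires complete data; restrict to complete cases first")
    stopifnot(length(y) >= folds)
    if (!is.null(seed)) set.seed(seed)
    M <- apply(X, 2L, max, na.rm = TRUE) + 1L
    cellId <- .cellIds(X, factors, M)
    nCells <- max(cellId)
    fold <- .stratifiedFolds(y, folds)
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
        test <- fold == f
        if (!any(y[test] == 1L))
            warning(sprintf("fold %d contains no cases", f))
        high <- .mdrTrainLabels(cellId[!test], y[!test], nCells, threshold)
        acc[f] <- .mdrAccuracy(high, cellId[test], y[test])
    }
    list(accuracy = mean(acc), foldAccuracy = acc)
}

#' Exhaustive MDR scan over factor combinations
#'
#' For each combination order `p` from 1 to `maxOrder`, every `p`-subset of
#' the covariates is evaluated under 10-fold cross-validation: within each
#' fold the subset with the highest training-set classification accuracy is
#' the fold winner (ties broken lexicographically by factor indices), and
#' each subset's held-out prediction accuracy is recorded. Per order, the
#' reported best combination maximises the mean prediction accuracy; its
#' cross-validation consistency (CVC) is the number of folds (out of 10) in
#' which it was the fold winner.
#'
#' @inheritParams mdrCrossValidate
#' @param maxOrder largest combination order to scan.
#' @param maxCombinations guard against combinatorial explosion: error if the
#'   total number of subsets to evaluate exceeds this.
#' @return a data.frame with one row per order: `order`, `factors`
#'   (comma-separated names), `accuracy`, `cvc`; the winning subsets are
#'   attached as the `"winners"` attribute.
#' @export
mdrScan <- function(data, y = NULL, maxOrder = 2L, threshold = 1,
                    folds = 10L, seed = NULL, maxCombinations = 5000L) {
    if (is(data, "ProfileDataset")) {
        y <- outcome(data)
        X <- covariateMatrix(data)
    } else X <- data
    if (anyNA(X))
        stop("MDR requires complete data; restrict to complete cases first")
    P <- ncol(X)
    stopifnot(maxOrder >= 1L, maxOrder <= P)
    total <- sum(choose(P, seq_len(maxOrder)))
    if (total > maxCombinations)
        stop(sprintf("%d combinations exceed the limit of %d",
                     total, maxCombinations))
    if (!is.null(seed)) set.seed(seed)
    M <- apply(X, 2L, max, na.rm = TRUE) + 1L
    fold <- .stratifiedFolds(y, folds)
    nm <- if (!is.null(colnames(X))) colnames(X) else paste0("f", seq_len(P))
    rows <- vector("list", maxOrder)
    winners <- vector("list", maxOrder)
    for (ord in seq_len(maxOrder)) {
        subs <- combn(P, ord, simplify = FALSE)
        nS <- length(subs)
        trainAcc <- testAcc <- matrix(NA_real_, nS, folds)
        for (s in seq_len(nS)) {
            cellId <- .cellIds(X, subs[[s]], M)
            nCells <- max(cellId)
            for (f in seq_len(folds)) {
                test <- fold == f
                high <- .mdrTrainLabels(cellId[!test], y[!test], nCells,
                                        threshold)
                trainAcc[s, f] <- .mdrAccuracy(high, cellId[!test], y[!test])
                testAcc[s, f] <- .mdrAccuracy(high, cellId[test], y[test])
            }
        }
        # fold winner by training accuracy; combn order is lexicographic, and
        # which.max takes the first maximum, giving the documented tie-break
        foldWinner <- apply(trainAcc, 2L, which.max)
        meanTest <- rowMeans(testAcc)
        bestS <- which.max(meanTest)
        rows[[ord]] <- data.frame(
            order = ord,
            factors = paste(nm[subs[[bestS]]], collapse = ","),
            accuracy = meanTest[bestS],
            cvc = sum(foldWinner == bestS),
            stringsAsFactors = FALSE)
        winners[[ord]] <- subs[[bestS]]
    }
    res <- do.call(rbind, rows)
    attr(res, "winners") <- winners
    res
}
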