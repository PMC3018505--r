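#' Accessors for ProfileDataset and fit objects
#'
#' `covariateMatrix()` returns the subjects-by-covariates integer code matrix
#' (`NA` at missing entries); `missingMask()` the matching logical mask;
#' `outcome()` the binary outcome vector; `confounders()` the numeric
#' confounder matrix (zero columns when none were declared);
#' `covariateSpecs()` the covariate metadata (`kind`, `nCategories`, optional
#' `labels`); `nCategories()` the per-covariate category counts.
#'
#' @param x a [ProfileDataset-class].
#' @return see the individual descriptions above.
#' @name ProfileDataset-accessors
#' @examples
#' pd <- syntheticPreset("null", n = 20, seed = 1)$data
#' dim(covariateMatrix(pd))
#' table(outcome(pd))
NULL

#' @rdname ProfileDataset-accessors
#' @export
covariateMatrix <- function(x) {
    stopifnot(is(x, "ProfileDataset"))
    t(SummarizedExperiment::assay(x, "covariates"))
}

#' @rdname ProfileDataset-accessors
#' @export
missingMask <- function(x) {
    stopifnot(is(x, "ProfileDataset"))
    t(SummarizedExperiment::assay(x, "missing"))
}

#' @rdname ProfileDataset-accessors
#' @export
outcome <- function(x) {
    stopifnot(is(x, "ProfileDataset"))
    as.integer(SummarizedExperiment::colData(x)$y)
}

#' @rdname ProfileDataset-accessors
#' @export
confounders <- function(x) {
    stopifnot(is(x, "ProfileDataset"))
    conf <- S4Vectors::metadata(x)$confounders
    cd <- SummarizedExperiment::colData(x)
    if (!length(conf))
        return(matrix(numeric(), nrow = ncol(x), ncol = 0))
    as.matrix(as.data.frame(cd[, conf, drop = FALSE]))
}

#' @rdname ProfileDataset-accessors
#' @export
covariateSpecs <- function(x) {
    stopifnot(is(x, "ProfileDataset"))
    rd <- SummarizedExperiment::rowData(x)
    df <- data.frame(name = rownames(rd),
                     kind = rd$kind,
                     nCategories = rd$nCategories,
                     stringsAsFactors = FALSE)
    if ("labels" %in% colnames(rd)) df$labels <- as.list(rd$labels)
    df
}

#' @rdname ProfileDataset-accessors
#' @export
nCategories <- function(x) {
    stopifnot(is(x, "ProfileDataset"))
    rd <- SummarizedExperiment::rowData(x)
    setNames(as.integer(rd$nCategories), rownames(rd))
}

#' Accessors for ProfileRegressionFit
#'
#' `riskDraws()` returns the retained iterations x subjects matrix of
#' per-subject disease probabilities; `allocationDraws()` the matching cluster
#' allocation matrix; `subjectRisk()` the posterior mean risk per subject;
#' `occupiedClusters()` the per-iteration count of occupied clusters;
#' `acceptanceRates()` the Metropolis acceptance diagnostics.
#'
#' @param fit a [ProfileRegressionFit-class].
#' @name ProfileRegressionFit-accessors
NULL

#' @rdname ProfileRegressionFit-accessors
#' @export
riskDraws <- function(fit) {
    stopifnot(is(fit, "ProfileRegressionFit"))
    fit@risk
}

#' @rdname ProfileRegressionFit-accessors
#' @export
allocationDraws <- function(fit) {
    stopifnot(is(fit, "ProfileRegressionFit"))
    fit@allocations
}

#' @rdname ProfileRegressionFit-accessors
#' @export
subjectRisk <- function(fit) {
    stopifnot(is(fit, "ProfileRegressionFit"))
    colMeans(fit@risk)
}

#' @rdname ProfileRegressionFit-accessors
#' @export
occupiedClusters <- function(fit) {
    stopifnot(is(fit, "ProfileRegressionFit"))
    fit@kOccupied
}

#' @rdname ProfileRegressionFit-accessors
#' @export
acceptanceRates <- function(fit) {
    stopifnot(is(fit, "ProfileRegressionFit"))
    fit@acceptance
}

#' Group labels of a best partition
#'
#' @param x a [BestPartition-class].
#' @return integer vector of group labels `1..G` (via `groupLabels`), or the
#'   integer group sizes (via `groupSizes`).
#' @export
groupLabels <- function(x) {
    stopifnot(is(x, "BestPartition"))
    x@labels
}

#' @rdname groupLabels
#' @export
groupSizes <- function(x) {
    stopifnot(is(x, "BestPartition"))
    x@groupSizes
}
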