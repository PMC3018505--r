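#' @import methods
#' @importFrom stats pnorm qnorm dnorm rnorm runif rbeta rgamma rbinom quantile
#'   plogis qlogis dbinom setNames
#' @importFrom utils read.csv write.csv combn head
#' @importFrom tools file_ext
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ProfileDataset: a case-control sample of categorical/ordinal exposure
#' profiles
#'
#' An S4 container for profile regression input data, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are covariates, columns
#' are subjects. Two assays are carried: `"covariates"`, an integer matrix of
#' 0-based category codes with `NA` at missing entries, and `"missing"`, the
#' corresponding logical missingness mask. Covariate metadata (kind, number of
#' categories, optional category labels) live in `rowData`; the binary outcome
#' and any confounder columns live in `colData`.
#'
#' Invariants enforced by the validity method:
#' * every non-missing code lies in `0 .. nCategories - 1` for its covariate;
#' * the outcome contains only 0 and 1, with at least one case and one control;
#' * the `"missing"` assay is `TRUE` exactly where `"covariates"` is `NA`;
#' * `nCategories >= 2` and `kind` is `"nominal"` or `"ordinal"`.
#'
#' @seealso [ProfileDataset()] for the constructor, [readProfileDataset()] for
#'   delimited-text input, [covariateMatrix()], [outcome()], [confounders()],
#'   [missingMask()], [covariateSpecs()] for accessors.
#' @aliases ProfileDataset-class
#' @exportClass ProfileDataset
setClass("ProfileDataset", contains = "SummarizedExperiment")

.validProfileDataset <- function(object) {
    msg <- character()
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("covariates", "missing") %in% a))
        return("assays 'covariates' and 'missing' are required")
    X <- SummarizedExperiment::assay(object, "covariates")
    M <- SummarizedExperiment::assay(object, "missing")
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("kind", "nCategories") %in% colnames(rd)))
        return("rowData must contain 'kind' and 'nCategories'")
    if (!("y" %in% colnames(cd)))
        return("colData must contain the outcome column 'y'")
    if (!identical(dim(X), dim(M)))
        msg <- c(msg, "covariate and missing assays must share dimensions")
    if (!is.logical(M))
        msg <- c(msg, "'missing' assay must be logical")
    if (!identical(unname(is.na(X)), unname(M == TRUE)))
        msg <- c(msg, "'missing' mask must be TRUE exactly where codes are NA")
    if (!all(rd$kind %in% c("nominal", "ordinal")))
        msg <- c(msg, "covariate kind must be 'nominal' or 'ordinal'")
    if (any(rd$nCategories < 2))
        msg <- c(msg, "every covariate needs at least 2 categories")
    for (p in seq_len(nrow(X))) {
        xp <- X[p, ]
        xp <- xp[!is.na(xp)]
        if (length(xp) == 0L) {
            msg <- c(msg, sprintf("covariate '%s' is entirely missing",
                                  rownames(X)[p]))
        } else if (any(xp < 0 | xp >= rd$nCategories[p])) {
            msg <- c(msg, sprintf(
                "covariate '%s' has codes outside 0..%d",
                rownames(X)[p], rd$nCategories[p] - 1L))
        }
    }
    y <- cd$y
    if (any(is.na(y)) || !all(y %in% c(0, 1)))
        msg <- c(msg, "outcome must be 0/1 with no missing values")
    else if (sum(y == 1) == 0L || sum(y == 0) == 0L)
        msg <- c(msg, "need at least one case and one control")
    wn <- S4Vectors::metadata(object)$confounders
    if (length(wn) && !all(wn %in% colnames(cd)))
        msg <- c(msg, "metadata()$confounders names absent from colData")
    if (length(msg)) msg else TRUE
}
setValidity("ProfileDataset", .validProfileDataset)

#' Construct a ProfileDataset
#'
#' @param X integer matrix, subjects in rows and covariates in columns, holding
#'   0-based category codes with `NA` at missing entries.
#' @param y binary outcome vector (1 = case, 0 = control), one per subject.
#' @param specs a `data.frame` with one row per covariate and columns `name`,
#'   `kind` (`"nominal"` or `"ordinal"`) and `nCategories`; an optional
#'   `labels` list column carries original category labels.
#' @param W optional numeric matrix of confounders (subjects in rows); its
#'   column names become the confounder columns of `colData`.
#'
#' @return a validated [ProfileDataset-class] object.
#' @examples
#' sp <- data.frame(name = c("exposure", "dose"),
#'                  kind = c("nominal", "ordinal"),
#'                  nCategories = c(2L, 3L))
#' X <- cbind(exposure = c(0L, 1L, 1L, 0L), dose = c(0L, 2L, 1L, NA))
#' pd <- ProfileDataset(X, y = c(1, 0, 0, 1), specs = sp)
#' pd
#' @export
ProfileDataset <- function(X, y, specs, W = NULL) {
    X <- as.matrix(X)
    storage.mode(X) <- "integer"
    stopifnot(nrow(specs) == ncol(X), nrow(X) == length(y))
    if (is.null(colnames(X))) colnames(X) <- specs$name
    rd <- S4Vectors::DataFrame(
        kind = as.character(specs$kind),
        nCategories = as.integer(specs$nCategories),
        row.names = as.character(specs$name))
    if (!is.null(specs$labels)) rd$labels <- specs$labels
    cd <- S4Vectors::DataFrame(y = as.integer(y))
    conf <- character()
    if (!is.null(W)) {
        W <- as.matrix(W)
        if (is.null(colnames(W)))
            colnames(W) <- paste0("w", seq_len(ncol(W)))
        for (q in seq_len(ncol(W))) cd[[colnames(W)[q]]] <- W[, q]
        conf <- colnames(W)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(covariates = t(X), missing = t(is.na(X))),
        rowData = rd, colData = cd,
        metadata = list(confounders = conf))
    new("ProfileDataset", se)
}

#' Posterior sample from a profile regression fit
#'
#' Holds the thinned MCMC output of [profileRegression()]: per-subject risks on
#' the probability scale, cluster allocations, imputed values for the missing
#' covariate entries, the concentration parameter, occupied-cluster counts, a
#' complete-data log-likelihood trace, and acceptance-rate diagnostics. All
#' reported summaries downstream ([similarityMatrix()], [groupRiskDraws()],
#' [profileDeviations()]) are invariant to cluster relabelling.
#'
#' @slot risk numeric matrix, retained iterations x subjects, each entry the
#'   subject's disease probability at that iteration.
#' @slot allocations integer matrix, retained iterations x subjects.
#' @slot imputed integer matrix of 0-based imputed codes, retained iterations x
#'   number of missing entries (zero columns when the data are complete).
#' @slot missIndex two-column integer matrix (subject, covariate) locating the
#'   columns of `imputed` in the covariate matrix.
#' @slot kOccupied,alpha,logLik per-iteration scalars.
#' @slot acceptance named list of acceptance rates for the Metropolis moves.
#' @slot mode `"plain"` or `"logistic"`.
#' @slot beta numeric matrix of confounder coefficient draws (0 columns in
#'   plain mode).
#' @slot settings the sampler settings used, including the seed.
#' @slot data the [ProfileDataset-class] the sampler was run on.
#' @aliases ProfileRegressionFit-class
#' @exportClass ProfileRegressionFit
setClass("ProfileRegressionFit", representation(
    risk = "matrix",
    allocations = "matrix",
    imputed = "matrix",
    missIndex = "matrix",
    kOccupied = "integer",
    alpha = "numeric",
    logLik = "numeric",
    acceptance = "list",
    mode = "character",
    beta = "matrix",
    settings = "list",
    data = "ProfileDataset"))

setValidity("ProfileRegressionFit", function(object) {
    msg <- character()
    TT <- nrow(object@risk)
    if (nrow(object@allocations) != TT)
        msg <- c(msg, "risk and allocations must have equal iteration counts")
    if (any(object@risk <= 0 | object@risk >= 1))
        msg <- c(msg, "risks must lie strictly in (0,1)")
    if (length(object@kOccupied) != TT)
        msg <- c(msg, "kOccupied length must match retained iterations")
    if (length(msg)) msg else TRUE
})

#' Representative partition derived from a similarity matrix
#'
#' The single deterministic clustering that most closely matches the posterior
#' similarity matrix, scored by the least-squares discrepancy
#' \eqn{\sum_{i<j} (S_{ij} - A_{ij})^2} where \eqn{A_{ij} = 1} when subjects
#' share a group. Produced by [bestPartition()].
#'
#' @slot labels integer group labels `1..G`, relabelled by decreasing group
#'   size.
#' @slot groupSizes integer group sizes, summing to the number of subjects.
#' @slot score the least-squares discrepancy of the partition to the
#'   similarity matrix.
#' @slot method `"exhaustive"` or `"pam"`.
#' @aliases BestPartition-class
#' @exportClass BestPartition
setClass("BestPartition", representation(
    labels = "integer",
    groupSizes = "integer",
    score = "numeric",
    method = "character"))

setValidity("BestPartition", function(object) {
    if (sum(object@groupSizes) != length(object@labels))
        "group sizes must sum to the number of subjects" else TRUE
})

setMethod("show", "ProfileDataset", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("ProfileDataset:", ncol(object), "subjects,", nrow(object),
        "covariates\n")
    cat(sprintf("  cases: %d  controls: %d\n",
                sum(cd$y == 1), sum(cd$y == 0)))
    rd <- SummarizedExperiment::rowData(object)
    nm <- sum(SummarizedExperiment::assay(object, "missing"))
    cat(sprintf("  kinds: %d nominal, %d ordinal; %d missing entries\n",
                sum(rd$kind == "nominal"), sum(rd$kind == "ordinal"), nm))
    conf <- S4Vectors::metadata(object)$confounders
    if (length(conf)) cat("  confounders:", paste(conf, collapse = ", "), "\n")
    invisible(object)
})

setMethod("show", "ProfileRegressionFit", function(object) {
    cat("ProfileRegressionFit (", object@mode, " disease submodel)\n",
        sep = "")
    cat(sprintf("  %d retained iterations, %d subjects\n",
                nrow(object@risk), ncol(object@risk)))
    cat(sprintf("  occupied clusters: median %d (range %d-%d)\n",
                as.integer(stats::median(object@kOccupied)),
                min(object@kOccupied), max(object@kOccupied)))
    if (ncol(object@imputed))
        cat(sprintf("  %d missing covariate entries imputed per sweep\n",
                    ncol(object@imputed)))
    invisible(object)
})

setMethod("show", "BestPartition", function(object) {
    cat("BestPartition:", length(object@groupSizes), "groups (",
        paste(object@groupSizes, collapse = ", "), "subjects ) — method:",
        object@method, "\n")
    cat("  least-squares score vs similarity matrix:",
        format(object@score, digits = 6), "\n")
    invisible(object)
})
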