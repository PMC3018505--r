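# Delimited-text input/output for ProfileDataset with a YAML/JSON covariate
# declaration. The config names the outcome column and, per covariate, its
# kind (nominal/ordinal) and number of categories; optional confounder
# columns are taken as already numeric.

.cfgField <- function(x, ...) {
    for (key in c(...)) if (!is.null(x[[key]])) return(x[[key]])
    NULL
}

#' Read a covariate declaration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file declaring `outcome`,
#'   `covariates` (each with `name`, `kind`, `n_categories`, optional
#'   `labels`), optional `confounders`, `missing_code` and
#'   `center_confounders`.
#' @return the configuration as a list.
#' @export
readProfileConfig <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                                simplifyDataFrame = FALSE)
    else stop("config must be a .yaml or .json file")
}

#' Load a case-control dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row and assembles a validated
#' [ProfileDataset-class] according to a covariate declaration. Category
#' values are re-coded to 0-based contiguous integers: columns already coded
#' `0..M-1` are kept as-is; otherwise the sorted unique observed values (or
#' the declared `labels`, in order) define the coding, and the original
#' labels are retained in the covariate metadata for reporting. Rows with a
#' missing outcome are dropped with a message; rows with missing confounder
#' values are dropped with a warning (covariates are the only variables the
#' model imputes).
#'
#' @param path delimited text file; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param config a configuration list or the path to one (see
#'   [readProfileConfig()]).
#' @param missingCode string marking missing covariate entries (default from
#'   the config, falling back to `"NA"`).
#' @return a [ProfileDataset-class].
#' @export
readProfileDataset <- function(path, config, missingCode = NULL) {
    if (is.character(config) && length(config) == 1L)
        config <- readProfileConfig(config)
    if (is.null(missingCode))
        missingCode <- .cfgField(config, "missing_code", "missingCode")
    if (is.null(missingCode)) missingCode <- "NA"
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character",
                             check.names = FALSE, na.strings = NULL,
                             stringsAsFactors = FALSE)
    outcomeCol <- .cfgField(config, "outcome")
    confCols <- .cfgField(config, "confounders")
    if (is.null(confCols)) confCols <- character()
    covs <- config$covariates
    covNames <- vapply(covs, function(x) as.character(.cfgField(x, "name")),
                       "")
    for (col in c(outcomeCol, covNames, confCols))
        if (!col %in% names(raw))
            stop(sprintf("column '%s' not found in %s", col, path))

    isMissing <- function(v) is.na(v) | v == missingCode | v == ""
    yRaw <- raw[[outcomeCol]]
    keep <- !isMissing(yRaw)
    if (any(!keep))
        message(sprintf("dropped %d row(s) with missing outcome",
                        sum(!keep)))
    raw <- raw[keep, , drop = FALSE]
    y <- suppressWarnings(as.integer(raw[[outcomeCol]]))
    if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
        stop(sprintf("outcome column '%s' must contain only 0 and 1",
                     outcomeCol))

    W <- NULL
    if (length(confCols)) {
        W <- vapply(confCols, function(cn)
            suppressWarnings(as.numeric(ifelse(isMissing(raw[[cn]]), NA,
                                               raw[[cn]]))),
            numeric(nrow(raw)))
        W <- matrix(W, ncol = length(confCols),
                    dimnames = list(NULL, confCols))
        bad <- rowSums(is.na(W)) > 0L
        if (any(bad)) {
            warning(sprintf(
                "dropped %d row(s) with missing confounder values",
                sum(bad)))
            raw <- raw[!bad, , drop = FALSE]
            y <- y[!bad]
            W <- W[!bad, , drop = FALSE]
        }
        if (isTRUE(.cfgField(config, "center_confounders",
                             "centerConfounders")))
            W <- scale(W, center = TRUE, scale = FALSE)
    }

    n <- nrow(raw)
    P <- length(covs)
    X <- matrix(NA_integer_, n, P, dimnames = list(NULL, covNames))
    labelList <- vector("list", P)
    for (p in seq_len(P)) {
        M <- as.integer(.cfgField(covs[[p]], "n_categories", "nCategories"))
        v <- raw[[covNames[p]]]
        miss <- isMissing(v)
        if (all(miss))
            stop(sprintf("covariate '%s' is entirely missing", covNames[p]))
        obs <- v[!miss]
        labels <- .cfgField(covs[[p]], "labels")
        if (!is.null(labels)) {
            labels <- as.character(labels)
            code <- match(obs, labels) - 1L
            if (anyNA(code)) {
                i <- which(!miss)[which(is.na(code))[1L]]
                stop(sprintf(
                    "covariate '%s', row %d: value '%s' not in labels",
                    covNames[p], i, v[i]))
            }
        } else {
            num <- suppressWarnings(as.numeric(obs))
            if (!anyNA(num) && all(num == floor(num)) &&
                all(num >= 0) && all(num <= M - 1L)) {
                code <- as.integer(num)        # identity coding
                labels <- as.character(seq_len(M) - 1L)
            } else {
                labels <- if (!anyNA(num)) as.character(sort(unique(num)))
                          else sort(unique(obs))
                if (length(labels) > M)
                    stop(sprintf(
                        "covariate '%s' has %d distinct values but %d declared categories",
                        covNames[p], length(labels), M))
                code <- match(as.character(if (!anyNA(num)) num else obs),
                              labels) - 1L
            }
        }
        if (any(code < 0L | code >= M)) {
            i <- which(!miss)[which(code < 0L | code >= M)[1L]]
            stop(sprintf(
                "covariate '%s', row %d: category '%s' outside 0..%d",
                covNames[p], i, v[i], M - 1L))
        }
        X[!miss, p] <- code
        labelList[[p]] <- labels
    }
    specs <- data.frame(
        name = covNames,
        kind = vapply(covs, function(x) as.character(.cfgField(x, "kind")),
                      ""),
        nCategories = vapply(covs, function(x)
            as.integer(.cfgField(x, "n_categories", "nCategories")), 1L),
        stringsAsFactors = FALSE)
    specs$labels <- labelList
    ProfileDataset(X, y, specs, W = W)
}

#' Write a ProfileDataset back to delimited text
#'
#' Writes the 0-based covariate codes (missing entries as `missingCode`), the
#' outcome as column `y`, and any confounder columns. Re-loading the file
#' with the matching configuration ([profileConfig()]) reproduces the
#' dataset exactly.
#'
#' @param data a [ProfileDataset-class].
#' @param path output file; `.csv` gives comma separation, anything else
#'   tabs.
#' @param missingCode string written at missing entries.
#' @return `path`, invisibly.
#' @export
writeProfileDataset <- function(data, path, missingCode = "NA") {
    X <- covariateMatrix(data)
    out <- as.data.frame(X)
    for (p in seq_along(out))
        out[[p]] <- ifelse(is.na(out[[p]]), missingCode,
                           as.character(out[[p]]))
    out$y <- outcome(data)
    W <- confounders(data)
    for (q in seq_len(ncol(W))) out[[colnames(W)[q]]] <- W[, q]
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Configuration matching a ProfileDataset
#'
#' Builds the covariate declaration that [readProfileDataset()] needs to
#' re-load a file written by [writeProfileDataset()].
#'
#' @param data a [ProfileDataset-class].
#' @param missingCode missing-value marker to declare.
#' @return a configuration list.
#' @export
profileConfig <- function(data, missingCode = "NA") {
    specs <- covariateSpecs(data)
    list(outcome = "y",
         missing_code = missingCode,
         covariates = lapply(seq_len(nrow(specs)), function(p)
             list(name = specs$name[p], kind = specs$kind[p],
                  n_categories = specs$nCategories[p])),
         confounders = as.list(S4Vectors::metadata(data)$confounders))
}

#' Summarise a ProfileDataset
#'
#' Case/control counts, the sample-average risk (case fraction), per-covariate
#' category frequencies among non-missing entries (each summing to 1), and
#' per-covariate missingness counts.
#'
#' @param data a [ProfileDataset-class].
#' @return a list with `nSubjects`, `nCases`, `nControls`, `caseFraction`,
#'   `nConfounders`, `categoryFreq` (named list of frequency vectors) and
#'   `missingCounts` (named integer vector).
#' @examples
#' pd <- syntheticPreset("null", n = 50, seed = 1)$data
#' summarizeProfiles(pd)$caseFraction
#' @export
summarizeProfiles <- function(data) {
    stopifnot(is(data, "ProfileDataset"))
    X <- covariateMatrix(data)
    y <- outcome(data)
    specs <- covariateSpecs(data)
    freq <- lapply(seq_len(ncol(X)), function(p) {
        xp <- X[, p]
        xp <- xp[!is.na(xp)]
        f <- tabulate(xp + 1L, specs$nCategories[p])
        setNames(f / sum(f), seq_len(specs$nCategories[p]) - 1L)
    })
    names(freq) <- specs$name
    list(nSubjects = length(y),
         nCases = sum(y == 1L),
         nControls = sum(y == 0L),
         caseFraction = mean(y == 1L),
         nConfounders = ncol(confounders(data)),
         categoryFreq = freq,
         missingCounts = setNames(colSums(is.na(X)), specs$name))
}
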