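test_that("delimited text loads with identity coding and missing mapping", {
    dir <- withr::local_tempdir()
    f <- file.path(dir, "toy.csv")
    writeLines(c("mainroad,pm10,y",
                 "0,NA,1",
                 "1,2,0",
                 "1,0,0"), f)
    cfg <- list(outcome = "y", missing_code = "NA",
                covariates = list(
                    list(name = "mainroad", kind = "nominal",
                         n_categories = 2),
                    list(name = "pm10", kind = "ordinal",
                         n_categories = 4)))
    pd <- readProfileDataset(f, cfg)
    X <- covariateMatrix(pd)
    expect_identical(unname(X[, "mainroad"]), c(0L, 1L, 1L))
    expect_identical(unname(X[, "pm10"]), c(NA_integer_, 2L, 0L))
    expect_identical(unname(missingMask(pd)),
                     cbind(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE)))
    expect_identical(outcome(pd), c(1L, 0L, 0L))
})

test_that("loader errors name the offending column and cell", {
    dir <- withr::local_tempdir()
    f <- file.path(dir, "bad.csv")
    writeLines(c("a,y", "5,1", "2,0", "0,0"), f)
    cfg <- list(outcome = "y", covariates = list(
        list(name = "a", kind = "nominal", n_categories = 2)))
    expect_error(readProfileDataset(f, cfg), "distinct values")
    # declared labels make any unlisted value an error with its location
    cfgLab <- list(outcome = "y", covariates = list(
        list(name = "a", kind = "nominal", n_categories = 2,
             labels = c("0", "2"))))
    expect_error(readProfileDataset(f, cfgLab), "row 1")
    cfgUnknown <- list(outcome = "y", covariates = list(
        list(name = "zzz", kind = "nominal", n_categories = 2)))
    expect_error(readProfileDataset(f, cfgUnknown), "zzz")
    f2 <- file.path(dir, "allmiss.csv")
    writeLines(c("a,y", "NA,1", "NA,0"), f2)
    expect_error(readProfileDataset(f2, cfg), "entirely missing")
})

test_that("rows with missing outcome are dropped with a count", {
    dir <- withr::local_tempdir()
    f <- file.path(dir, "miss.csv")
    writeLines(c("a,y", "0,1", "1,NA", "1,0"), f)
    cfg <- list(outcome = "y", covariates = list(
        list(name = "a", kind = "nominal", n_categories = 2)))
    expect_message(pd <- readProfileDataset(f, cfg), "1 row")
    expect_identical(ncol(pd), 2L)
})

test_that("the nine-covariate study coding is representable", {
    # binary road proximity; 4-level PM10; 3-level NO2; 4-level work
    # activity; 3-level leisure activity; 3-level BMI; two binary genetic
    # markers; 3-level DNA adducts
    sim <- syntheticPreset("paper_shape", seed = 5)
    expect_identical(unname(nCategories(sim$data)),
                     c(2L, 4L, 3L, 4L, 3L, 3L, 2L, 2L, 3L))
    expect_identical(covariateSpecs(sim$data)$kind[c(1, 2, 3)],
                     c("nominal", "ordinal", "ordinal"))
})

test_that("summary reports the sample-average risk and missingness", {
    pd <- countedDataset(63L, 482L)
    s <- summarizeProfiles(pd)
    expect_equal(s$caseFraction, 63 / 545)
    expect_equal(s$nCases, 63L)
    expect_equal(s$nConfounders, 0L)
    # frequencies over non-missing entries each sum to 1
    for (f in s$categoryFreq) expect_equal(sum(f), 1, tolerance = 1e-12)
})

test_that("generated MCAR missingness is reported at its planted rate", {
    sp <- data.frame(name = c("a", "b"), kind = c("nominal", "ordinal"),
                     nCategories = c(2L, 3L), stringsAsFactors = FALSE)
    phi <- list(rbind(c(0.6, 0.4)), rbind(c(0.3, 0.4, 0.3)))
    sim <- syntheticProfiles(n = 1000, weights = 1, theta = 0.2,
                             specs = sp, phi = phi,
                             missingRate = c(0, 0.3), seed = 42)
    s <- summarizeProfiles(sim$data)
    expect_lt(abs(s$missingCounts[["b"]] / 1000 - 0.3), 0.03)
    expect_identical(s$missingCounts[["a"]], 0)
})

test_that("write/read round-trip reproduces the dataset exactly", {
    sim <- syntheticPreset("paper_shape", n = 120, seed = 9)
    pd <- sim$data
    dir <- withr::local_tempdir()
    f <- file.path(dir, "rt.csv")
    writeProfileDataset(pd, f)
    back <- readProfileDataset(f, profileConfig(pd))
    expect_identical(covariateMatrix(back), covariateMatrix(pd))
    expect_identical(outcome(back), outcome(pd))
    expect_identical(missingMask(back), missingMask(pd))
    expect_identical(unname(confounders(back)), unname(confounders(pd)))
})

test_that("validity rejects malformed containers", {
    sp <- binarySpecs(1)
    expect_error(ProfileDataset(cbind(f1 = c(0L, 3L)), c(1, 0), sp),
                 "outside")
    expect_error(ProfileDataset(cbind(f1 = c(0L, 1L)), c(1, 1), sp),
                 "control")
    expect_error(ProfileDataset(cbind(f1 = c(NA_integer_, NA_integer_)),
                                c(1, 0), sp),
                 "entirely missing")
})
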