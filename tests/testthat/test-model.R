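test_that("rank-1 fits recover exact multiplicative structure", {
    X <- matrix(6, 2, 3)
    fit <- fitRank1(X)
    expect_equal(fit@affinity, c(1, 1, 1))
    expect_equal(fit@theta, c(6, 6))
    expect_equal(max(abs(fit@residuals)), 0)

    X2 <- outer(c(2, 4), c(0.5, 2))          # geomean(a) already 1
    fit2 <- fitRank1(X2)
    expect_equal(fit2@theta, c(2, 4))
    expect_equal(fit2@affinity, c(0.5, 2))
    expect_equal(sqrt(sum(fit2@residuals^2)), 0)

    expect_error(fitRank1(matrix(0, 2, 2)), "all-zero")
})

test_that("the affinity constraint and scale equivariance hold on random data", {
    set.seed(41)
    for (i in 1:20) {
        X <- matrix(rlnorm(24, 4, 1), 4, 6)
        fit <- fitRank1(X)
        expect_equal(exp(mean(log(fit@affinity))), 1, tolerance = 1e-12)
        expect_true(all(fit@affinity > 0))
        expect_true(all(fit@theta > 0))
        k <- runif(1, 0.1, 10)
        fitK <- fitRank1(k * X)
        expect_equal(fitK@theta, k * fit@theta, tolerance = 1e-9)
        expect_equal(fitK@affinity, fit@affinity, tolerance = 1e-9)
    }
})

test_that("the SVD fit attains the brute-force rank-1 optimum", {
    set.seed(42)
    for (i in 1:20) {
        X <- matrix(rlnorm(24, 4, 1), 4, 6)
        ours <- sqrt(sum(fitRank1(X)@residuals^2))
        expect_equal(ours, alsRank1Residual(X), tolerance = 1e-6)
    }
})

test_that("EM with an empty mask is the plain fit", {
    X <- matrix(rlnorm(24, 4, 1), 4, 6)
    em <- imputeEM(X, matrix(FALSE, 4, 6))
    fit <- fitRank1(X)
    expect_equal(em@theta, fit@theta)
    expect_identical(em@completed, X)
    expect_equal(em@nIter, 1L)
})

test_that("rank-1 completion solves the 2x2 identity and recovers exact low rank", {
    # a single weakly anchored cell converges slowly: give the linear
    # iteration room to reach its fixed point x22 = x12*x21/x11
    X <- matrix(c(1, 2, 4, 8), 2, 2)         # [[1,4],[2,8]]
    mask <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
    em <- imputeEM(X, mask, maxIter = 5000L)
    expect_equal(em@completed[2, 2], 8, tolerance = 1e-6)

    set.seed(43)
    theta <- rlnorm(4, 4, 1); a <- exp(rnorm(6, 0, 0.5))
    a <- a / exp(mean(log(a)))
    X <- tcrossprod(theta, a)
    mask <- matrix(runif(24) < 0.2, 4, 6)
    mask[, 1] <- FALSE                        # keep every chip anchored
    em <- suppressWarnings(imputeEM(X, mask, tol = 1e-14, maxIter = 20000L))
    expect_lt(max(abs(em@completed[mask] - X[mask]) / X[mask]), 1e-6)
    expect_true(em@converged)
})

test_that("EM error is non-increasing and converges on noisy masked data", {
    set.seed(44)
    for (i in 1:10) {
        X <- matrix(rlnorm(48, 4, 0.8), 6, 8)
        mask <- matrix(runif(48) < 0.2, 6, 8)
        if (all(mask)) next
        em <- suppressWarnings(imputeEM(X, mask, maxIter = 2000L))
        expect_true(em@converged)            # monotonicity asserted internally
    }
})

test_that("non-convergence at the iteration cap is flagged, not hidden", {
    X <- matrix(c(1, 2, 4, 8), 2, 2)
    mask <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
    expect_warning(em <- imputeEM(X, mask, maxIter = 10L), "did not converge")
    expect_false(em@converged)
    expect_equal(em@nIter, 10L)
})

test_that("mismatch flags have no effect on fitted expression", {
    sim <- simulateBatch(simConfig(nChips = 6L, nCols = 16L, nRows = 16L,
                                   nProbeSets = 20L, probesPerSet = 8L,
                                   noiseSd = 0, seed = 88L))
    mats <- probeSetMatrices(sim$chipset)
    rd <- SummarizedExperiment::rowData(sim$chipset)
    expect_true(any(rd$isMismatch, na.rm = TRUE))  # both kinds present
    for (ps in names(mats)[1:5]) {
        fit <- fitRank1(mats[[ps]]$X, ps)
        expect_equal(fit@theta, unname(sim$theta[ps, ]), tolerance = 1e-9)
    }
})

test_that("expression tables are natural-log and round trip through TSV", {
    m1 <- fitRank1(outer(c(2, 4), c(0.5, 2)), "psB")
    m2 <- fitRank1(matrix(6, 2, 3), "psA")
    tab <- expressionTable(list(m1, m2), chipIds = c("c1", "c2"))
    expect_equal(rownames(tab), c("psA", "psB"))   # ordered by id
    expect_equal(unname(tab["psB", ]), log(c(2, 4)))
    expect_equal(unname(tab["psA", ]), log(c(6, 6)))
    p <- withr::local_tempfile()
    writeExpressionTable(tab, p)
    expect_equal(readExpressionTable(p), tab, tolerance = 1e-12)
})

test_that("residual maps localize an injected hot spot and shrink after imputation", {
    sim <- simulateBatch(simConfig(nChips = 6L, nCols = 32L, nRows = 32L,
                                   nProbeSets = 100L, probesPerSet = 8L,
                                   seed = 89L))
    ins <- injectDisk(sim$chipset, chip = 2L, center = c(16, 16),
                      diameter = 15, factor = 3)
    norm <- normalizeIteratively(ins$chipset, segment = FALSE)$chipset
    models <- fitProbeSets(norm)
    rmap <- residualMap(models, norm, 2L)
    rd <- SummarizedExperiment::rowData(norm)
    fp <- maskMatrix(ins$footprint)[, 2] & !is.na(rd$probeSet)
    grid <- rmap[cbind(rd$y + 1, rd$x + 1)]
    expect_gt(median(grid[fp]), 0)            # hot spot: positive residuals

    modelsI <- fitProbeSets(norm, ins$footprint)
    rmapI <- residualMap(modelsI, norm, 2L)
    gridI <- rmapI[cbind(rd$y + 1, rd$x + 1)]
    expect_lt(median(abs(gridI[fp])), median(abs(grid[fp])))

    clean <- fitRank1(outer(c(2, 4), c(0.5, 2)), "ps1")
    cleanMap <- residualMap(list(clean), makeChipSet(
        t(outer(c(2, 4), c(0.5, 2))), 2L, 1L), 1L)
    expect_equal(max(abs(cleanMap)), 0, tolerance = 1e-12)
})
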