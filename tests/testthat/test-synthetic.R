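test_that("the generator is deterministic and satisfies its own model", {
    cfg <- simConfig(nChips = 5L, nCols = 16L, nRows = 16L, nProbeSets = 20L,
                     probesPerSet = 8L, seed = 91L)
    a <- simulateBatch(cfg)
    b <- simulateBatch(cfg)
    expect_identical(intensities(a$chipset), intensities(b$chipset))
    expect_identical(a$theta, b$theta)

    for (ps in names(a$affinity))
        expect_equal(exp(mean(log(a$affinity[[ps]]))), 1, tolerance = 1e-12)
})

test_that("at zero noise the rank-1 fit recovers the generating parameters", {
    cfg <- simConfig(nChips = 5L, nCols = 16L, nRows = 16L, nProbeSets = 20L,
                     probesPerSet = 8L, noiseSd = 0, seed = 92L)
    sim <- simulateBatch(cfg)
    mats <- probeSetMatrices(sim$chipset)
    for (ps in names(mats)[c(1, 7, 20)]) {
        fit <- fitRank1(mats[[ps]]$X, ps)
        expect_equal(fit@theta, unname(sim$theta[ps, ]), tolerance = 1e-9)
        expect_equal(fit@affinity,
                     unname(sim$affinity[[ps]][colnames(mats[[ps]]$X)]),
                     tolerance = 1e-9)
    }
})

test_that("parameter recovery error vanishes as noise does", {
    errs <- vapply(c(0, 0.01, 0.1), function(ns) {
        sim <- simulateBatch(simConfig(nChips = 6L, nCols = 16L, nRows = 16L,
                                       nProbeSets = 20L, probesPerSet = 8L,
                                       noiseSd = ns, seed = 93L))
        mats <- probeSetMatrices(sim$chipset)
        mean(vapply(names(mats), function(ps)
            mean(abs(log(fitRank1(mats[[ps]]$X, ps)@theta) -
                     log(sim$theta[ps, ]))), 0))
    }, 0)
    expect_lt(errs[1], 1e-9)
    expect_true(all(diff(errs) > 0))
})

test_that("disk insults alter exactly the enumerated footprint", {
    cs <- makeChipSet(matrix(100, 1600, 4), 40L, 40L)
    ins <- injectDisk(cs, chip = 2L, center = c(20, 20), diameter = 10,
                      factor = 2)
    fp <- maskMatrix(ins$footprint)
    expect_equal(sum(fp), 81L)               # integer points with dx^2+dy^2 <= 25
    expect_true(all(fp[, -2] == FALSE))
    m0 <- intensities(cs); m1 <- intensities(ins$chipset)
    expect_identical(m1[!fp], m0[!fp])       # locality, bit-identical outside
    expect_equal(m1[fp], 2 * m0[fp])

    neutral <- injectDisk(cs, chip = 1L, center = c(20, 20), diameter = 10,
                          factor = 1)
    expect_identical(intensities(neutral$chipset), m0)
    expect_equal(sum(maskMatrix(neutral$footprint)), 81L)

    expect_error(injectDisk(cs, 1L, center = c(1, 20), diameter = 30, factor = 2),
                 "half the radius")
})

test_that("a 75-probe disk on a 200x200 chip matches brute-force enumeration", {
    n <- 200L
    cs <- makeChipSet(matrix(50, n * n, 4), n, n)
    center <- c(99.5, 120.25)
    ins <- injectDisk(cs, chip = 3L, center = center, diameter = 75, factor = 2)
    fp <- maskMatrix(ins$footprint)[, 3]
    g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
    brute <- (g$x - center[1])^2 + (g$y - center[2])^2 <= 37.5^2
    expect_equal(sum(fp), sum(brute))
    expect_equal(unname(which(fp)), which(brute))
    m0 <- intensities(cs); m1 <- intensities(ins$chipset)
    expect_equal(unname(m1[fp, 3]), rep(100, sum(fp)))
    expect_identical(m1[!fp, 3], m0[!fp, 3])
})

test_that("ellipses degenerate to disks and black holes lower every footprint value", {
    cs <- makeChipSet(matrix(100, 1600, 4), 40L, 40L)
    disk <- injectDisk(cs, 1L, center = c(20, 20), diameter = 14, factor = 2)
    ell <- injectEllipse(cs, 1L, center = c(20, 20), axes = c(7, 7),
                         angle = 0.7, factor = 2)
    expect_identical(maskMatrix(ell$footprint), maskMatrix(disk$footprint))

    bh <- injectEllipse(cs, 2L, center = c(20, 18), axes = c(9, 4),
                        angle = pi / 6, factor = 0.25)
    fp <- maskMatrix(bh$footprint)
    expect_gt(sum(fp), 0)
    expect_true(all(intensities(bh$chipset)[fp] < intensities(cs)[fp]))

    spec <- artifactSpec("ellipse", "chip2", center = c(20, 18),
                         axes = c(9, 4), angle = pi / 6, factor = 0.25)
    viaSpec <- injectArtifact(cs, spec)
    expect_identical(maskMatrix(viaSpec$footprint), fp)
})

test_that("the chip-thirds protocol alters two row bands and yields a trimodal chip", {
    sim <- simulateBatch(simConfig(nChips = 6L, nCols = 32L, nRows = 32L,
                                   nProbeSets = 100L, probesPerSet = 8L,
                                   seed = 94L))
    ins <- injectThirds(sim$chipset, chip = 1L)
    nAltered <- sum(maskMatrix(ins$footprints$low)) +
        sum(maskMatrix(ins$footprints$high))
    expect_equal(nAltered, 2L * (32L %/% 3L) * 32L)

    m0 <- intensities(sim$chipset); m1 <- intensities(ins$chipset)
    lo <- maskMatrix(ins$footprints$low)[, 1]
    hi <- maskMatrix(ins$footprints$high)[, 1]
    expect_equal(m1[lo, 1], 0.5 * m0[lo, 1])
    expect_equal(m1[hi, 1], 10 * m0[hi, 1])
    expect_identical(m1[!lo & !hi, 1], m0[!lo & !hi, 1])

    # three separated intensity modes on the altered chip (log scale)
    d <- stats::density(log2(m1[, 1]), bw = 0.3)
    peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
    expect_gte(length(peaks[d$y[peaks] > 0.05 * max(d$y)]), 3L)

    same <- injectThirds(sim$chipset, chip = 1L, fLow = 1, fHigh = 1)
    expect_identical(intensities(same$chipset), m0)
})
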