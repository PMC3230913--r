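.diskGrid <- function(n = 40L, radius = 5, center = c(20, 20), hi = 10) {
    g <- matrix(0, n, n)
    for (y in seq_len(n)) for (x in seq_len(n))
        if ((x - 1 - center[1])^2 + (y - 1 - center[2])^2 <= radius^2)
            g[y, x] <- hi
    g
}

test_that("a high-score disk is flagged per window enumeration, background untouched", {
    g <- .diskGrid()
    sm <- makeScoreMap(list(g), 40L, 40L)
    mk <- segmentArtifacts(sm, window = 5L, tProbe = 1, tRegion = 1,
                           fMin = 0.5, thresholdMode = "absolute")
    dist2 <- (sm@x - 20)^2 + (sm@y - 20)^2
    inDisk <- dist2 <= 25
    expect_equal(sum(inDisk), 81L)            # integer points with dx^2+dy^2 <= 25
    # flags equal the brute-force window enumeration exactly
    oracle <- segOracle(g, 5L, 1, 1, 0.5)
    expect_identical(unname(mk@flags[, 1]),
                     oracle[cbind(sm@y + 1L, sm@x + 1L)])
    # the disk interior is flagged; only rim probes whose window majority
    # falls outside the disk escape (their window fraction is below 1/2)
    expect_true(all(mk@flags[dist2 <= 4^2, 1]))
    expect_true(all(inDisk[mk@flags[, 1]]))   # nothing outside the disk
    farBg <- dist2 > (5 + 3)^2
    expect_false(any(mk@flags[farBg, 1]))
    expect_equal(unname(coverageFraction(mk, 1)), sum(oracle) / 1600)
})

test_that("constant score fields yield empty masks under quantile thresholds", {
    for (const in c(0, 2.5)) {
        sm <- makeScoreMap(list(matrix(const, 20, 20)), 20L, 20L)
        for (mode in c("robust", "empirical")) {
            mk <- segmentArtifacts(sm, window = 5L, thresholdMode = mode)
            expect_false(any(mk@flags), info = paste(mode, const))
        }
    }
})

test_that("an isolated extreme probe is never flagged", {
    g <- matrix(0, 30, 30)
    g[15, 15] <- 100
    sm <- makeScoreMap(list(g), 30L, 30L)
    mk <- segmentArtifacts(sm, window = 5L, tProbe = 1, tRegion = 1,
                           fMin = 0.5, thresholdMode = "absolute")
    expect_false(any(mk@flags))
})

test_that("raising scores inside a flagged region cannot unflag it", {
    g <- .diskGrid()
    sm <- makeScoreMap(list(g), 40L, 40L)
    base <- segmentArtifacts(sm, window = 5L, tProbe = 1, tRegion = 1,
                             fMin = 0.5, thresholdMode = "absolute")
    g2 <- g; g2[g > 0] <- g[g > 0] * 3
    sm2 <- makeScoreMap(list(g2), 40L, 40L)
    up <- segmentArtifacts(sm2, window = 5L, tProbe = 1, tRegion = 1,
                           fMin = 0.5, thresholdMode = "absolute")
    expect_true(all(up@flags[base@flags]))
})

test_that("segmentation is deterministic and validates its window", {
    set.seed(3)
    sm <- makeScoreMap(list(matrix(rexp(400), 20, 20)), 20L, 20L)
    a <- segmentArtifacts(sm, window = 5L)
    b <- segmentArtifacts(sm, window = 5L)
    expect_identical(a@flags, b@flags)
    expect_error(segmentArtifacts(sm, window = 21L), "exceeds")
    expect_error(segmentArtifacts(sm, window = 4L), "odd")
    expect_error(segmentArtifacts(sm, window = 5L, fMin = 0), "fMin")
})

test_that("undefined scores drop out of the window denominator", {
    g <- .diskGrid()
    g[1:40, 17:19] <- NA                      # a dead stripe through the disk
    sm <- makeScoreMap(list(g), 40L, 40L)
    mk <- segmentArtifacts(sm, window = 5L, tProbe = 1, tRegion = 1,
                           fMin = 0.5, thresholdMode = "absolute")
    oracle <- segOracle(g, 5L, 1, 1, 0.5)
    expect_identical(unname(mk@flags[, 1]),
                     oracle[cbind(sm@y + 1L, sm@x + 1L)])
    # probes beside the stripe still reach the window fraction because the
    # undefined cells do not count toward the denominator
    dist2 <- (sm@x - 20)^2 + (sm@y - 20)^2
    core <- dist2 <= 4^2 & !is.na(g[cbind(sm@y + 1L, sm@x + 1L)])
    expect_true(all(mk@flags[core, 1]))
})

test_that("QC report names overloaded chips and warns on small batches", {
    set.seed(4)
    cs10 <- makeChipSet(matrix(runif(100 * 10, 50, 150), 100, 10), 10L, 10L)
    mk <- emptyMask(cs10)
    mk@flags[1:60, "chip3"] <- TRUE
    rep10 <- qcReport(mk, cs10)
    expect_match(rep10$warnings, "chip3", all = FALSE)
    expect_match(rep10$warnings, "60.0%", all = FALSE)
    expect_equal(rep10$perChip$coverage[rep10$perChip$chip == "chip3"], 0.6)

    cs5 <- makeChipSet(matrix(runif(100 * 5, 50, 150), 100, 5), 10L, 10L)
    rep5 <- qcReport(emptyMask(cs5), cs5)
    expect_match(rep5$warnings, "less than 6", all = FALSE)

    clean <- qcReport(emptyMask(cs10), cs10)
    expect_length(clean$warnings, 0L)

    tp <- withr::local_tempfile(); yp <- withr::local_tempfile()
    writeQcReport(rep10, tp, yp)
    expect_match(readLines(tp), "chip3", all = FALSE)
    y <- yaml::read_yaml(yp)
    expect_equal(y$summary$nChips, 10L)
    expect_length(y$warnings, 1L)
})
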