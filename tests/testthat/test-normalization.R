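.twoChips <- function(a, b) {
    makeChipSet(cbind(chipA = a, chipB = b), length(a), 1L)
}

test_that("the clean reference is the chip-mean quantile function", {
    cs <- .twoChips(c(1, 2, 3, 4), c(2, 4, 6, 8))
    ref <- buildReference(cs)
    expect_equal(ref@values, c(1.5, 3, 4.5, 6))
    expect_equal(ref@levels, (1:4 - 0.5) / 4)

    same <- .twoChips(c(5, 1, 9, 3), c(5, 1, 9, 3))
    expect_equal(buildReference(same)@values, c(1, 3, 5, 9))
})

test_that("masked probes drop out of the reference via plotting-position interpolation", {
    cs <- .twoChips(c(1, 2, 3, 100), c(1, 2, 3, 4))
    mk <- emptyMask(cs)
    mk@flags[4, "chipA"] <- TRUE
    ref <- buildReference(cs, mk)
    # chip A contributes {1,2,3} at positions (1/6, 3/6, 5/6) interpolated
    # to levels (.125, .375, .625, .875) with flat ends:
    #   1, 1 + (.375-1/6)/(1/3), 2 + (.625-.5)/(1/3), 3
    chipA <- c(1, 1.625, 2.375, 3)
    expect_equal(ref@values, (chipA + c(1, 2, 3, 4)) / 2)
})

test_that("plain quantile normalization matches the limma oracle", {
    cs <- .twoChips(c(1, 2, 3, 4), c(2, 4, 6, 8))
    out <- applyNormalization(cs, reference = buildReference(cs))
    expect_equal(unname(intensities(out)),
                 cbind(c(1.5, 3, 4.5, 6), c(1.5, 3, 4.5, 6)))
    expect_equal(scaleState(out), "normalized")

    set.seed(31)
    for (i in 1:5) {
        m <- matrix(runif(200 * 6, 1, 1000), 200, 6)   # distinct values
        cs <- makeChipSet(m, 20L, 10L)
        ours <- intensities(applyNormalization(cs, reference = buildReference(cs)))
        oracle <- limma::normalizeQuantiles(m, ties = TRUE)
        expect_equal(unname(ours), unname(oracle), tolerance = 1e-12)
    }
})

test_that("normalization is monotone per chip and identity on identical chips", {
    set.seed(32)
    m <- matrix(rlnorm(100 * 4, 5, 1), 100, 4)
    cs <- makeChipSet(m, 10L, 10L)
    out <- intensities(applyNormalization(cs, reference = buildReference(cs)))
    for (j in 1:4)
        expect_true(all(diff(out[order(m[, j]), j]) >= 0))

    same <- makeChipSet(cbind(m[, 1], m[, 1], m[, 1]), 10L, 10L)
    outS <- applyNormalization(same, reference = buildReference(same))
    expect_equal(unname(intensities(outS)), unname(cbind(m[, 1], m[, 1], m[, 1])))
})

test_that("chips with identical unmasked multisets normalize identically", {
    set.seed(33)
    v <- rlnorm(100, 5, 1)
    m <- cbind(a = v, b = sample(v), c = rlnorm(100, 5.5, 0.8))
    cs <- makeChipSet(m, 10L, 10L)
    out <- intensities(applyNormalization(cs, reference = buildReference(cs)))
    expect_equal(unname(sort(out[, "a"])), unname(sort(out[, "b"])))
})

test_that("masked probes ride the monotone map instead of shaping it", {
    a <- c(1, 2, 3, 4, 1000)
    b <- c(1.5, 2.5, 3.5, 4.5, 5.5)
    cs <- .twoChips(a, b)
    mk <- emptyMask(cs)
    mk@flags[5, "chipA"] <- TRUE
    ref <- buildReference(cs, mk)
    out <- intensities(applyNormalization(cs, mk, ref))
    # the artifact value lies beyond every unmasked value: flat extrapolation
    # maps it to the top assigned value, and it influenced nothing else
    expect_equal(out[5, "chipA"], max(out[1:4, "chipA"]))
    expect_true(all(diff(out[1:4, "chipA"]) > 0))
})

test_that("ties share the mean of their tied reference values", {
    cs <- .twoChips(c(2, 2, 5, 9), c(1, 3, 6, 10))
    ref <- buildReference(cs)
    out <- intensities(applyNormalization(cs, reference = ref))
    expect_equal(out[1, "chipA"], out[2, "chipA"])
    expect_equal(out[1, "chipA"], mean(ref@values[1:2]))
})

test_that("the iterative loop is plain normalization plus one scoring pass at n_iter = 1", {
    set.seed(34)
    sim <- simulateBatch(simConfig(nChips = 6L, nCols = 16L, nRows = 16L,
                                   nProbeSets = 30L, probesPerSet = 8L, seed = 77L))
    one <- suppressWarnings(normalizeIteratively(sim$chipset, iterations = 1L))
    ref <- buildReference(sim$chipset)
    direct <- applyNormalization(sim$chipset, reference = ref)
    expect_equal(intensities(one$chipset), intensities(direct))
})

test_that("a clean batch converges to an empty mask and identical distributions", {
    sim <- simulateBatch(simConfig(nChips = 8L, nCols = 32L, nRows = 32L,
                                   nProbeSets = 100L, probesPerSet = 8L, seed = 55L))
    res <- normalizeIteratively(sim$chipset, iterations = 4L)
    expect_lt(max(coverageFraction(res$mask)), 0.01)
    m <- intensities(res$chipset)
    ranges <- apply(apply(m, 2L, sort), 1L, function(r) diff(range(r)))
    expect_lt(max(ranges) / median(m), 1e-8)
})
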