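#' Per-probe variance scores across a batch
#'
#' For every grid location and chip, compares the chip's log2 intensity to
#' the distribution of log2 intensities at the same location on all other
#' chips, in the spirit of a t-test for whether the observation belongs to
#' that distribution.  Probes currently flagged as artifact still receive a
#' score but never contribute to any reference set, so artifacts on one
#' chip cannot "ghost" onto clean chips.
#'
#' With `y` the log2 intensity at location `g` on chip `j` and `S` the
#' unmasked log2 intensities at `g` on the other chips:
#' `z = (y - mean(S)) / max(sd(S), floor)` and `h = |z| * sqrt((n-1)/n)`,
#' `n = |S|`.  The `sqrt((n-1)/n)` factor attenuates scores from small
#' reference sets; the standard-deviation floor (0.01 times the batch
#' median of `sd(S)`) keeps scores finite at near-constant locations.
#' Locations with fewer than two reference chips are undefined (`NA`).
#'
#' @param chipset a [ChipSet-class]; linear-scale intensities are log2
#'   transformed internally, `scaleState = "log2"` values are used as is.
#' @param mask an [ArtifactMask-class] of probes to exclude from reference
#'   sets, or `NULL` for none.
#' @return A [ScoreMap-class].
#' @details Batches of 3 or fewer chips are refused: the leave-one-out
#'   reference distribution is then estimated from at most 2 values.
#'   Batches of 4 or 5 chips produce a warning; artifact detection power
#'   grows with batch size and with similarity between the samples.
#' @export
computeScores <- function(chipset, mask = NULL) {
    m <- intensities(chipset)
    N <- ncol(m)
    if (N <= 3L)
        stop(sprintf("batch has %d chips; variance scoring requires more than 3", N),
             call. = FALSE)
    if (N < 6L)
        warning(sprintf("batch has only %d chips; artifact detection power is reduced for batches with less than 6 chips", N))
    y <- if (scaleState(chipset) == "log2") m else log2(m)
    U <- if (is.null(mask)) matrix(TRUE, nrow(y), ncol(y)) else !mask@flags
    yu <- y * U
    s1 <- rowSums(yu)
    s2 <- rowSums(yu * yu)
    nTot <- rowSums(U)
    # leave-one-out sums: drop chip j's own value only where it is unmasked
    n <- matrix(nTot, nrow(y), N) - U
    sum1 <- matrix(s1, nrow(y), N) - yu
    sum2 <- matrix(s2, nrow(y), N) - yu * yu
    mu <- sum1 / n
    varS <- (sum2 - sum1 * sum1 / n) / (n - 1)
    varS[n < 2L] <- NA_real_
    sdS <- sqrt(pmax(varS, 0))
    floorSd <- 0.01 * median(sdS, na.rm = TRUE)
    if (!is.finite(floorSd) || floorSd <= 0) floorSd <- .Machine$double.eps
    z <- (y - mu) / pmax(sdS, floorSd)
    h <- abs(z) * sqrt((n - 1) / n)
    z[n < 2L] <- NA_real_
    h[n < 2L] <- NA_real_
    dimnames(z) <- dimnames(h) <- dimnames(n) <- dimnames(m)
    rd <- SummarizedExperiment::rowData(chipset)
    lay <- chipLayout(chipset)
    new("ScoreMap", z = z, h = h, nEff = matrix(as.integer(n), nrow(n), ncol(n),
                                                dimnames = dimnames(n)),
        x = as.integer(rd$x), y = as.integer(rd$y),
        nCols = lay@nCols, nRows = lay@nRows)
}

# Arrange a per-row vector of values into the nRows x nCols grid.
.toGrid <- function(values, x, y, nCols, nRows) {
    g <- matrix(NA_real_, nRows, nCols)
    g[cbind(y + 1L, x + 1L)] <- values
    g
}

#' Grid of variance scores for one chip
#'
#' @param scores a [ScoreMap-class].
#' @param chip chip identifier or index.
#' @return numeric `nRows x nCols` matrix of `h` scores (`NA` where
#'   undefined), suitable for [renderHeatmap()].
#' @export
scoreGrid <- function(scores, chip) {
    if (is.character(chip) && !(chip %in% colnames(scores@h)))
        stop(sprintf("unknown chip '%s'", chip), call. = FALSE)
    .toGrid(scores@h[, chip], scores@x, scores@y, scores@nCols, scores@nRows)
}

#' Render the variance-score heat map of one chip
#'
#' Dark cells mark high scores (poor quality); probes flagged in `mask`
#' are overlaid in red.
#'
#' @param scores a [ScoreMap-class].
#' @param chip chip identifier or index.
#' @param path output PNG path.
#' @param mask optional [ArtifactMask-class] overlay.
#' @return `path`, invisibly.
#' @export
scoreHeatmap <- function(scores, chip, path, mask = NULL) {
    g <- scoreGrid(scores, chip)
    mg <- if (is.null(mask)) NULL
          else .toGrid(as.numeric(mask@flags[, chip]), scores@x, scores@y,
                       scores@nCols, scores@nRows) > 0
    renderHeatmap(g, kind = "score", path = path, mask = mg)
}

#' Export scores as a tidy table
#' @param scores a [ScoreMap-class].
#' @param path optional TSV output path.
#' @return `data.frame` with columns chip, x, y, z, h (invisibly when
#'   written to `path`).
#' @export
scoreTable <- function(scores, path = NULL) {
    chips <- colnames(scores@h)
    d <- data.frame(
        chip = rep(chips, each = nrow(scores@h)),
        x = rep(scores@x, length(chips)),
        y = rep(scores@y, length(chips)),
        z = as.vector(scores@z),
        h = as.vector(scores@h))
    if (!is.null(path)) {
        write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(d))
    }
    d
}
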