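# Marching-window artifact segmentation of variance-score maps.

# Sum of M over the (2*half+1)-square window centered at each cell, windows
# clipped at the grid border.  M must be free of NA.
.boxSum <- function(M, half) {
    nR <- nrow(M); nC <- ncol(M)
    cs <- apply(M, 2L, cumsum)
    cs <- t(apply(cs, 1L, cumsum))              # summed-area table
    P <- matrix(0, nR + 1L, nC + 1L)
    P[-1L, -1L] <- cs
    r1 <- pmax(seq_len(nR) - half, 1L); r2 <- pmin(seq_len(nR) + half, nR)
    c1 <- pmax(seq_len(nC) - half, 1L); c2 <- pmin(seq_len(nC) + half, nC)
    R2 <- matrix(r2 + 1L, nR, nC); R1 <- matrix(r1, nR, nC)
    C2 <- matrix(c2 + 1L, nR, nC, byrow = TRUE); C1 <- matrix(c1, nR, nC, byrow = TRUE)
    idx <- function(r, c) (c - 1L) * (nR + 1L) + r
    P[idx(R2, C2)] - P[idx(R1, C2)] - P[idx(R2, C1)] + P[idx(R1, C1)]
}

.resolveThresholds <- function(h, tProbe, tRegion, thresholdMode) {
    if (thresholdMode == "absolute")
        return(c(tProbe = tProbe, tRegion = tRegion))
    v <- h[is.finite(h)]
    if (!length(v)) return(c(tProbe = Inf, tRegion = Inf))
    if (thresholdMode == "empirical")
        return(c(tProbe = unname(quantile(v, tProbe)),
                 tRegion = unname(quantile(v, tRegion))))
    # robust: calibrate a half-normal null from the batch median of h, so
    # thresholds track the quantile levels of the uncontaminated score
    # distribution even when a large artifact occupies the upper tail
    s <- median(v) / qnorm(0.75)
    if (s <= 0) s <- .Machine$double.eps
    c(tProbe = s * qnorm((1 + tProbe) / 2), tRegion = s * qnorm((1 + tRegion) / 2))
}

#' Segment variance scores into a binary artifact mask
#'
#' Flags a probe when two conditions hold simultaneously: (1) it sits in a
#' neighborhood of other high-scoring probes -- at least `fMin` of the
#' defined probes in the `window x window` square centered on it exceed the
#' region threshold -- and (2) its own score exceeds the probe threshold.
#' Requiring both keeps isolated single-probe outliers (which downstream
#' summarization methods handle well) unflagged while catching spatially
#' coherent artifacts.
#'
#' Thresholds are interpreted per `thresholdMode`:
#' \describe{
#'   \item{`"robust"` (default)}{`tProbe`/`tRegion` are quantile levels of
#'     the null score distribution, reached through a half-normal
#'     calibration of the batch: the null scale is estimated as
#'     `median(h) / qnorm(0.75)`, which ignores the upper tail and so stays
#'     honest when artifacts occupy a sizable fraction of the batch.}
#'   \item{`"empirical"`}{levels are taken as empirical batch quantiles of
#'     `h`.  Adequate for small contamination only: a large artifact
#'     inflates the upper quantiles and masks itself.}
#'   \item{`"absolute"`}{`tProbe`/`tRegion` are used directly as `h`
#'     cutoffs.}
#' }
#' All comparisons are strict, so a constant score field yields an empty
#' mask.  Windows are clipped at chip borders and the neighborhood
#' fraction uses the actual window population, so border probes are not
#' penalized.
#'
#' @param scores a [ScoreMap-class].
#' @param window odd window edge length in probes (default 15).
#' @param tProbe,tRegion thresholds, see `thresholdMode`.  Defaults: 0.995
#'   and 0.95 quantile levels.
#' @param fMin minimum fraction of window probes exceeding `tRegion`
#'   (default 0.5).
#' @param thresholdMode `"robust"`, `"empirical"` or `"absolute"`.
#' @return An [ArtifactMask-class].
#' @export
segmentArtifacts <- function(scores, window = 15L, tProbe = 0.995,
                             tRegion = 0.95, fMin = 0.5,
                             thresholdMode = c("robust", "empirical", "absolute")) {
    thresholdMode <- match.arg(thresholdMode)
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
        stop("window must be an odd integer >= 3", call. = FALSE)
    if (window > scores@nCols || window > scores@nRows)
        stop(sprintf("window %d exceeds the %dx%d chip", window,
                     scores@nCols, scores@nRows), call. = FALSE)
    if (fMin <= 0 || fMin > 1)
        stop("fMin must be in (0, 1]", call. = FALSE)
    th <- .resolveThresholds(scores@h, tProbe, tRegion, thresholdMode)
    half <- (window - 1L) %/% 2L
    flags <- matrix(FALSE, nrow(scores@h), ncol(scores@h),
                    dimnames = dimnames(scores@h))
    cell <- cbind(scores@y + 1L, scores@x + 1L)
    for (j in seq_len(ncol(scores@h))) {
        g <- .toGrid(scores@h[, j], scores@x, scores@y, scores@nCols, scores@nRows)
        defined <- is.finite(g)
        high <- defined & !is.na(g) & g > th["tRegion"]
        nDef <- .boxSum(defined + 0, half)
        nHigh <- .boxSum(high + 0, half)
        frac <- ifelse(nDef > 0, nHigh / nDef, 0)
        flagGrid <- defined & g > th["tProbe"] & frac >= fMin
        flags[, j] <- flagGrid[cell]
    }
    ArtifactMask(flags)
}

#' Batch quality-control report
#'
#' Summarizes per-chip artifact coverage and raises the two usage
#' warnings: chips with more than 50\% of probes flagged lean too heavily
#' on imputation and are better removed from the batch, and batches of
#' fewer than 6 chips give the variance score little resolving power.
#'
#' @param mask an [ArtifactMask-class].
#' @param chipset the scored [ChipSet-class].
#' @return list with `perChip` (`data.frame`: chip, nFlagged, coverage),
#'   `warnings` (character), and `summary` (named list).
#' @export
qcReport <- function(mask, chipset) {
    cov <- coverageFraction(mask)
    perChip <- data.frame(chip = names(cov),
                          nFlagged = colSums(mask@flags),
                          coverage = unname(cov),
                          row.names = NULL)
    warnings <- character()
    over <- perChip[perChip$coverage > 0.5, ]
    for (i in seq_len(nrow(over)))
        warnings <- c(warnings, sprintf(
            "chip '%s' has excessive artifact coverage (%.1f%% > 50%%); consider removing it from the batch rather than relying on imputation",
            over$chip[i], 100 * over$coverage[i]))
    if (ncol(chipset) < 6L)
        warnings <- c(warnings, sprintf(
            "batch has only %d chips (less than 6); inspect score and mask images before trusting automated artifact calls",
            ncol(chipset)))
    list(perChip = perChip,
         warnings = warnings,
         summary = list(nChips = ncol(chipset),
                        nProbes = nrow(chipset),
                        meanCoverage = mean(perChip$coverage),
                        maxCoverage = max(perChip$coverage),
                        nWarnings = length(warnings)))
}

#' Serialize a QC report
#' @param report output of [qcReport()].
#' @param textPath,yamlPath optional output paths for the human-readable
#'   and machine-readable forms.
#' @return the text lines, invisibly.
#' @export
writeQcReport <- function(report, textPath = NULL, yamlPath = NULL) {
    lines <- c("Artifact QC report",
               sprintf("chips: %d  probes per chip: %d",
                       report$summary$nChips, report$summary$nProbes),
               sprintf("mean coverage: %.4f  max coverage: %.4f",
                       report$summary$meanCoverage, report$summary$maxCoverage),
               "",
               sprintf("%-20s %10s %10s", "chip", "flagged", "coverage"),
               sprintf("%-20s %10d %10.4f", report$perChip$chip,
                       report$perChip$nFlagged, report$perChip$coverage))
    if (length(report$warnings))
        lines <- c(lines, "", "WARNINGS:", paste0("  - ", report$warnings))
    else
        lines <- c(lines, "", "no warnings")
    if (!is.null(textPath)) writeLines(lines, textPath)
    if (!is.null(yamlPath))
        yaml::write_yaml(list(summary = report$summary,
                              per_chip = report$perChip,
                              warnings = as.list(report$warnings)), yamlPath)
    invisible(lines)
}

#' Export an artifact mask as a tidy table
#' @param mask an [ArtifactMask-class].
#' @param scores a [ScoreMap-class] supplying grid coordinates (or any
#'   object with `x`/`y` per row); alternatively `NULL` to derive from
#'   `"x:y"` rownames.
#' @param path optional TSV output path; only flagged probes are listed.
#' @return `data.frame` with columns chip, x, y.
#' @export
maskTable <- function(mask, scores = NULL, path = NULL) {
    if (!is.null(scores)) {
        x <- scores@x; y <- scores@y
    } else {
        xy <- do.call(rbind, strsplit(rownames(mask@flags), ":", fixed = TRUE))
        x <- as.integer(xy[, 1L]); y <- as.integer(xy[, 2L])
    }
    chips <- colnames(mask@flags)
    d <- do.call(rbind, lapply(seq_along(chips), function(j) {
        i <- which(mask@flags[, j])
        if (!length(i)) return(NULL)
        data.frame(chip = chips[j], x = x[i], y = y[i])
    }))
    if (is.null(d)) d <- data.frame(chip = character(), x = integer(), y = integer())
    if (!is.null(path)) {
        write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(d))
    }
    d
}
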