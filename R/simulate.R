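# Synthetic chip batches and parameterized spatial insults.
#
# The generator draws from the same multiplicative model the pipeline
# fits: probe intensity = expression x affinity + additive noise.  It
# emulates a replicate-like batch from one platform -- the setting the
# method is designed for -- not scanner physics or probe-sequence effects.

#' Simulation settings for a synthetic batch
#'
#' @param nChips number of chips (default 10).
#' @param nCols,nRows grid dimensions (default 64 x 64).
#' @param nProbeSets,probesPerSet probe sets and probes per set (default
#'   500 x 8); their product may not exceed the grid, leftover cells
#'   become background probes.
#' @param affinitySd lognormal sigma of probe affinities; each set's
#'   affinities are recentred so their geometric mean is exactly 1.
#' @param exprSetSd lognormal sigma of baseline expression across probe
#'   sets (spread of gene abundances; default 1).
#' @param exprChipSd lognormal sigma of chip-to-chip expression variation
#'   per probe set (default 0.15, a replicate-like cohort of similar
#'   samples).
#' @param chipScaleSd lognormal sigma of the global per-chip brightness
#'   factor removed by normalization (default 0.1).
#' @param noiseSd additive Gaussian noise on the linear scale, relative:
#'   the noise standard deviation is `noiseSd` times the model value
#'   (default 0.05).
#' @param baseExpr median expression level on the intensity scale
#'   (default 200).
#' @param bgMeanLog,bgSdLog log-mean/-sigma of background cell
#'   intensities (default `log(50)`, 0.3); background cells are constant
#'   across chips up to chip scale and noise.
#' @param layoutMode `"random"` scatters each set's probes over the grid
#'   (modern chip designs); `"blocks"` packs each set into a contiguous
#'   block (older designs, convenient for residual-image inspection).
#' @param seed integer seed; every draw is reproducible given it.
#' @return list of settings for [simulateBatch()].
#' @export
simConfig <- function(nChips = 10L, nCols = 64L, nRows = 64L,
                      nProbeSets = 500L, probesPerSet = 8L,
                      affinitySd = 0.5, exprSetSd = 1, exprChipSd = 0.15,
                      chipScaleSd = 0.1, noiseSd = 0.05, baseExpr = 200,
                      bgMeanLog = log(50), bgSdLog = 0.3,
                      layoutMode = c("random", "blocks"), seed = 1L) {
    layoutMode <- match.arg(layoutMode)
    cfg <- list(nChips = as.integer(nChips), nCols = as.integer(nCols),
                nRows = as.integer(nRows), nProbeSets = as.integer(nProbeSets),
                probesPerSet = as.integer(probesPerSet),
                affinitySd = affinitySd, exprSetSd = exprSetSd,
                exprChipSd = exprChipSd, chipScaleSd = chipScaleSd,
                noiseSd = noiseSd, baseExpr = baseExpr,
                bgMeanLog = bgMeanLog, bgSdLog = bgSdLog,
                layoutMode = layoutMode, seed = as.integer(seed))
    if (cfg$nProbeSets * cfg$probesPerSet > cfg$nCols * cfg$nRows)
        stop("probe sets do not fit on the grid", call. = FALSE)
    if (any(c(affinitySd, exprSetSd, exprChipSd, chipScaleSd, noiseSd) < 0))
        stop("all sigmas must be >= 0", call. = FALSE)
    cfg
}

#' Simulate a clean synthetic chip batch
#'
#' Draws expression `theta[p, j] = baseExpr * set effect * chip scale *
#' chip-level variation` (all lognormal), probe affinities lognormal with
#' geometric mean forced to exactly one per set, and intensities
#' `X = theta * a + eps` with `eps` zero-mean Gaussian of standard
#' deviation `noiseSd * theta * a`, clamped away from zero.  The recorded
#' ground truth `theta` is the realized expression signal on each chip
#' (chip scale included), so a rank-1 fit at zero noise recovers it
#' exactly.
#'
#' @param config a [simConfig()] list.
#' @return list with `chipset` (raw [ChipSet-class]), `theta`
#'   (probe set x chip truth matrix, linear scale), `affinity` (named
#'   list of per-set affinity vectors), `layout`.
#' @export
simulateBatch <- function(config = simConfig()) {
    cfg <- config
    set.seed(cfg$seed)
    nCells <- cfg$nCols * cfg$nRows
    P <- cfg$nProbeSets; B <- cfg$probesPerSet; N <- cfg$nChips
    psIds <- sprintf("ps%04d", seq_len(P))
    cells <- seq_len(nCells)
    if (cfg$layoutMode == "random") {
        assigned <- sample(cells, P * B)
    } else {
        assigned <- seq_len(P * B)          # contiguous row-major blocks
    }
    cellX <- (cells - 1L) %% cfg$nCols
    cellY <- (cells - 1L) %/% cfg$nCols
    probes <- data.frame(
        x = cellX[assigned], y = cellY[assigned],
        probeSet = rep(psIds, each = B),
        isMismatch = rep(c(FALSE, TRUE), length.out = B)[rep(seq_len(B), P)])
    layout <- ProbeLayout(cfg$nCols, cfg$nRows, probes)

    setEffect <- rnorm(P, 0, cfg$exprSetSd)
    chipScale <- rnorm(N, 0, cfg$chipScaleSd)
    chipVar <- matrix(rnorm(P * N, 0, cfg$exprChipSd), P, N)
    theta <- exp(log(cfg$baseExpr) + setEffect + chipVar +
                 matrix(chipScale, P, N, byrow = TRUE))
    affinity <- lapply(seq_len(P), function(p) {
        lg <- rnorm(B, 0, cfg$affinitySd)
        exp(lg - mean(lg))                  # geometric mean exactly 1
    })
    names(affinity) <- psIds

    chipIdv <- sprintf("chip%02d", seq_len(N))
    m <- matrix(NA_real_, nCells, N,
                dimnames = list(.gridKeys(cfg$nCols, cfg$nRows), chipIdv))
    keys <- rownames(m)
    probeKey <- paste(probes$x, probes$y, sep = ":")
    rowIdx <- match(probeKey, keys)
    signal <- matrix(NA_real_, nCells, N)
    for (p in seq_len(P)) {
        sel <- ((p - 1L) * B + 1L):(p * B)
        rows <- rowIdx[sel]
        names(affinity[[p]]) <- probeKey[sel]     # keyed by grid cell
        signal[rows, ] <- outer(affinity[[p]], theta[p, ])
    }
    bg <- which(is.na(signal[, 1L]))
    if (length(bg)) {
        bgBase <- exp(rnorm(length(bg), cfg$bgMeanLog, cfg$bgSdLog))
        signal[bg, ] <- outer(bgBase, exp(chipScale))
    }
    noise <- matrix(rnorm(nCells * N, 0, 1), nCells, N) * cfg$noiseSd * signal
    m[] <- pmax(signal + noise, 1e-6)
    rownames(theta) <- psIds
    colnames(theta) <- chipIdv
    list(chipset = ChipSet(m, layout, chipIds = chipIdv, scaleState = "raw"),
         theta = theta, affinity = affinity, layout = layout)
}

.chipCol <- function(chipset, chip) {
    j <- if (is.character(chip)) match(chip, colnames(chipset)) else as.integer(chip)
    if (is.na(j) || j < 1L || j > ncol(chipset))
        stop(sprintf("unknown chip '%s'", chip), call. = FALSE)
    j
}

.footprintMask <- function(chipset, rows, chip) {
    f <- matrix(FALSE, nrow(chipset), ncol(chipset),
                dimnames = dimnames(intensities(chipset)))
    f[rows, .chipCol(chipset, chip)] <- TRUE
    ArtifactMask(f)
}

.applyFactor <- function(chipset, rows, chip, factor) {
    m <- intensities(chipset)
    j <- .chipCol(chipset, chip)
    m[rows, j] <- m[rows, j] * factor
    ChipSet(m, chipLayout(chipset), chipIds = colnames(m),
            scaleState = scaleState(chipset))
}

#' Inject a circular multiplicative insult
#'
#' Probes whose center lies within Euclidean distance `diameter / 2` of
#' `center` are multiplied by `factor`.  The center is constrained so
#' that no more than half the radius extends off the chip.
#'
#' @param chipset a [ChipSet-class].
#' @param chip target chip identifier or index.
#' @param center numeric `(x, y)` in grid coordinates.
#' @param diameter disk diameter in probes.
#' @param factor multiplicative factor (`< 1` "black hole", `> 1`
#'   "hot spot"; `1` leaves intensities untouched).
#' @return list with `chipset` (altered copy) and `footprint`
#'   ([ArtifactMask-class] of the exact altered probes).
#' @export
injectDisk <- function(chipset, chip, center, diameter, factor) {
    r <- diameter / 2
    lay <- chipLayout(chipset)
    lim <- c(lay@nCols, lay@nRows) - 1
    if (any(center < r / 2) || any(center > lim - r / 2))
        stop(sprintf("disk center (%g, %g) leaves more than half the radius off the %dx%d chip",
                     center[1L], center[2L], lay@nCols, lay@nRows), call. = FALSE)
    rd <- SummarizedExperiment::rowData(chipset)
    inside <- (rd$x - center[1L])^2 + (rd$y - center[2L])^2 <= r^2
    rows <- which(inside)
    list(chipset = .applyFactor(chipset, rows, chip, factor),
         footprint = .footprintMask(chipset, rows, chip))
}

#' Inject an elliptical multiplicative insult
#'
#' Rotated-ellipse membership is tested against probe centers: a probe at
#' `(x, y)` is inside when, after translating to `center` and rotating by
#' `-angle`, `(dx/axes[1])^2 + (dy/axes[2])^2 <= 1`.
#'
#' @inheritParams injectDisk
#' @param axes numeric `(a, b)` semi-axes in probes.
#' @param angle orientation in radians.
#' @return as [injectDisk()].
#' @export
injectEllipse <- function(chipset, chip, center, axes, angle = 0, factor) {
    lay <- chipLayout(chipset)
    r <- max(axes)
    lim <- c(lay@nCols, lay@nRows) - 1
    if (any(center < r / 2) || any(center > lim - r / 2))
        stop("ellipse center leaves more than half the major radius off the chip",
             call. = FALSE)
    rd <- SummarizedExperiment::rowData(chipset)
    dx <- rd$x - center[1L]; dy <- rd$y - center[2L]
    u <- dx * cos(angle) + dy * sin(angle)
    v <- -dx * sin(angle) + dy * cos(angle)
    rows <- which((u / axes[1L])^2 + (v / axes[2L])^2 <= 1)
    list(chipset = .applyFactor(chipset, rows, chip, factor),
         footprint = .footprintMask(chipset, rows, chip))
}

#' Inject the chip-thirds insult
#'
#' Multiplies the first third of the chip (by rows, or columns) by
#' `fLow` and the last third by `fHigh`, leaving the middle untouched:
#' the protocol that makes an altered chip's intensity distribution
#' trimodal and exercises normalization warping.
#'
#' @inheritParams injectDisk
#' @param fLow,fHigh multiplicative factors for the first and last third
#'   (defaults 0.5 and 10).
#' @param by partition the grid by `"rows"` (default) or `"cols"`.
#' @return list with `chipset` and `footprints`, a list of two
#'   [ArtifactMask-class] objects (`low`, `high`).
#' @export
injectThirds <- function(chipset, chip, fLow = 0.5, fHigh = 10,
                         by = c("rows", "cols")) {
    by <- match.arg(by)
    lay <- chipLayout(chipset)
    rd <- SummarizedExperiment::rowData(chipset)
    n <- if (by == "rows") lay@nRows else lay@nCols
    coord <- if (by == "rows") rd$y else rd$x
    third <- n %/% 3L
    lowRows <- which(coord < third)
    highRows <- which(coord >= n - third)
    out <- .applyFactor(chipset, lowRows, chip, fLow)
    out <- .applyFactor(out, highRows, chip, fHigh)
    list(chipset = out,
         footprints = list(low = .footprintMask(chipset, lowRows, chip),
                           high = .footprintMask(chipset, highRows, chip)))
}

#' Apply a parametric artifact specification
#'
#' Dispatch wrapper over [injectDisk()], [injectEllipse()] and
#' [injectThirds()] driven by an [ArtifactSpec-class].
#'
#' @param chipset a [ChipSet-class].
#' @param spec an [ArtifactSpec-class].
#' @return as the underlying injector.
#' @export
injectArtifact <- function(chipset, spec) {
    switch(spec@shape,
        disk = injectDisk(chipset, spec@chip, spec@center, spec@diameter,
                          spec@factor),
        ellipse = injectEllipse(chipset, spec@chip, spec@center, spec@axes,
                                spec@angle, spec@factor),
        thirds = injectThirds(chipset, spec@chip))
}

#' Construct an ArtifactSpec
#' @param shape `"disk"`, `"ellipse"` or `"thirds"`.
#' @param chip target chip id.
#' @param center,diameter,axes,angle,factor geometry, see
#'   [ArtifactSpec-class].
#' @export
artifactSpec <- function(shape, chip, center = c(NA_real_, NA_real_),
                         diameter = NA_real_, axes = c(NA_real_, NA_real_),
                         angle = 0, factor = 1) {
    new("ArtifactSpec", shape = shape, chip = as.character(chip),
        center = as.numeric(center), diameter = as.numeric(diameter),
        axes = as.numeric(axes), angle = as.numeric(angle),
        factor = as.numeric(factor))
}
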