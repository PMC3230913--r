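#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx median quantile sd qnorm rnorm runif setNames ave aggregate
#' @importFrom graphics plot lines arrows legend
#' @importFrom utils read.delim write.table
NULL

.SCALE_STATES <- c("raw", "log2", "normalized")

#' Probe grid layout
#'
#' Maps every assayed probe of a chip design to its 0-based grid coordinate
#' and (optionally) a probe set.  Grid cells absent from `probes` are
#' background/control cells: they are scored and normalized like any other
#' cell but never enter the expression model.
#'
#' @slot nCols,nRows integer grid dimensions (columns indexed by `x`,
#'   rows by `y`, both 0-based).
#' @slot probes `data.frame` with columns `x`, `y`, `probeSet`,
#'   `isMismatch`.  One row per assigned probe; `(x, y)` pairs are unique.
#'
#' @aliases ProbeLayout
#' @exportClass ProbeLayout
setClass("ProbeLayout",
    representation(nCols = "integer", nRows = "integer", probes = "data.frame"))

setValidity("ProbeLayout", function(object) {
    p <- object@probes
    msg <- character()
    if (length(object@nCols) != 1L || length(object@nRows) != 1L ||
        is.na(object@nCols) || is.na(object@nRows) ||
        object@nCols < 1L || object@nRows < 1L)
        msg <- c(msg, "nCols and nRows must be positive scalars")
    need <- c("x", "y", "probeSet", "isMismatch")
    if (!all(need %in% names(p)))
        return(paste("probes must have columns", paste(need, collapse = ", ")))
    if (nrow(p)) {
        bad <- p$x < 0L | p$x >= object@nCols | p$y < 0L | p$y >= object@nRows
        if (any(bad))
            msg <- c(msg, sprintf("out-of-bounds probe coordinates: %s",
                paste(sprintf("(%d,%d)", p$x[bad], p$y[bad])[seq_len(min(5L, sum(bad)))],
                      collapse = " ")))
        key <- paste(p$x, p$y, sep = ":")
        if (anyDuplicated(key))
            msg <- c(msg, sprintf("duplicate probe coordinates: %s",
                paste(unique(key[duplicated(key)])[seq_len(min(5L, sum(duplicated(key))))],
                      collapse = " ")))
        if (anyNA(p$probeSet))
            msg <- c(msg, "probeSet must not contain NA (omit background cells instead)")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a ProbeLayout
#'
#' @param nCols,nRows grid dimensions.
#' @param probes `data.frame` with columns `x`, `y`, `probeSet` and
#'   optionally `isMismatch` (defaults to `FALSE`).
#' @return A [ProbeLayout-class] object.
#' @export
ProbeLayout <- function(nCols, nRows, probes) {
    probes <- as.data.frame(probes)
    if (is.null(probes$isMismatch))
        probes$isMismatch <- FALSE
    probes$x <- as.integer(probes$x)
    probes$y <- as.integer(probes$y)
    probes$probeSet <- as.character(probes$probeSet)
    probes$isMismatch <- as.logical(probes$isMismatch)
    new("ProbeLayout", nCols = as.integer(nCols), nRows = as.integer(nRows),
        probes = probes[c("x", "y", "probeSet", "isMismatch")])
}

# canonical row-major ordering of grid cells: y outer, x inner
.gridKeys <- function(nCols, nRows) {
    g <- expand.grid(x = seq_len(nCols) - 1L, y = seq_len(nRows) - 1L)
    paste(g$x, g$y, sep = ":")
}

.layoutRowData <- function(layout) {
    nc <- layout@nCols; nr <- layout@nRows
    g <- expand.grid(x = seq_len(nc) - 1L, y = seq_len(nr) - 1L)
    key <- paste(g$x, g$y, sep = ":")
    ps <- rep(NA_character_, nrow(g))
    mm <- rep(NA, nrow(g))
    p <- layout@probes
    if (nrow(p)) {
        idx <- match(paste(p$x, p$y, sep = ":"), key)
        ps[idx] <- p$probeSet
        mm[idx] <- p$isMismatch
    }
    S4Vectors::DataFrame(x = as.integer(g$x), y = as.integer(g$y),
                         probeSet = ps, isMismatch = mm, row.names = key)
}

#' Batch of chips on a shared probe grid
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose rows are the
#' grid cells of one chip design (row-major order, rownames `"x:y"`) and
#' whose columns are chips.  The single assay `"intensities"` holds strictly
#' positive fluorescence values; `scaleState` records whether they are raw,
#' log2, or quantile-normalized.
#'
#' @aliases ChipSet
#' @exportClass ChipSet
setClass("ChipSet",
    contains = "SummarizedExperiment",
    representation(chipLayout = "ProbeLayout", scaleState = "character"))

setValidity("ChipSet", function(object) {
    msg <- character()
    if (!(object@scaleState %in% .SCALE_STATES))
        msg <- c(msg, sprintf("scaleState must be one of %s",
                              paste(.SCALE_STATES, collapse = ", ")))
    if (!"intensities" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensities' is required")
    else {
        m <- SummarizedExperiment::assay(object, "intensities")
        if (anyNA(m) || any(!is.finite(m)))
            msg <- c(msg, "intensities must be finite")
        else if (object@scaleState != "log2" && any(m <= 0))
            msg <- c(msg, "intensities must be strictly positive on the linear scale")
    }
    expected <- object@chipLayout@nCols * object@chipLayout@nRows
    if (nrow(object) != expected)
        msg <- c(msg, sprintf("expected %d grid cells, got %d rows", expected, nrow(object)))
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a ChipSet
#'
#' @param intensities numeric matrix, grid cells x chips.  Rows either in
#'   canonical row-major grid order or named with `"x:y"` keys (any order).
#'   Values `<= 0` are clamped to the smallest positive value on that chip,
#'   with a warning: the multiplicative model and the log domain require
#'   positivity.
#' @param layout a [ProbeLayout-class].
#' @param chipIds chip identifiers; default column names of `intensities`.
#' @param scaleState one of `"raw"`, `"log2"`, `"normalized"`.
#' @return A [ChipSet-class].
#' @export
ChipSet <- function(intensities, layout, chipIds = NULL, scaleState = "raw") {
    intensities <- as.matrix(intensities)
    keys <- .gridKeys(layout@nCols, layout@nRows)
    if (nrow(intensities) != length(keys))
        stop(sprintf("intensity matrix has %d rows but layout grid has %d cells",
                     nrow(intensities), length(keys)))
    if (!is.null(rownames(intensities))) {
        idx <- match(keys, rownames(intensities))
        if (anyNA(idx))
            stop("intensity row names do not cover the layout grid (missing e.g. ",
                 keys[which(is.na(idx))[1L]], ")")
        intensities <- intensities[idx, , drop = FALSE]
    }
    rownames(intensities) <- keys
    if (is.null(chipIds)) chipIds <- colnames(intensities)
    if (is.null(chipIds)) chipIds <- paste0("chip", seq_len(ncol(intensities)))
    colnames(intensities) <- chipIds
    if (scaleState != "log2" && any(intensities <= 0)) {
        for (j in seq_len(ncol(intensities))) {
            bad <- intensities[, j] <= 0
            if (any(bad)) {
                floorv <- min(intensities[!bad, j])
                warning(sprintf("chip '%s': clamped %d nonpositive intensities to %g",
                                chipIds[j], sum(bad), floorv))
                intensities[bad, j] <- floorv
            }
        }
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensities = intensities),
        rowData = .layoutRowData(layout),
        colData = S4Vectors::DataFrame(chip = chipIds, row.names = chipIds))
    new("ChipSet", se, chipLayout = layout, scaleState = scaleState)
}

#' Per-chip artifact flags
#'
#' Boolean grid-cell x chip matrix aligned with a [ChipSet-class]:
#' `TRUE` marks a probe flagged as part of a spatial artifact.
#'
#' @slot flags logical matrix, same dim/dimnames as the chip set assay.
#' @aliases ArtifactMask
#' @exportClass ArtifactMask
setClass("ArtifactMask", representation(flags = "matrix"))

setValidity("ArtifactMask", function(object) {
    if (!is.logical(object@flags)) return("flags must be a logical matrix")
    if (anyNA(object@flags)) return("flags must not contain NA")
    TRUE
})

#' @rdname ArtifactMask-class
#' @param flags logical matrix (grid cells x chips).
#' @export
ArtifactMask <- function(flags) new("ArtifactMask", flags = flags)

#' All-clear mask matching a chip set
#' @param chipset a [ChipSet-class].
#' @return An [ArtifactMask-class] with no probe flagged.
#' @export
emptyMask <- function(chipset) {
    m <- SummarizedExperiment::assay(chipset, "intensities")
    f <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
    ArtifactMask(f)
}

#' Per-probe, per-chip variance scores
#'
#' Holds the signed leave-one-out statistic `z`, the nonnegative variance
#' score `h`, and `nEff`, the number of reference chips each score was
#' computed against.  Cells with fewer than two reference chips carry `NA`.
#'
#' @slot z,h numeric matrices (grid cells x chips).
#' @slot nEff integer matrix of reference-set sizes.
#' @slot x,y integer grid coordinates per row.
#' @slot nCols,nRows integer grid dimensions.
#' @aliases ScoreMap
#' @exportClass ScoreMap
setClass("ScoreMap",
    representation(z = "matrix", h = "matrix", nEff = "matrix",
                   x = "integer", y = "integer",
                   nCols = "integer", nRows = "integer"))

setValidity("ScoreMap", function(object) {
    if (any(object@h < 0, na.rm = TRUE)) return("h must be nonnegative")
    if (!identical(dim(object@z), dim(object@h))) return("z and h dims differ")
    TRUE
})

#' Rank-1 multiplicative model fit for one probe set
#'
#' Intensities of one probe set are modeled as expression times probe
#' affinity: `X[j, b] = theta[j] * a[b] + eps[j, b]`, with the geometric
#' mean of the affinities constrained to one so that `theta` is on the
#' intensity scale.
#'
#' @slot probeSet probe set identifier.
#' @slot theta length-N expression vector (linear scale, one per chip).
#' @slot affinity length-B probe affinity vector, geometric mean 1.
#' @slot residuals N x B matrix of data minus model,
#'   `completed - theta %*% t(affinity)`: for a plain fit this is the
#'   residual of the observed data; after imputation, masked cells carry
#'   their model value and so have zero residual.
#' @slot completed N x B data matrix after EM imputation of masked cells.
#' @slot mask N x B logical artifact indicator used in the fit.
#' @slot converged logical; `FALSE` if EM stopped at `maxIter`.
#' @slot nIter EM iterations used (1 for a plain fit).
#' @aliases ProbeSetModel
#' @exportClass ProbeSetModel
setClass("ProbeSetModel",
    representation(probeSet = "character", theta = "numeric",
                   affinity = "numeric", residuals = "matrix",
                   completed = "matrix", mask = "matrix",
                   converged = "logical", nIter = "integer"))

#' Common quantile grid of a batch
#'
#' Reference distribution for quantile normalization: values of the mean
#' unmasked quantile function of the batch at levels `(k - 0.5) / K`,
#' `K` = grid cells per chip.
#'
#' @slot values nondecreasing numeric vector of length K.
#' @slot levels the quantile levels.
#' @aliases QuantileReference
#' @exportClass QuantileReference
setClass("QuantileReference",
    representation(values = "numeric", levels = "numeric"))

setValidity("QuantileReference", function(object) {
    if (length(object@values) != length(object@levels))
        return("values and levels lengths differ")
    if (is.unsorted(object@values, na.rm = TRUE))
        return("reference values must be nondecreasing")
    TRUE
})

#' Parametric description of a synthetic spatial insult
#'
#' @slot shape `"disk"`, `"ellipse"` or `"thirds"`.
#' @slot chip target chip identifier.
#' @slot center `(x, y)` center in grid coordinates (disk/ellipse).
#' @slot diameter disk diameter in probes.
#' @slot axes semi-axes of an ellipse, in probes.
#' @slot angle ellipse orientation, radians.
#' @slot factor multiplicative intensity factor (> 0); `< 1` is a
#'   "black hole", `> 1` a "hot spot".
#' @aliases ArtifactSpec
#' @exportClass ArtifactSpec
setClass("ArtifactSpec",
    representation(shape = "character", chip = "character",
                   center = "numeric", diameter = "numeric",
                   axes = "numeric", angle = "numeric", factor = "numeric"))

setValidity("ArtifactSpec", function(object) {
    if (!(object@shape %in% c("disk", "ellipse", "thirds")))
        return("shape must be disk, ellipse or thirds")
    if (length(object@factor) != 1L || object@factor <= 0)
        return("factor must be a positive scalar")
    if (object@shape == "disk" &&
        !(length(object@diameter) == 1L && isTRUE(object@diameter > 0)))
        return("disk requires a positive diameter")
    if (object@shape == "ellipse" &&
        !(length(object@axes) == 2L && all(!is.na(object@axes)) && all(object@axes > 0)))
        return("ellipse requires two positive semi-axes")
    TRUE
})
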