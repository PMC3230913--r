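#' @name arrayClean-accessors
#' @title Accessors for arrayClean classes
#' @param x an arrayClean object.
#' @param object an arrayClean object.
#' @param chip a chip identifier or column index.
#' @description Slot access for [ChipSet-class], [ArtifactMask-class],
#'   [ScoreMap-class] and [ProbeSetModel-class] objects.
NULL

#' @rdname arrayClean-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname arrayClean-accessors
#' @export
setGeneric("chipIds", function(x) standardGeneric("chipIds"))

#' @rdname arrayClean-accessors
#' @export
setGeneric("scaleState", function(x) standardGeneric("scaleState"))

#' @rdname arrayClean-accessors
#' @export
setGeneric("chipLayout", function(x) standardGeneric("chipLayout"))

#' @rdname arrayClean-accessors
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname arrayClean-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname arrayClean-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Fraction of a chip's probes flagged as artifact
#'
#' @param mask an [ArtifactMask-class].
#' @param chip chip identifier or index; if missing, all chips.
#' @return numeric in `[0, 1]`, named by chip.
#' @export
setGeneric("coverageFraction", function(mask, chip) standardGeneric("coverageFraction"))

setMethod("intensities", "ChipSet", function(x)
    SummarizedExperiment::assay(x, "intensities"))

setMethod("chipIds", "ChipSet", function(x) colnames(x))

setMethod("scaleState", "ChipSet", function(x) x@scaleState)

setMethod("chipLayout", "ChipSet", function(x) x@chipLayout)

setMethod("gridSize", "ProbeLayout", function(x)
    c(nCols = x@nCols, nRows = x@nRows))

setMethod("gridSize", "ChipSet", function(x) gridSize(x@chipLayout))

setMethod("maskMatrix", "ArtifactMask", function(x) x@flags)

setMethod("scoreMatrix", "ScoreMap", function(x) x@h)

setMethod("coverageFraction", signature("ArtifactMask", "ANY"),
    function(mask, chip) {
        f <- mask@flags[, chip, drop = FALSE]
        setNames(colMeans(f), colnames(f))
    })

setMethod("coverageFraction", signature("ArtifactMask", "missing"),
    function(mask, chip) setNames(colMeans(mask@flags), colnames(mask@flags)))

setMethod("show", "ProbeLayout", function(object) {
    cat(sprintf("ProbeLayout: %d x %d grid (%d cells), %d assigned probes, %d probe sets\n",
        object@nCols, object@nRows, object@nCols * object@nRows,
        nrow(object@probes), length(unique(object@probes$probeSet))))
})

setMethod("show", "ChipSet", function(object) {
    cat(sprintf("ChipSet: %d chips on a %d x %d grid [%s scale]\n",
        ncol(object), object@chipLayout@nCols, object@chipLayout@nRows,
        object@scaleState))
    cat("chips:", paste(utils::head(colnames(object), 6L), collapse = ", "),
        if (ncol(object) > 6L) "..." else "", "\n")
})

setMethod("show", "ArtifactMask", function(object) {
    cov <- colMeans(object@flags)
    cat(sprintf("ArtifactMask: %d cells x %d chips; coverage %.2f%%-%.2f%% (mean %.2f%%)\n",
        nrow(object@flags), ncol(object@flags),
        100 * min(cov), 100 * max(cov), 100 * mean(cov)))
})

setMethod("show", "ScoreMap", function(object) {
    cat(sprintf("ScoreMap: %d cells x %d chips on a %d x %d grid; median h = %.3f\n",
        nrow(object@h), ncol(object@h), object@nCols, object@nRows,
        median(object@h, na.rm = TRUE)))
})

setMethod("show", "ProbeSetModel", function(object) {
    cat(sprintf("ProbeSetModel '%s': %d chips x %d probes; %d masked cells; %s in %d iter\n",
        object@probeSet, length(object@theta), length(object@affinity),
        sum(object@mask),
        if (object@converged) "converged" else "NOT converged", object@nIter))
})

setMethod("show", "QuantileReference", function(object) {
    cat(sprintf("QuantileReference: %d levels, range [%.4g, %.4g]\n",
        length(object@values), min(object@values), max(object@values)))
})

setMethod("show", "ArtifactSpec", function(object) {
    cat(sprintf("ArtifactSpec: %s on chip '%s', factor %.3g\n",
        object@shape, object@chip, object@factor))
})
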