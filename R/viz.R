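# Deterministic PNG rendering of score, residual and mask grids.
# One pixel per probe; no axes or antialiasing, so identical grids give
# identical files.

.writeRgb <- function(rgb, path) {
    png::writePNG(rgb, path)
    invisible(path)
}

#' Render a probe grid as a PNG heat map
#'
#' Three palettes, one per map kind:
#' \describe{
#'   \item{`"score"`}{monochrome, dark = high score (poor quality);
#'     optionally overlays `mask` in bright red.}
#'   \item{`"residual"`}{symmetric diverging blue-white-red with zero at
#'     white: red = higher than the model expects, blue = lower.}
#'   \item{`"mask"`}{red on white.}
#' }
#' `NA` cells render neutral gray.
#'
#' @param grid numeric `nRows x nCols` matrix (row 1 = grid row `y = 0`).
#' @param kind `"score"`, `"residual"` or `"mask"`.
#' @param path output PNG path.
#' @param mask optional logical matrix overlay (score maps).
#' @param zlim optional symmetric color limit for residual maps /
#'   upper limit for score maps.
#' @return `path`, invisibly.
#' @export
renderHeatmap <- function(grid, kind = c("score", "residual", "mask"), path,
                          mask = NULL, zlim = NULL) {
    kind <- match.arg(kind)
    nR <- nrow(grid); nC <- ncol(grid)
    rgb <- array(0.75, dim = c(nR, nC, 3L))      # neutral gray for NA
    ok <- is.finite(grid)
    if (kind == "score") {
        hi <- if (is.null(zlim)) max(grid[ok], 0) else zlim
        v <- if (hi > 0) pmin(grid[ok] / hi, 1) else grid[ok] * 0
        shade <- 1 - v                            # dark = high
        for (ch in 1:3) { p <- rgb[, , ch]; p[ok] <- shade; rgb[, , ch] <- p }
        if (!is.null(mask)) {
            m <- !is.na(mask) & mask
            p <- rgb[, , 1L]; p[m] <- 1; rgb[, , 1L] <- p
            p <- rgb[, , 2L]; p[m] <- 0; rgb[, , 2L] <- p
            p <- rgb[, , 3L]; p[m] <- 0; rgb[, , 3L] <- p
        }
    } else if (kind == "residual") {
        hi <- if (is.null(zlim)) max(abs(grid[ok]), .Machine$double.eps) else zlim
        v <- pmax(pmin(grid[ok] / hi, 1), -1)
        r <- ifelse(v >= 0, 1, 1 + v)             # fade red below zero
        g <- 1 - abs(v)
        b <- ifelse(v <= 0, 1, 1 - v)
        p <- rgb[, , 1L]; p[ok] <- r; rgb[, , 1L] <- p
        p <- rgb[, , 2L]; p[ok] <- g; rgb[, , 2L] <- p
        p <- rgb[, , 3L]; p[ok] <- b; rgb[, , 3L] <- p
    } else {
        m <- !is.na(grid) & grid > 0
        rgb[, , 1L] <- 1
        rgb[, , 2L] <- ifelse(m, 0, 1)
        rgb[, , 3L] <- ifelse(m, 0, 1)
    }
    .writeRgb(rgb, path)
}

#' Render an artifact mask for one chip
#' @param mask an [ArtifactMask-class].
#' @param scores a [ScoreMap-class] supplying the grid geometry.
#' @param chip chip identifier or index.
#' @param path output PNG path.
#' @export
maskHeatmap <- function(mask, scores, chip, path) {
    g <- .toGrid(as.numeric(mask@flags[, chip]), scores@x, scores@y,
                 scores@nCols, scores@nRows)
    renderHeatmap(g, kind = "mask", path = path)
}

#' Render the model-residual heat map of one chip
#' @param models list of [ProbeSetModel-class].
#' @param chipset the fitted [ChipSet-class].
#' @param chip chip identifier or index.
#' @param path output PNG path.
#' @param zlim optional symmetric color limit.
#' @export
residualHeatmap <- function(models, chipset, chip, path, zlim = NULL) {
    renderHeatmap(residualMap(models, chipset, chip), kind = "residual",
                  path = path, zlim = zlim)
}
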