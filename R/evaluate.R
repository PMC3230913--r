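# Quantifying artifact impact and correction quality.

#' Log-domain expression error between two expression tables
#'
#' Mean absolute difference between two natural-log expression tables --
#' the standard summary of how much an artifact (or a correction) moved
#' the expression estimates, comparable in spirit to average relative
#' error on the linear scale.  Tables are aligned by probe-set and chip
#' names when present.
#'
#' @param before,after probe set x chip matrices of ln expression.
#' @return list with `pooled` (grand mean |difference|), `perChip`
#'   (named numeric), `nProbeSets`, `nChips`.
#' @export
expressionError <- function(before, after) {
    if (!is.null(rownames(before)) && !is.null(rownames(after))) {
        if (!setequal(rownames(before), rownames(after)))
            stop("probe sets differ between tables", call. = FALSE)
        after <- after[rownames(before), , drop = FALSE]
    }
    if (!is.null(colnames(before)) && !is.null(colnames(after)) &&
        setequal(colnames(before), colnames(after)))
        after <- after[, colnames(before), drop = FALSE]
    if (!identical(dim(before), dim(after)))
        stop("expression tables have different shapes", call. = FALSE)
    d <- abs(after - before)
    list(pooled = mean(d, na.rm = TRUE),
         perChip = colMeans(d, na.rm = TRUE),
         nProbeSets = nrow(before),
         nChips = ncol(before))
}

#' ROC curve and AUC for fold-change detection
#'
#' Sweeps a threshold over `|score|` in descending order and accumulates
#' true/false positive counts; tied scores are resolved as a diagonal
#' segment, so the full AUC equals the Mann-Whitney concordance
#' statistic with ties counted 0.5.  With `maxFp` set, the curve is
#' truncated at that false-positive count (interpolating within a tie
#' group) and the AUC is normalized by `maxFp * #positives`, so capped
#' values remain comparable across runs.
#'
#' @param scores numeric statistic per gene (e.g. log fold change); the
#'   magnitude is the ranking criterion.
#' @param labels logical (or 0/1) truth per gene.
#' @param maxFp optional false-positive cap.
#' @return list with `fp`, `tp` (cumulative counts per threshold step)
#'   and `auc`.
#' @export
rocAuc <- function(scores, labels, maxFp = NULL) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels))
        stop("scores and labels lengths differ", call. = FALSE)
    nPos <- sum(labels); nNeg <- sum(!labels)
    if (nPos == 0L || nNeg == 0L)
        stop("need at least one positive and one negative label", call. = FALSE)
    s <- abs(scores)
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; lab <- labels[ord]
    grp <- cumsum(!duplicated(s))
    dTp <- tapply(as.integer(lab), grp, sum)
    dFp <- tapply(as.integer(!lab), grp, sum)
    tp <- cumsum(dTp); fp <- cumsum(dFp)
    tpPrev <- c(0, tp[-length(tp)]); fpPrev <- c(0, fp[-length(fp)])
    if (is.null(maxFp)) {
        area <- sum(dFp * (tpPrev + dTp / 2))
        return(list(fp = as.numeric(fp), tp = as.numeric(tp),
                    auc = area / (nPos * nNeg)))
    }
    area <- 0
    for (k in seq_along(dTp)) {
        if (fpPrev[k] >= maxFp) break
        if (fp[k] <= maxFp) {
            area <- area + dFp[k] * (tpPrev[k] + dTp[k] / 2)
        } else {
            t <- (maxFp - fpPrev[k]) / dFp[k]
            area <- area + dFp[k] * t * (tpPrev[k] + t * dTp[k] / 2)
        }
    }
    list(fp = as.numeric(pmin(fp, maxFp)), tp = as.numeric(tp),
         auc = unname(area) / (maxFp * nPos))
}

#' Artifact size/magnitude sweep experiment
#'
#' For every combination of disk diameter, multiplicative magnitude,
#' pipeline variant and replicate: simulate a clean batch, compute its
#' reference expression with the variant, inject a random-center disk on
#' one chip, rerun the variant, and record the pooled log-domain
#' expression error.  Replicates use distinct derived seeds.
#'
#' @param sizes disk diameters in probes.
#' @param magnitudes multiplicative factors.
#' @param replicates replicates per cell (default 3).
#' @param config base [simConfig()]; its seed anchors the sweep.
#' @param variants subset of `c("corrected", "uncorrected")`.
#' @param ... passed to [runPipeline()] (iterations, window, ...).
#' @return `data.frame` with columns size, magnitude, variant, replicate,
#'   seed, error.
#' @export
sweepExperiment <- function(sizes, magnitudes, replicates = 3L,
                            config = simConfig(),
                            variants = c("corrected", "uncorrected"), ...) {
    grid <- expand.grid(size = sizes, magnitude = magnitudes,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
    rows <- list()
    for (i in seq_len(nrow(grid))) {
        sz <- grid$size[i]; mag <- grid$magnitude[i]; rep <- grid$replicate[i]
        seed <- (config$seed + 7919L * i) %% .Machine$integer.max
        cfg <- config; cfg$seed <- seed
        sim <- simulateBatch(cfg)
        r <- sz / 2
        lim <- c(cfg$nCols, cfg$nRows) - 1
        set.seed(seed + 1L)
        center <- c(runif(1, r / 2, lim[1L] - r / 2),
                    runif(1, r / 2, lim[2L] - r / 2))
        insult <- injectDisk(sim$chipset, chip = 1L, center = center,
                             diameter = sz, factor = mag)
        for (v in variants) {
            corr <- v == "corrected"
            expr0 <- runPipeline(sim$chipset, correct = corr, ...)$expression
            expr1 <- runPipeline(insult$chipset, correct = corr, ...)$expression
            err <- expressionError(expr0, expr1)$pooled
            rows[[length(rows) + 1L]] <-
                data.frame(size = sz, magnitude = mag, variant = v,
                           replicate = rep, seed = seed, error = err)
        }
    }
    do.call(rbind, rows)
}

#' Plot a sweep result with error bars
#'
#' Mean pooled error against magnitude (or size), one line per variant,
#' error bars one standard deviation across replicates.
#'
#' @param results output of [sweepExperiment()].
#' @param by x axis: `"magnitude"` or `"size"`.
#' @param path optional PNG output path.
#' @export
plotSweep <- function(results, by = c("magnitude", "size"), path = NULL) {
    by <- match.arg(by)
    agg <- aggregate(error ~ results[[by]] + variant, data = results,
                     FUN = function(v) c(mean = mean(v), sd = sd(v)))
    names(agg)[1L] <- by
    x <- agg[[by]]; mu <- agg$error[, "mean"]; s <- agg$error[, "sd"]
    s[is.na(s)] <- 0
    if (!is.null(path)) grDevices::png(path, width = 640, height = 480)
    variants <- unique(agg$variant)
    cols <- setNames(seq_along(variants) + 1L, variants)
    plot(range(x), range(c(mu - s, mu + s)), type = "n",
         xlab = by, ylab = "mean |delta ln expression|",
         main = "artifact impact on expression")
    for (v in variants) {
        i <- agg$variant == v
        o <- order(x[i])
        lines(x[i][o], mu[i][o], type = "b", col = cols[v], pch = 19)
        arrows(x[i], mu[i] - s[i], x[i], mu[i] + s[i], angle = 90, code = 3,
               length = 0.04, col = cols[v])
    }
    legend("topleft", legend = variants, col = cols, lty = 1, pch = 19,
           bty = "n")
    if (!is.null(path)) grDevices::dev.off()
    invisible(agg)
}
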