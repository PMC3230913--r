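# Multiplicative rank-1 probe-set model and EM imputation.
#
# Within a probe set, the observed (normalized) intensity of probe b on
# chip j is modeled as expression times probe affinity plus additive
# error:  X[j, b] = theta[j] * a[b] + eps[j, b].  The Frobenius-optimal
# rank-1 fit is the leading singular triplet of X; constraining the
# geometric mean of the affinities to one puts theta on the intensity
# scale.  Perfect-match and mismatch probes enter identically (no PM-MM
# differencing).

.geomean <- function(v) exp(mean(log(v)))

#' Fit the rank-1 multiplicative model to one probe set
#'
#' Computes the SVD `X = U S V'` and takes `theta = s1 * U[, 1]`,
#' `a = V[, 1]`, the rank-1 pair minimizing the Frobenius norm of the
#' residual.  Signs are flipped so `sum(a) > 0`, then both vectors are
#' rescaled by the geometric mean of `a` (`a` divided, `theta`
#' multiplied) to enforce `geomean(a) = 1`.
#'
#' @param X numeric matrix, chips x probes, finite and positive.
#' @param probeSet identifier recorded in the result.
#' @return A [ProbeSetModel-class] with `nIter = 1`.
#' @export
fitRank1 <- function(X, probeSet = "probe_set") {
    X <- as.matrix(X)
    if (any(!is.finite(X)))
        stop("X must be finite", call. = FALSE)
    if (all(X == 0))
        stop(sprintf("probe set '%s': degenerate all-zero matrix", probeSet),
             call. = FALSE)
    sv <- svd(X, nu = 1L, nv = 1L)
    theta <- sv$d[1L] * sv$u[, 1L]
    a <- sv$v[, 1L]
    if (sum(a) < 0) { a <- -a; theta <- -theta }
    if (any(a <= 0)) {
        # pathological: leading right singular vector not strictly positive
        # (cannot happen for strictly positive X by Perron-Frobenius)
        warning(sprintf("probe set '%s': nonpositive affinity in leading singular vector",
                        probeSet))
        a[a <= 0] <- .Machine$double.eps
    }
    g <- .geomean(a)
    a <- a / g
    theta <- theta * g
    resid <- X - tcrossprod(theta, a)
    new("ProbeSetModel", probeSet = as.character(probeSet),
        theta = as.numeric(theta), affinity = as.numeric(a),
        residuals = resid, completed = X,
        mask = matrix(FALSE, nrow(X), ncol(X)),
        converged = TRUE, nIter = 1L)
}

#' Impute artifact cells of a probe set by rank-1 EM
#'
#' Alternates (1) fitting the rank-1 model to the current matrix and
#' (2) overwriting masked cells with the model prediction
#' `theta %*% t(a)`.  Step 2 zeroes the masked residuals and cannot
#' increase the Frobenius norm of the error; step 1 is its global
#' minimizer given the data, so the unmasked-cell residual norm is
#' non-increasing and bounded by zero, guaranteeing convergence (the
#' singular-value-decomposition imputation scheme of the missing-value
#' literature).  Masked cells are initialized at the per-probe mean of
#' unmasked values, falling back to the chip mean and then the global
#' mean.
#'
#' @param X numeric matrix, chips x probes.
#' @param mask logical matrix, same shape; `TRUE` = artifact.
#' @param probeSet identifier recorded in the result.
#' @param tol convergence tolerance on the relative change of the
#'   unmasked-cell residual norm (default 1e-8).
#' @param maxIter iteration cap (default 100); hitting it yields a
#'   warning and `converged = FALSE`.
#' @return A [ProbeSetModel-class]; `completed` holds the imputed matrix.
#' @export
imputeEM <- function(X, mask, probeSet = "probe_set", tol = 1e-8,
                     maxIter = 100L) {
    X <- as.matrix(X)
    mask <- as.matrix(mask)
    if (!identical(dim(X), dim(mask)))
        stop("X and mask dimensions differ", call. = FALSE)
    if (all(mask))
        stop(sprintf("probe set '%s': every cell masked", probeSet), call. = FALSE)
    if (tol <= 0) stop("tol must be positive", call. = FALSE)
    if (!any(mask)) {
        fit <- fitRank1(X, probeSet)
        fit@mask <- mask
        return(fit)
    }
    Xw <- X
    for (b in seq_len(ncol(X))) {
        bad <- mask[, b]
        if (any(bad)) {
            ok <- X[!bad, b]
            Xw[bad, b] <- if (length(ok)) mean(ok) else NA_real_
        }
    }
    if (anyNA(Xw)) {                       # probes masked on every chip
        for (j in seq_len(nrow(Xw))) {
            miss <- is.na(Xw[j, ])
            if (any(miss)) {
                ok <- X[j, !mask[j, ]]
                Xw[j, miss] <- if (length(ok)) mean(ok) else NA_real_
            }
        }
        if (anyNA(Xw)) Xw[is.na(Xw)] <- mean(X[!mask])
    }
    unmaskedNorm <- function(fit)
        sqrt(sum(fit@residuals[!mask]^2))
    scaleNorm <- sqrt(sum(X[!mask]^2))       # slack scale for the assertion
    errPrev <- Inf
    fit <- NULL
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        fit <- fitRank1(Xw, probeSet)
        err <- unmaskedNorm(fit)
        # EM monotonicity, up to floating-point noise at the matrix scale
        stopifnot(err <= errPrev * (1 + 1e-10) + 1e-10 * scaleNorm)
        Xw[mask] <- tcrossprod(fit@theta, fit@affinity)[mask]
        if (is.finite(errPrev) &&
            (errPrev - err) <= tol * max(errPrev, .Machine$double.eps)) {
            converged <- TRUE
            break
        }
        errPrev <- err
    }
    if (!converged)
        warning(sprintf("probe set '%s': EM did not converge in %d iterations",
                        probeSet, maxIter))
    fit@completed <- Xw
    fit@mask <- mask
    # residuals of the completed data: masked cells carry their model value,
    # so their residual is zero once imputation has replaced them
    fit@residuals <- Xw - tcrossprod(fit@theta, fit@affinity)
    fit@converged <- converged
    fit@nIter <- iter
    fit
}

#' Split a chip set into per-probe-set matrices
#'
#' @param chipset a [ChipSet-class].
#' @param mask optional [ArtifactMask-class].
#' @return named list, one element per probe set: `X` (chips x probes),
#'   `mask` (same shape), `rows` (grid-row indices of the probes).
#'   Background cells (no probe set) are excluded.
#' @export
probeSetMatrices <- function(chipset, mask = NULL) {
    rd <- SummarizedExperiment::rowData(chipset)
    m <- intensities(chipset)
    fl <- if (is.null(mask)) matrix(FALSE, nrow(m), ncol(m)) else mask@flags
    assigned <- which(!is.na(rd$probeSet))
    groups <- split(assigned, rd$probeSet[assigned])
    lapply(groups, function(rows) {
        list(X = t(m[rows, , drop = FALSE]),
             mask = t(fl[rows, , drop = FALSE]),
             rows = rows)
    })
}

#' Fit (and impute) every probe set of a batch
#'
#' @param chipset a normalized [ChipSet-class].
#' @param mask optional [ArtifactMask-class]; masked cells are imputed by
#'   [imputeEM()], clean probe sets get a plain [fitRank1()].
#' @param tol,maxIter EM controls.
#' @return named list of [ProbeSetModel-class] objects, ordered by probe
#'   set id.
#' @export
fitProbeSets <- function(chipset, mask = NULL, tol = 1e-8, maxIter = 100L) {
    mats <- probeSetMatrices(chipset, mask)
    models <- lapply(names(mats), function(ps) {
        mm <- mats[[ps]]
        fit <- if (any(mm$mask)) imputeEM(mm$X, mm$mask, probeSet = ps,
                                          tol = tol, maxIter = maxIter)
               else fitRank1(mm$X, probeSet = ps)
        fit@mask <- mm$mask
        fit
    })
    names(models) <- names(mats)
    models[order(names(models))]
}

#' Natural-log expression table
#'
#' @param models list of [ProbeSetModel-class] (e.g. from
#'   [fitProbeSets()]).
#' @param chipIds chip identifiers for the columns.
#' @return probe set x chip matrix of `ln(theta)`; nonpositive expression
#'   values (possible only for pathological fits) become `NA` with a
#'   warning.
#' @export
expressionTable <- function(models, chipIds = NULL) {
    models <- models[order(vapply(models, function(m) m@probeSet, ""))]
    tab <- do.call(rbind, lapply(models, function(m) {
        th <- m@theta
        if (any(th <= 0)) {
            warning(sprintf("probe set '%s': nonpositive expression flagged as missing",
                            m@probeSet))
            th[th <= 0] <- NA_real_
        }
        log(th)
    }))
    rownames(tab) <- vapply(models, function(m) m@probeSet, "")
    if (!is.null(chipIds)) colnames(tab) <- chipIds
    tab
}

#' Write / read an expression table TSV
#' @param tab probe set x chip matrix from [expressionTable()].
#' @param path file path.
#' @export
writeExpressionTable <- function(tab, path) {
    d <- data.frame(probe_set = rownames(tab), tab, check.names = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeExpressionTable
#' @export
readExpressionTable <- function(path) {
    d <- read.delim(path, sep = "\t", check.names = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$probe_set
    m
}

#' Grid of model residuals for one chip
#'
#' Signed residuals `X - theta %*% t(a)` of every fitted probe set,
#' arranged at the probes' grid coordinates; background cells are `NA`.
#' Rendered with a diverging palette, red marks higher-than-expected and
#' blue lower-than-expected intensity.
#'
#' @param models list of [ProbeSetModel-class].
#' @param chipset the [ChipSet-class] the models were fitted on.
#' @param chip chip identifier or index.
#' @return numeric `nRows x nCols` matrix.
#' @export
residualMap <- function(models, chipset, chip) {
    rd <- SummarizedExperiment::rowData(chipset)
    lay <- chipLayout(chipset)
    j <- if (is.character(chip)) match(chip, colnames(chipset)) else chip
    if (is.na(j)) stop(sprintf("unknown chip '%s'", chip), call. = FALSE)
    vals <- rep(NA_real_, nrow(chipset))
    mats <- probeSetMatrices(chipset)
    for (m in models) {
        rows <- mats[[m@probeSet]]$rows
        vals[rows] <- m@residuals[j, ]
    }
    .toGrid(vals, rd$x, rd$y, lay@nCols, lay@nRows)
}
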