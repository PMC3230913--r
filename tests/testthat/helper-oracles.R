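# Independent oracles and small in-code fixtures.

# Brute-force rank-1 Frobenius minimizer: alternating least squares from
# several random starts, never touching svd().
alsRank1Residual <- function(X, restarts = 8L, iters = 300L) {
    X <- as.matrix(X)
    best <- Inf
    for (r in seq_len(restarts)) {
        set.seed(5000L + r)
        a <- runif(ncol(X), 0.5, 1.5)
        th <- rep(1, nrow(X))
        for (i in seq_len(iters)) {
            th <- as.vector(X %*% a) / sum(a^2)
            a <- as.vector(crossprod(X, th)) / sum(th^2)
        }
        best <- min(best, sqrt(sum((X - tcrossprod(th, a))^2)))
    }
    best
}

# Mann-Whitney concordance on |score|, ties counted one half.
aucPairwise <- function(scores, labels) {
    s <- abs(scores)
    pos <- s[as.logical(labels)]
    neg <- s[!as.logical(labels)]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
}

# a ChipSet straight from a cells x chips matrix, all cells in one probe
# set unless a layout is supplied
makeChipSet <- function(m, nCols, nRows, scaleState = "raw", probes = NULL) {
    if (is.null(probes)) {
        g <- expand.grid(x = seq_len(nCols) - 1L, y = seq_len(nRows) - 1L)
        probes <- data.frame(x = g$x, y = g$y, probeSet = "ps1",
                             isMismatch = FALSE)
    }
    lay <- ProbeLayout(nCols, nRows, probes)
    if (is.null(rownames(m)))
        rownames(m) <- paste(
            (seq_len(nrow(m)) - 1L) %% nCols,
            (seq_len(nrow(m)) - 1L) %/% nCols, sep = ":")
    ChipSet(m, lay, scaleState = scaleState)
}

# ScoreMap from a list of nRows x nCols grids, one per chip
makeScoreMap <- function(grids, nCols, nRows) {
    h <- vapply(grids, function(g) {
        v <- numeric(nCols * nRows)
        for (i in seq_along(v)) {
            x <- (i - 1L) %% nCols; y <- (i - 1L) %/% nCols
            v[i] <- g[y + 1L, x + 1L]
        }
        v
    }, numeric(nCols * nRows))
    h <- matrix(h, ncol = length(grids))
    colnames(h) <- paste0("chip", seq_along(grids))
    rownames(h) <- paste((seq_len(nrow(h)) - 1L) %% nCols,
                         (seq_len(nrow(h)) - 1L) %/% nCols, sep = ":")
    new("ScoreMap", z = h, h = h,
        nEff = matrix(3L, nrow(h), ncol(h)),
        x = as.integer((seq_len(nrow(h)) - 1L) %% nCols),
        y = as.integer((seq_len(nrow(h)) - 1L) %/% nCols),
        nCols = as.integer(nCols), nRows = as.integer(nRows))
}

celFixtureLines <- function(means, nCols = 2L, nRows = 2L) {
    g <- expand.grid(x = seq_len(nCols) - 1L, y = seq_len(nRows) - 1L)
    c("[CEL]", "Version=3", "",
      "[HEADER]", sprintf("Cols=%d", nCols), sprintf("Rows=%d", nRows), "",
      "[INTENSITY]", sprintf("NumberCells=%d", nCols * nRows),
      "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS",
      sprintf("%d\t%d\t%.1f\t%.1f\t%d", g$x, g$y, means, 0, 1L))
}

# Brute-force segmentation oracle: double loop over cells and windows,
# NA cells excluded from the window denominator, strict comparisons.
segOracle <- function(g, window, tProbe, tRegion, fMin) {
    half <- (window - 1L) %/% 2L
    nR <- nrow(g); nC <- ncol(g)
    out <- matrix(FALSE, nR, nC)
    for (r in seq_len(nR)) for (c in seq_len(nC)) {
        if (is.na(g[r, c]) || !(g[r, c] > tProbe)) next
        rs <- max(1L, r - half):min(nR, r + half)
        cs <- max(1L, c - half):min(nC, c + half)
        w <- g[rs, cs]
        nDef <- sum(!is.na(w))
        if (nDef > 0 && sum(w > tRegion, na.rm = TRUE) / nDef >= fMin)
            out[r, c] <- TRUE
    }
    out
}
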