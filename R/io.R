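# CEL version-3 text dialect, layout TSV and intensity-matrix TSV I/O.
# Only the v3 text CEL dialect is supported: it is bit-exact reproducible
# and sufficient for interoperation with downstream summarization tools.

.celStop <- function(path, line, msg)
    stop(sprintf("CEL format error in '%s' (line %d): %s", path, line, msg),
         call. = FALSE)

#' Read a CEL version-3 text file
#'
#' Parses the `[CEL]`, `[HEADER]` and `[INTENSITY]` sections of an
#' Affymetrix CEL v3 text file.  Only the MEAN intensity of each cell is
#' used downstream; STDV and NPIXELS are carried through for round
#' tripping.
#'
#' @param path file path.
#' @return list with `nCols`, `nRows`, and `records`, a `data.frame` with
#'   columns `x`, `y`, `mean`, `stdv`, `npixels` in file order.
#' @export
readCelV3 <- function(path) {
    lines <- readLines(path, warn = FALSE)
    sec <- function(name) {
        i <- which(trimws(lines) == paste0("[", name, "]"))
        if (!length(i))
            stop(sprintf("CEL format error in '%s': missing [%s] section", path, name),
                 call. = FALSE)
        i[1L]
    }
    iCel <- sec("CEL"); iHead <- sec("HEADER"); iInt <- sec("INTENSITY")
    keyval <- function(from, key) {
        pat <- paste0("^", key, "=")
        rel <- grep(pat, lines[(from + 1L):length(lines)])
        if (!length(rel))
            stop(sprintf("CEL format error in '%s': missing %s=", path, key),
                 call. = FALSE)
        i <- from + rel[1L]
        list(line = i, value = sub(pat, "", lines[i]))
    }
    ver <- keyval(iCel, "Version")
    if (trimws(ver$value) != "3")
        .celStop(path, ver$line, paste0("unsupported Version=", ver$value))
    num <- function(kv, what) {
        v <- suppressWarnings(as.numeric(kv$value))
        if (is.na(v)) .celStop(path, kv$line, paste0("non-numeric ", what))
        v
    }
    nCols <- num(keyval(iHead, "Cols"), "Cols")
    nRows <- num(keyval(iHead, "Rows"), "Rows")
    nc <- keyval(iInt, "NumberCells")
    nCells <- num(nc, "NumberCells")
    ch <- keyval(iInt, "CellHeader")
    first <- ch$line + 1L
    last <- first + nCells - 1L
    avail <- lines[first:length(lines)]
    avail <- avail[cumsum(grepl("^\\[", trimws(avail))) == 0L]  # stop at next section
    avail <- avail[nzchar(trimws(avail))]
    if (length(avail) < nCells)
        .celStop(path, nc$line,
                 sprintf("NumberCells=%d but only %d data lines present",
                         nCells, length(avail)))
    recs <- matrix(NA_real_, nCells, 5L)
    for (i in seq_len(nCells)) {
        f <- strsplit(trimws(avail[i]), "[ \t]+")[[1L]]
        if (length(f) < 5L)
            .celStop(path, first + i - 1L, "expected 5 fields (X Y MEAN STDV NPIXELS)")
        v <- suppressWarnings(as.numeric(f[1:5]))
        if (anyNA(v))
            .celStop(path, first + i - 1L, paste0("non-numeric cell: ", avail[i]))
        recs[i, ] <- v
    }
    records <- data.frame(x = as.integer(recs[, 1L]), y = as.integer(recs[, 2L]),
                          mean = recs[, 3L], stdv = recs[, 4L],
                          npixels = as.integer(recs[, 5L]))
    if (any(records$x < 0L | records$x >= nCols | records$y < 0L | records$y >= nRows))
        stop(sprintf("CEL format error in '%s': cell coordinates outside %dx%d grid",
                     path, nCols, nRows), call. = FALSE)
    list(nCols = as.integer(nCols), nRows = as.integer(nRows), records = records)
}

#' Write a CEL version-3 text file
#'
#' Inverse of [readCelV3()]: `readCelV3(writeCelV3(...))` reproduces the
#' records exactly, and a write-read-write cycle is byte identical.  MEAN
#' and STDV are printed with one decimal place.
#'
#' @param nCols,nRows grid dimensions.
#' @param records `data.frame` with columns `x`, `y`, `mean`, `stdv`,
#'   `npixels`; must cover the declared grid exactly once.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCelV3 <- function(nCols, nRows, records, path) {
    nCells <- as.integer(nCols) * as.integer(nRows)
    key <- paste(records$x, records$y, sep = ":")
    want <- .gridKeys(as.integer(nCols), as.integer(nRows))
    if (nrow(records) != nCells || !setequal(key, want) || anyDuplicated(key))
        stop(sprintf("records do not cover the %dx%d grid exactly once", nCols, nRows),
             call. = FALSE)
    if (is.null(records$stdv)) records$stdv <- 0
    if (is.null(records$npixels)) records$npixels <- 1L
    body <- sprintf("%d\t%d\t%.1f\t%.1f\t%d",
                    as.integer(records$x), as.integer(records$y),
                    records$mean, records$stdv, as.integer(records$npixels))
    lines <- c("[CEL]", "Version=3", "",
               "[HEADER]",
               sprintf("Cols=%d", as.integer(nCols)),
               sprintf("Rows=%d", as.integer(nRows)), "",
               "[INTENSITY]",
               sprintf("NumberCells=%d", nCells),
               "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS",
               body)
    writeLines(lines, path)
    invisible(path)
}

#' Read a probe layout TSV
#'
#' The layout file replaces the proprietary chip description file: a
#' tab-separated table with header columns `probe_set_id`, `x`, `y`,
#' `is_mm` assigning grid cells to probe sets.  Grid dimensions default to
#' the smallest grid containing all coordinates unless given.
#'
#' @param path file path.
#' @param nCols,nRows optional explicit grid dimensions.
#' @return A [ProbeLayout-class].
#' @export
readLayout <- function(path, nCols = NULL, nRows = NULL) {
    d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("probe_set_id", "x", "y", "is_mm")
    if (!all(need %in% names(d)))
        stop(sprintf("layout '%s' must have columns %s", path,
                     paste(need, collapse = ", ")), call. = FALSE)
    if (is.null(nCols)) nCols <- max(d$x) + 1L
    if (is.null(nRows)) nRows <- max(d$y) + 1L
    ProbeLayout(nCols, nRows,
                data.frame(x = d$x, y = d$y, probeSet = d$probe_set_id,
                           isMismatch = as.logical(d$is_mm)))
}

#' Write a probe layout TSV
#' @param layout a [ProbeLayout-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLayout <- function(layout, path) {
    p <- layout@probes
    d <- data.frame(probe_set_id = p$probeSet, x = p$x, y = p$y,
                    is_mm = as.integer(p$isMismatch))
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble a ChipSet from CEL files or an intensity matrix
#'
#' @param layout a [ProbeLayout-class] shared by all chips.
#' @param celPaths character vector of CEL v3 text files, one per chip.
#' @param intensities alternatively, a numeric matrix (grid cells x chips)
#'   with `"x:y"` row keys.
#' @param chipIds chip identifiers; defaults to CEL file base names or
#'   matrix column names.
#' @return A [ChipSet-class] with `scaleState = "raw"`, chips in input
#'   order.
#' @export
assembleChipSet <- function(layout, celPaths = NULL, intensities = NULL,
                            chipIds = NULL) {
    if (is.null(celPaths) == is.null(intensities))
        stop("supply exactly one of celPaths or intensities", call. = FALSE)
    if (!is.null(celPaths)) {
        if (is.null(chipIds))
            chipIds <- sub("\\.[Cc][Ee][Ll](\\.txt)?$", "", basename(celPaths))
        keys <- .gridKeys(layout@nCols, layout@nRows)
        m <- matrix(NA_real_, length(keys), length(celPaths),
                    dimnames = list(keys, chipIds))
        for (j in seq_along(celPaths)) {
            cel <- readCelV3(celPaths[j])
            if (cel$nCols != layout@nCols || cel$nRows != layout@nRows)
                stop(sprintf("chip '%s': CEL grid %dx%d does not match layout %dx%d",
                             chipIds[j], cel$nCols, cel$nRows,
                             layout@nCols, layout@nRows), call. = FALSE)
            k <- paste(cel$records$x, cel$records$y, sep = ":")
            m[match(k, keys), j] <- cel$records$mean
        }
        intensities <- m
    }
    ChipSet(intensities, layout, chipIds = chipIds, scaleState = "raw")
}

#' Read / write an intensity matrix TSV
#'
#' First column `probe` holds `"x:y"` grid keys; remaining columns are
#' chips.
#'
#' @param path file path.
#' @return For the reader, a numeric matrix with `"x:y"` rownames.
#' @export
readIntensityMatrix <- function(path) {
    d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
    if (names(d)[1L] != "probe")
        stop(sprintf("'%s': first column must be 'probe'", path), call. = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$probe
    storage.mode(m) <- "double"
    m
}

#' @rdname readIntensityMatrix
#' @param m numeric matrix with `"x:y"` rownames.
#' @param digits significant digits used when printing.
#' @export
writeIntensityMatrix <- function(m, path, digits = 10L) {
    d <- data.frame(probe = rownames(m),
                    apply(m, 2L, function(v) formatC(v, digits = digits, format = "g")),
                    check.names = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write cleaned CEL v3 files for every chip
#'
#' Emits one CEL v3 text file per chip with the chip set's current
#' intensities (typically normalized and imputed, i.e. on the normalized
#' scale) as MEAN values, STDV 0 and NPIXELS 1.
#'
#' @param chipset a [ChipSet-class].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
writeCleanCels <- function(chipset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    lay <- chipLayout(chipset)
    rd <- SummarizedExperiment::rowData(chipset)
    m <- intensities(chipset)
    paths <- character(ncol(m))
    for (j in seq_len(ncol(m))) {
        recs <- data.frame(x = rd$x, y = rd$y, mean = m[, j],
                           stdv = 0, npixels = 1L)
        paths[j] <- file.path(dir, paste0(colnames(m)[j], ".CEL.txt"))
        writeCelV3(lay@nCols, lay@nRows, recs, paths[j])
    }
    invisible(paths)
}
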