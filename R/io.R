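#' Read and write gene x sample intensity matrices as TSV
#'
#' Plain tab-separated text: first column the gene id, header row the
#' sample ids. Round trips are lossless (floats serialized with 17
#' significant digits). Duplicate or missing ids are rejected with the
#' offending id named.
#'
#' @param path file path.
#' @return for `readIntensityMatrix`, a numeric matrix with gene
#'   rownames and sample colnames.
#' @export
readIntensityMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate gene id: ", ids[duplicated(ids)][1L])
    if (anyNA(ids) || any(!nzchar(ids)))
        stop("missing gene id in first column")
    if (anyDuplicated(colnames(df)[-1L]))
        stop("duplicate sample id: ",
             colnames(df)[-1L][duplicated(colnames(df)[-1L])][1L])
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    m
}

#' @rdname readIntensityMatrix
#' @param x numeric matrix (or [IntensityExperiment-class]) to write.
#' @param idColumn name of the gene-id column (default `"gene"`).
#' @return for `writeIntensityMatrix`, `path` invisibly.
#' @export
writeIntensityMatrix <- function(x, path, idColumn = "gene") {
    if (is(x, "IntensityExperiment")) x <- intensities(x)
    df <- data.frame(id = rownames(x),
                     format(x, digits = 17, trim = TRUE, scientific = NA),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c(idColumn, colnames(x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble an IntensityExperiment from TSV files
#'
#' @param matrixPath intensity matrix TSV (see [readIntensityMatrix()]).
#' @param samplesPath sample annotation TSV: first column sample id, plus
#'   `donor`, `medium` and optionally `sex` columns.
#' @param genesPath optional gene annotation TSV: first column gene id,
#'   plus `symbol`, `chromosome`, `hkg_candidate`, `negative_control`.
#' @return an [IntensityExperiment-class].
#' @export
readExperiment <- function(matrixPath, samplesPath, genesPath = NULL) {
    m <- readIntensityMatrix(matrixPath)
    si <- read.delim(samplesPath, stringsAsFactors = FALSE)
    rownames(si) <- si[[1L]]
    si <- si[colnames(m), -1L, drop = FALSE]
    gi <- NULL
    if (!is.null(genesPath)) {
        gi <- read.delim(genesPath, stringsAsFactors = FALSE)
        rownames(gi) <- gi[[1L]]
        gi <- gi[rownames(m), -1L, drop = FALSE]
    }
    IntensityExperiment(m, si, gi)
}
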