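#' Select housekeeping genes by expression stability
#'
#' Ranks candidate reference genes by the sample standard deviation of
#' their log2 intensities across samples and returns the `k` most stable
#' ones. Log scale is used because all downstream analyses operate on
#' log-transformed values and the ranking is then robust to overall
#' brightness differences between genes. Ties are broken
#' lexicographically by gene id; the output is ordered by ascending SD.
#'
#' @param x an [IntensityExperiment-class] or intensity matrix.
#' @param candidates character vector of candidate gene ids (all must be
#'   rows of `x`).
#' @param k number of genes to select (`k <= length(candidates)`).
#' @return character vector of `k` gene ids.
#' @name selectHousekeeping
#' @aliases selectHousekeeping,matrix-method
#'   selectHousekeeping,IntensityExperiment-method
setMethod("selectHousekeeping", "matrix", function(x, candidates, k) {
    missing <- setdiff(candidates, rownames(x))
    if (length(missing))
        stop("unknown candidate gene id(s): ",
             paste(missing, collapse = ", "))
    if (k > length(candidates))
        stop("k must not exceed the number of candidates")
    sdlog <- apply(log2(x[candidates, , drop = FALSE]), 1L, sd)
    candidates[order(sdlog, candidates)][seq_len(k)]
})

setMethod("selectHousekeeping", "IntensityExperiment",
          function(x, candidates, k)
              selectHousekeeping(intensities(x), candidates, k))

#' Housekeeping-gene normalization
#'
#' Rescales every sample multiplicatively so that its mean housekeeping
#' intensity equals the grand mean of the per-sample housekeeping means:
#' the factor for sample s is `grandMean / hkgMean_s`. Multiplicative
#' scaling on the raw scale (additive on the log scale) is the standard
#' reference-gene convention and preserves non-negativity. The operation
#' is idempotent.
#'
#' @param x an [IntensityExperiment-class] or intensity matrix.
#' @param hkgIds non-empty character vector of housekeeping gene ids.
#' @return for a matrix, a list with `matrix` (normalized) and `factors`
#'   (named per-sample scale factors); for an `IntensityExperiment`, the
#'   object with its intensity assay normalized and the factors stored in
#'   `metadata(x)$hkgScaleFactors`.
#' @name normalizeByHkg
#' @aliases normalizeByHkg,matrix-method
#'   normalizeByHkg,IntensityExperiment-method
setMethod("normalizeByHkg", "matrix", function(x, hkgIds) {
    if (!length(hkgIds)) stop("hkgIds must be non-empty")
    missing <- setdiff(hkgIds, rownames(x))
    if (length(missing))
        stop("unknown housekeeping gene id(s): ",
             paste(missing, collapse = ", "))
    hkgMeans <- colMeans(x[hkgIds, , drop = FALSE])
    if (any(hkgMeans <= 0))
        stop("degenerate sample: zero housekeeping mean in ",
             paste(colnames(x)[hkgMeans <= 0], collapse = ", "))
    factors <- mean(hkgMeans) / hkgMeans
    list(matrix = sweep(x, 2L, factors, `*`), factors = factors)
})

setMethod("normalizeByHkg", "IntensityExperiment", function(x, hkgIds) {
    res <- normalizeByHkg(intensities(x), hkgIds)
    assay(x, "intensity") <- res$matrix
    metadata(x)$hkgScaleFactors <- res$factors
    x
})

#' Detection limit from negative-control genes
#'
#' Pools all intensities of the negative-control genes over all samples
#' into one vector and returns its `q`-th percentile, computed by linear
#' interpolation between closest ranks (position `1 + (n - 1) q` on the
#' sorted vector; `stats::quantile` type 7).
#'
#' @param x an [IntensityExperiment-class] or intensity matrix.
#' @param negativeIds non-empty character vector of negative-control
#'   gene ids.
#' @param q percentile in (0, 1); default 0.95.
#' @return the detection limit, in fluorescence units.
#' @name detectionLimit
#' @aliases detectionLimit,matrix-method
#'   detectionLimit,IntensityExperiment-method
setMethod("detectionLimit", "matrix", function(x, negativeIds, q = 0.95) {
    if (!length(negativeIds))
        stop("negativeIds must be non-empty")
    missing <- setdiff(negativeIds, rownames(x))
    if (length(missing))
        stop("unknown negative-control gene id(s): ",
             paste(missing, collapse = ", "))
    if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
    pooled <- as.numeric(x[negativeIds, , drop = FALSE])
    quantile(pooled, q, type = 7, names = FALSE)
})

setMethod("detectionLimit", "IntensityExperiment",
          function(x, negativeIds, q = 0.95)
              detectionLimit(intensities(x), negativeIds, q))

#' Three-criterion expressed-gene filter
#'
#' A gene is kept iff it is expressed (1) strictly above the detection
#' limit in at least 4 samples, or (2) above twice the limit in at least
#' 2 samples, or (3) above three times the limit in at least 1 sample.
#' "Above" is strict; boundary equality fails the criterion.
#'
#' @param x an [IntensityExperiment-class] or intensity matrix.
#' @param limit detection limit (fluorescence units, >= 0).
#' @return named logical keep-mask per gene.
#' @name filterExpressed
#' @aliases filterExpressed,matrix-method
#'   filterExpressed,IntensityExperiment-method
setMethod("filterExpressed", "matrix", function(x, limit) {
    if (limit < 0) stop("limit must be >= 0")
    c1 <- rowSums(x > limit) >= 4L
    c2 <- rowSums(x > 2 * limit) >= 2L
    c3 <- rowSums(x > 3 * limit) >= 1L
    structure(c1 | c2 | c3, names = rownames(x))
})

setMethod("filterExpressed", "IntensityExperiment",
          function(x, limit) filterExpressed(intensities(x), limit))

#' Exclude sex-linked genes
#'
#' Removes genes annotated to chromosome Y and the gene with symbol XIST,
#' the standardization applied when donors are of mixed sex. Genes with
#' missing chromosome annotation are retained, never silently dropped.
#' With `invert = TRUE` the *complement* is returned (only the sex genes),
#' supporting the quality-control contrast that re-includes them.
#'
#' @param x an [IntensityExperiment-class].
#' @param invert return only the sex-linked genes instead of dropping
#'   them.
#' @return the subsetted [IntensityExperiment-class].
#' @export
excludeSexGenes <- function(x, invert = FALSE) {
    stopifnot(is(x, "IntensityExperiment"))
    gi <- geneAnnotation(x)
    chrom <- as.character(gi$chromosome)
    isSex <- (!is.na(chrom) & chrom == "Y") |
        (!is.na(gi$symbol) & gi$symbol == "XIST")
    if (invert) x[isSex, ] else x[!isSex, ]
}

#' Full pre-processing pipeline
#'
#' Fixed stage order: housekeeping selection and normalization, detection
#' limit on the *normalized* negative-control intensities, the
#' three-criterion expression filter, then sex-gene exclusion. The
#' report records gene counts at each stage (they telescope) and the
#' detection limit under both the normalized and raw conventions.
#'
#' @param x an [IntensityExperiment-class] whose `rowData` flags
#'   housekeeping candidates and negative controls.
#' @param hkgK number of housekeeping genes to use (default 12).
#' @param percentile negative-control percentile defining the detection
#'   limit (default 0.95).
#' @param excludeSex drop Y-chromosome genes and XIST (default TRUE; set
#'   FALSE for the sex-gene quality-control analysis).
#' @return list with `experiment` (the processed
#'   [IntensityExperiment-class]) and `report`
#'   (a [PreprocessReport-class]).
#' @examples
#' ie <- simulateExperiment(simConfig(seed = 2, nGenes = 400))
#' pp <- preprocess(ie)
#' pp$report
#' @export
preprocess <- function(x, hkgK = 12L, percentile = 0.95,
                       excludeSex = TRUE) {
    stopifnot(is(x, "IntensityExperiment"))
    gi <- geneAnnotation(x)
    candidates <- rownames(x)[gi$hkg_candidate]
    negativeIds <- rownames(x)[gi$negative_control]
    if (!length(candidates)) stop("no housekeeping candidates flagged")
    if (!length(negativeIds)) stop("no negative controls flagged")

    hkg <- selectHousekeeping(x, candidates, hkgK)
    limitRaw <- detectionLimit(x, negativeIds, percentile)
    norm <- normalizeByHkg(x, hkg)
    limit <- detectionLimit(norm, negativeIds, percentile)

    nx <- intensities(norm)
    keep <- filterExpressed(nx, limit)
    criterionCounts <- c(
        sum(rowSums(nx > limit) >= 4L),
        sum(rowSums(nx > 2 * limit) >= 2L),
        sum(rowSums(nx > 3 * limit) >= 1L))
    filtered <- norm[keep, ]
    out <- if (excludeSex) excludeSexGenes(filtered) else filtered

    report <- new("PreprocessReport",
                  hkgIds = hkg,
                  scaleFactors = metadata(norm)$hkgScaleFactors,
                  detectionLimit = limit,
                  detectionLimitRaw = limitRaw,
                  criterionCounts = as.integer(criterionCounts),
                  nInput = nrow(x),
                  nFiltered = nrow(x) - nrow(filtered),
                  nSexExcluded = nrow(filtered) - nrow(out),
                  nRetained = nrow(out))
    list(experiment = out, report = report)
}
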