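#' @rdname intensities
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Accessors for IntensityExperiment
#'
#' `intensities()` returns the gene x sample intensity matrix;
#' `sampleAnnotation()` and `geneAnnotation()` return the sample and gene
#' annotation tables as plain data.frames; `simTruth()` returns the
#' ground-truth record attached by [simulateExperiment()] (or `NULL`).
#'
#' @param x an [IntensityExperiment-class].
#' @return see description.
#' @name intensities
#' @aliases intensities,IntensityExperiment-method
setMethod("intensities", "IntensityExperiment",
          function(x) assay(x, "intensity"))

#' @rdname intensities
#' @export
setGeneric("sampleAnnotation", function(x) standardGeneric("sampleAnnotation"))

#' @rdname intensities
#' @aliases sampleAnnotation,IntensityExperiment-method
setMethod("sampleAnnotation", "IntensityExperiment",
          function(x) as.data.frame(colData(x)))

#' @rdname intensities
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname intensities
#' @aliases geneAnnotation,IntensityExperiment-method
setMethod("geneAnnotation", "IntensityExperiment",
          function(x) as.data.frame(rowData(x)))

#' @rdname intensities
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname intensities
#' @aliases simTruth,IntensityExperiment-method
setMethod("simTruth", "IntensityExperiment",
          function(x) metadata(x)$simTruth)

#' @rdname selectHousekeeping
#' @export
setGeneric("selectHousekeeping",
           function(x, candidates, k) standardGeneric("selectHousekeeping"))

#' @rdname normalizeByHkg
#' @export
setGeneric("normalizeByHkg",
           function(x, hkgIds) standardGeneric("normalizeByHkg"))

#' @rdname detectionLimit
#' @export
setGeneric("detectionLimit",
           function(x, negativeIds, q = 0.95) standardGeneric("detectionLimit"))

#' @rdname filterExpressed
#' @export
setGeneric("filterExpressed",
           function(x, limit) standardGeneric("filterExpressed"))

#' @rdname zscoreLog
#' @export
setGeneric("zscoreLog", function(x) standardGeneric("zscoreLog"))

#' @rdname spearmanMatrix
#' @export
setGeneric("spearmanMatrix",
           function(x, allowConstant = FALSE) standardGeneric("spearmanMatrix"))

#' @rdname clusterSamples
#' @export
setGeneric("clusterSamples", function(x, ...) standardGeneric("clusterSamples"))
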