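#' IntensityExperiment: gene x sample fluorescence intensities with
#' two-factor sample annotation
#'
#' The package's central container, a thin extension of
#' [SummarizedExperiment::SummarizedExperiment] that enforces the contract
#' every downstream stage relies on: a single non-negative, NA-free
#' `"intensity"` assay, unique gene and sample identifiers, and a sample
#' annotation carrying one `donor` and one `medium` level per sample.
#' Gene annotation (`rowData`) holds `symbol`, `chromosome` and the
#' `hkg_candidate` / `negative_control` flags that drive pre-processing.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @seealso [IntensityExperiment()] for construction,
#'   [simulateExperiment()] for synthetic instances.
#' @export
setClass("IntensityExperiment", contains = "SummarizedExperiment")

.validIntensityExperiment <- function(object) {
    msg <- character()
    if (!"intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        x <- assay(object, "intensity")
        if (anyNA(x)) msg <- c(msg, "intensity values must not contain NA")
        else if (any(x < 0)) msg <- c(msg, "intensity values must be >= 0")
    }
    if (nrow(object) < 2L || ncol(object) < 2L)
        msg <- c(msg, "at least 2 genes and 2 samples are required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    for (fac in c("donor", "medium"))
        if (!fac %in% colnames(colData(object)))
            msg <- c(msg, sprintf("colData must contain a '%s' column", fac))
    if (length(msg)) msg else TRUE
}

setValidity("IntensityExperiment", .validIntensityExperiment)

#' Construct an IntensityExperiment
#'
#' @param intensity numeric matrix of non-negative fluorescence values,
#'   genes in rows (unique rownames), samples in columns (unique colnames).
#' @param sampleInfo data.frame with one row per sample and at least the
#'   columns `donor` and `medium`; a `sex` column (`"male"`/`"female"`) is
#'   used by [excludeSexGenes()] quality-control contrasts when present.
#' @param geneInfo optional data.frame with one row per gene; recognised
#'   columns are `symbol`, `chromosome`, `hkg_candidate`,
#'   `negative_control`. Missing columns are filled with neutral defaults.
#'
#' @return an [IntensityExperiment-class] object.
#' @examples
#' m <- matrix(2^rnorm(40, 8), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' si <- data.frame(donor = rep(c("d1", "d2"), 2),
#'                  medium = rep(c("A", "B"), each = 2))
#' ie <- IntensityExperiment(m, si)
#' @export
IntensityExperiment <- function(intensity, sampleInfo, geneInfo = NULL) {
    intensity <- as.matrix(intensity)
    if (is.null(geneInfo))
        geneInfo <- data.frame(row.names = rownames(intensity))
    defaults <- list(symbol = rownames(intensity),
                     chromosome = NA_character_,
                     hkg_candidate = FALSE,
                     negative_control = FALSE)
    for (col in names(defaults))
        if (!col %in% colnames(geneInfo)) geneInfo[[col]] <- defaults[[col]]
    if (any(geneInfo$hkg_candidate & geneInfo$negative_control))
        stop("hkg_candidate and negative_control are mutually exclusive")
    se <- SummarizedExperiment(
        assays = list(intensity = intensity),
        colData = DataFrame(sampleInfo, row.names = colnames(intensity)),
        rowData = DataFrame(geneInfo, row.names = rownames(intensity)))
    new("IntensityExperiment", se)
}

setMethod("show", "IntensityExperiment", function(object) {
    cat(sprintf("IntensityExperiment: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    cd <- colData(object)
    cat(sprintf("  media:  %s\n",
                paste(unique(as.character(cd$medium)), collapse = ", ")))
    cat(sprintf("  donors: %s\n",
                paste(unique(as.character(cd$donor)), collapse = ", ")))
    rd <- rowData(object)
    cat(sprintf("  gene flags: %d housekeeping candidates, %d negative controls\n",
                sum(rd$hkg_candidate), sum(rd$negative_control)))
    invisible(NULL)
})

#' PreprocessReport: bookkeeping from the pre-processing pipeline
#'
#' Records which housekeeping genes were selected, the per-sample scale
#' factors, the detection limit (on both normalized and raw intensities,
#' since the convention is platform-dependent), per-criterion pass counts
#' of the three-criterion expression filter, and the gene counts at every
#' stage. Counts telescope: `nInput - nFiltered - nSexExcluded = nRetained`.
#'
#' @slot hkgIds character, selected housekeeping gene ids (ascending SD).
#' @slot scaleFactors numeric, per-sample multiplicative factors.
#' @slot detectionLimit numeric(1), detection limit on normalized values.
#' @slot detectionLimitRaw numeric(1), detection limit on raw values.
#' @slot criterionCounts integer(3), genes passing each filter criterion.
#' @slot nInput,nFiltered,nSexExcluded,nRetained integer(1) stage counts.
#' @export
setClass("PreprocessReport", representation(
    hkgIds = "character",
    scaleFactors = "numeric",
    detectionLimit = "numeric",
    detectionLimitRaw = "numeric",
    criterionCounts = "integer",
    nInput = "integer",
    nFiltered = "integer",
    nSexExcluded = "integer",
    nRetained = "integer"))

setValidity("PreprocessReport", function(object) {
    msg <- character()
    if (object@detectionLimit < 0)
        msg <- c(msg, "detection limit must be >= 0")
    if (object@nInput - object@nFiltered - object@nSexExcluded !=
        object@nRetained)
        msg <- c(msg, "stage counts must telescope")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PreprocessReport", function(object) {
    cat("PreprocessReport\n")
    cat(sprintf("  housekeeping genes (%d): %s\n", length(object@hkgIds),
                paste(object@hkgIds, collapse = ", ")))
    cat(sprintf("  detection limit: %.4g (raw-scale: %.4g)\n",
                object@detectionLimit, object@detectionLimitRaw))
    cat(sprintf("  criterion pass counts: %s\n",
                paste(object@criterionCounts, collapse = " / ")))
    cat(sprintf("  genes: %d in -> %d below detection -> %d sex-excluded -> %d retained\n",
                object@nInput, object@nFiltered, object@nSexExcluded,
                object@nRetained))
    invisible(NULL)
})

#' ContrastResult: one pairwise differential-expression comparison
#'
#' Per-gene statistics for a single two-group contrast fitted by
#' [fitContrast()]: log2 fold change (level A minus level B), group means,
#' gene-wise and moderated variances, moderated t, raw and BH-adjusted p,
#' and the four-way volcano class.
#'
#' @slot table data.frame with one row per gene (see [fitContrast()]).
#' @slot factorName `"medium"` or `"donor"`.
#' @slot levelA,levelB the contrasted factor levels.
#' @slot d0 prior degrees of freedom used (may be `Inf` or 0).
#' @slot s02 prior variance used (log2^2 units).
#' @slot fcThreshold,alpha thresholds behind the volcano classes.
#' @export
setClass("ContrastResult", representation(
    table = "data.frame",
    factorName = "character",
    levelA = "character",
    levelB = "character",
    d0 = "numeric",
    s02 = "numeric",
    fcThreshold = "numeric",
    alpha = "numeric"))

setMethod("show", "ContrastResult", function(object) {
    tab <- object@table
    cat(sprintf("ContrastResult: %s %s vs %s (%d genes)\n",
                object@factorName, object@levelA, object@levelB, nrow(tab)))
    cat(sprintf("  moderation prior: d0 = %.3g, s0^2 = %.3g\n",
                object@d0, object@s02))
    cls <- table(factor(tab$class, levels = c("red", "green", "blue", "grey")))
    cat(sprintf("  volcano classes: red %d, green %d, blue %d, grey %d\n",
                cls["red"], cls["green"], cls["blue"], cls["grey"]))
    invisible(NULL)
})

#' Accessor for the per-gene table of a ContrastResult
#'
#' @param x a [ContrastResult-class].
#' @return data.frame with columns `gene`, `log2FC`, `meanA`, `meanB`,
#'   `s2`, `df`, `s2Moderated`, `t`, `dfTotal`, `p`, `adjP`, `class`.
#' @export
contrastTable <- function(x) {
    stopifnot(is(x, "ContrastResult"))
    x@table
}
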