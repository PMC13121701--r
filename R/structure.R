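#' Per-gene z-scores of log2 intensities
#'
#' Row-wise standardization of the log2-transformed matrix: each gene is
#' centered to mean 0 and scaled to sample SD 1 (n - 1 denominator).
#' Constant rows cannot be scaled and map to all-zero rows with a
#' warning. Base-2 logs are used throughout the package; the base cancels
#' in the z-scores.
#'
#' @param x an [IntensityExperiment-class] or matrix of strictly positive
#'   intensities.
#' @return numeric matrix of the same shape (dimensionless).
#' @name zscoreLog
#' @aliases zscoreLog,matrix-method zscoreLog,IntensityExperiment-method
setMethod("zscoreLog", "matrix", function(x) {
    if (any(x <= 0))
        stop("non-positive intensity: log transform undefined")
    lg <- log2(x)
    mu <- rowMeans(lg)
    sdv <- sqrt(rowSums((lg - mu)^2) / (ncol(lg) - 1L))
    const <- sdv == 0
    if (any(const)) {
        warning(sprintf("%d constant gene row(s) mapped to zero", sum(const)))
        sdv[const] <- 1
    }
    z <- (lg - mu) / sdv
    z[const, ] <- 0
    z
})

setMethod("zscoreLog", "IntensityExperiment",
          function(x) zscoreLog(intensities(x)))

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns using Euclidean
#' distance and complete linkage (inter-cluster distance = maximum
#' pairwise distance). Returns a standard `hclust` tree; merge heights
#' are non-decreasing under complete linkage.
#'
#' @param x a matrix whose columns are samples (typically a z-score
#'   matrix from [zscoreLog()]), or an [IntensityExperiment-class]
#'   (clustered on z-scored log2 intensities).
#' @param method linkage method (default `"complete"`).
#' @return an object of class `hclust`.
#' @name clusterSamples
#' @aliases clusterSamples,matrix-method
#'   clusterSamples,IntensityExperiment-method
setMethod("clusterSamples", "matrix", function(x, method = "complete") {
    if (ncol(x) < 2L) stop("at least 2 samples required")
    hclust(dist(t(x), method = "euclidean"), method = method)
})

setMethod("clusterSamples", "IntensityExperiment",
          function(x, method = "complete")
              clusterSamples(zscoreLog(x), method = method))

#' Export a sample dendrogram as Newick
#'
#' @param hc an `hclust` object from [clusterSamples()].
#' @param path optional file path; when omitted, the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogramNewick <- function(hc, path = NULL) {
    phy <- ape::as.phylo(hc)
    if (is.null(path)) ape::write.tree(phy)
    else { ape::write.tree(phy, file = path); invisible(ape::write.tree(phy)) }
}

#' Spearman correlation matrix between samples
#'
#' Pairwise Spearman rank correlation over the gene dimension, using
#' mid-ranks for ties, computed on the raw (untransformed) expression
#' values — rank correlation is invariant to monotone transforms, so the
#' scale choice is cosmetic.
#'
#' @param x an [IntensityExperiment-class] or matrix (genes x samples).
#' @param allowConstant keep columns with zero variance (their
#'   correlations are `NA`) instead of erroring.
#' @return samples x samples symmetric matrix with unit diagonal.
#' @name spearmanMatrix
#' @aliases spearmanMatrix,matrix-method
#'   spearmanMatrix,IntensityExperiment-method
setMethod("spearmanMatrix", "matrix", function(x, allowConstant = FALSE) {
    if (nrow(x) < 2L) stop("at least 2 genes required")
    constant <- apply(x, 2L, function(v) max(v) == min(v))
    if (any(constant) && !allowConstant)
        stop("constant sample column(s): ",
             paste(colnames(x)[constant], collapse = ", "),
             " (set allowConstant = TRUE to keep as NA)")
    r <- suppressWarnings(cor(x, method = "spearman"))
    diag(r) <- 1
    r
})

setMethod("spearmanMatrix", "IntensityExperiment",
          function(x, allowConstant = FALSE)
              spearmanMatrix(intensities(x), allowConstant))

#' Principal component analysis of samples
#'
#' PCA of the samples in gene space via singular-value decomposition of
#' the column-centered data (each sample is an observation, each gene a
#' variable). Returns per-sample scores, per-gene importances (absolute
#' loadings) and the percentage of variance explained per component.
#' Sign convention: each component is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param z matrix (genes x samples), typically z-scores from
#'   [zscoreLog()] restricted to a gene subset.
#' @param nComponents number of components to report (default 3; reduced
#'   with a warning if it exceeds the rank).
#' @return list with `scores` (samples x k), `importance` (genes x k,
#'   absolute loadings), `loadings` (signed), and `r2` (percent variance,
#'   non-increasing).
#' @export
pcaSamples <- function(z, nComponents = 3L) {
    if (!nrow(z)) stop("gene set is empty")
    pc <- prcomp(t(z), center = TRUE, scale. = FALSE)
    r2all <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
    if (nComponents > rank) {
        warning(sprintf("nComponents reduced from %d to rank %d",
                        nComponents, rank))
        nComponents <- rank
    }
    k <- seq_len(nComponents)
    scores <- pc$x[, k, drop = FALSE]
    load <- pc$rotation[, k, drop = FALSE]
    for (j in seq_along(k)) {
        top <- which.max(abs(load[, j]))
        if (load[top, j] < 0) {
            load[, j] <- -load[, j]
            scores[, j] <- -scores[, j]
        }
    }
    list(scores = scores, importance = abs(load), loadings = load,
         r2 = r2all[k])
}

#' Clustering purity with respect to a sample factor
#'
#' Cuts the dendrogram into `k` clusters (removing the k - 1 tallest
#' merges) and returns the fraction of samples whose cluster's majority
#' label matches their own: `sum over clusters of majority count / n`.
#' Purity 1.0 means the clusters coincide with the factor's levels.
#'
#' @param hc an `hclust` tree over the samples.
#' @param labels factor levels, one per sample, in the tree's input
#'   order.
#' @param k number of clusters (`k <= n` samples).
#' @return purity in \[0, 1\].
#' @examples
#' ie <- simulateExperiment(simConfig(seed = 5, nGenes = 500,
#'                                    sigmaMedium = 2))
#' hc <- clusterSamples(ie)
#' groupingPurity(hc, sampleAnnotation(ie)$medium, k = 4)
#' @export
groupingPurity <- function(hc, labels, k) {
    n <- length(hc$order)
    stopifnot(length(labels) == n, k <= n)
    cl <- cutree(hc, k = k)
    maj <- tapply(as.character(labels), cl,
                  function(v) max(table(v)))
    sum(maj) / n
}
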