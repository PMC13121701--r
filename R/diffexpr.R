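#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on the sorted p-values,
#' adjusted p_(i) = min over j >= i of min(1, m p_(j) / j), mapped back
#' to the input order. Validates the input and delegates the arithmetic
#' to `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @examples
#' adjustBH(c(0.01, 0.02, 0.04, 0.5))
#' @export
adjustBH <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] and contain no NA")
    p.adjust(p, method = "BH")
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x` for `y > 0`, used by the
#' moment-matching estimator of the moderation prior. Monotone and
#' well-conditioned; extreme arguments use the asymptotic forms
#' `trigamma(y) ~ 1/y` (y large argument x small) and `~ 1/y` near zero.
#'
#' @param x positive numeric vector.
#' @return y with `trigamma(y) = x` (elementwise).
#' @keywords internal
trigammaInverse <- function(x) {
    y <- 0.5 + 1 / x
    out <- y
    small <- x < 1e-6       # trigamma(y) ~ 1/y^2 is irrelevant here; ~1/y tail
    big <- x > 1e7
    out[small] <- 1 / x[small]
    out[big] <- 1 / sqrt(x[big])
    todo <- which(!small & !big)
    y <- y[todo]; xv <- x[todo]
    for (i in seq_len(60)) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / xv) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (max(abs(dif / y)) < 1e-10) break
    }
    out[todo] <- y
    out
}

#' Moment-matching estimate of the variance-moderation prior
#'
#' Fits the empirical-Bayes hyperparameters (prior degrees of freedom d0
#' and prior variance s0^2) from the distribution of log gene-wise
#' variances. Under the scaled inverse-chi-square prior,
#' `Var(log s^2) = trigamma(d/2) + trigamma(d0/2)` and
#' `E(log s^2) = log s0^2 + digamma(d/2) - log(d/2) -
#' digamma(d0/2) + log(d0/2)`; both are solved in closed form given the
#' observed mean and variance of `log s^2`. If the observed spread does
#' not exceed the sampling spread `trigamma(d/2)`, d0 is `Inf` (complete
#' shrinkage to s0^2).
#'
#' @param s2 gene-wise residual variances (log2^2 units).
#' @param df residual degrees of freedom (scalar).
#' @return list with `d0` and `s02`.
#' @export
estimateModerationPrior <- function(s2, df) {
    ok <- is.finite(s2) & s2 > 0
    if (!any(ok))
        stop("degenerate fit: zero residual variance in all genes")
    if (mean(ok) < 0.95)
        warning(sprintf("%d genes with zero variance ignored in prior estimation",
                        sum(!ok)))
    z <- log(s2[ok])
    evar <- var(z) - trigamma(df / 2)
    if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
    } else {
        d0 <- 2 * trigammaInverse(evar)
        s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                       digamma(d0 / 2) - log(d0 / 2))
    }
    list(d0 = d0, s02 = s02)
}

#' Fit one pairwise contrast with a moderated t-statistic
#'
#' Two-group comparison under the replicate-swapping design: when media
#' are contrasted, the donor lines cultured in each medium act as
#' replicates, and vice versa. Per gene, `log2FC = mean(A) - mean(B)` on
#' the log2 scale, the pooled gene-wise variance s_g^2 has
#' `d_g = n_A + n_B - 2` degrees of freedom, the moderated variance is
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the moderated t is
#' `log2FC / (s~ sqrt(1/n_A + 1/n_B))` with `d0 + d_g` total degrees of
#' freedom. P-values are two-sided and BH-adjusted across all genes in
#' the contrast; each gene receives a four-way volcano class.
#'
#' @param x an [IntensityExperiment-class] (log2 is applied to its
#'   intensities) or an already log2-transformed matrix.
#' @param factorName `"medium"` or `"donor"`.
#' @param levelA,levelB the two levels to contrast (A minus B).
#' @param samples data.frame of per-sample factors; taken from the
#'   object's annotation when `x` is an `IntensityExperiment`.
#' @param prior `"estimate"` (moment matching, the default), or a list
#'   `list(d0 =, s02 =)`; `d0 = 0` gives the ordinary pooled t and
#'   `d0 = Inf` complete shrinkage to `s02`.
#' @param fcThreshold,alpha volcano thresholds (fold change on the
#'   natural scale, significance on adjusted p).
#' @return a [ContrastResult-class].
#' @examples
#' ie <- simulateExperiment(simConfig(seed = 3, nGenes = 300))
#' res <- fitContrast(ie, "medium", "EBM", "MCDB")
#' head(contrastTable(res))
#' @export
fitContrast <- function(x, factorName, levelA, levelB, samples = NULL,
                        prior = "estimate", fcThreshold = 2, alpha = 0.05) {
    if (is(x, "IntensityExperiment")) {
        samples <- sampleAnnotation(x)
        x <- log2(intensities(x))
    }
    stopifnot(is.matrix(x), !is.null(samples),
              factorName %in% colnames(samples))
    if (levelA == levelB) stop("levelA and levelB must differ")
    fac <- as.character(samples[[factorName]])
    selA <- which(fac == levelA)
    selB <- which(fac == levelB)
    nA <- length(selA); nB <- length(selB)
    if (nA < 2L || nB < 2L)
        stop(sprintf("design error: level '%s' has %d replicate sample(s); >= 2 required",
                     if (nA < 2L) levelA else levelB, min(nA, nB)))
    xA <- x[, selA, drop = FALSE]
    xB <- x[, selB, drop = FALSE]
    mA <- rowMeans(xA); mB <- rowMeans(xB)
    ssA <- rowSums((xA - mA)^2)
    ssB <- rowSums((xB - mB)^2)
    dg <- nA + nB - 2L
    s2 <- (ssA + ssB) / dg

    if (identical(prior, "estimate"))
        prior <- estimateModerationPrior(s2, dg)
    d0 <- prior$d0
    s02 <- if (is.null(prior$s02)) NA_real_ else as.numeric(prior$s02)
    if (is.null(d0) || d0 < 0) stop("prior d0 must be >= 0 (or Inf)")
    s2mod <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + dg * s2) / (d0 + dg)
    fc <- mA - mB
    se <- sqrt(s2mod * (1 / nA + 1 / nB))
    tstat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
    dfTotal <- d0 + dg
    p <- 2 * pt(-abs(tstat), df = dfTotal)
    adjP <- adjustBH(p)
    cls <- classifyVolcano(fc, adjP, fcThreshold, alpha)
    tab <- data.frame(gene = rownames(x), log2FC = fc, meanA = mA,
                      meanB = mB, s2 = s2, df = dg, s2Moderated = s2mod,
                      t = tstat, dfTotal = dfTotal, p = p, adjP = adjP,
                      class = cls, row.names = rownames(x))
    new("ContrastResult", table = tab, factorName = factorName,
        levelA = as.character(levelA), levelB = as.character(levelB),
        d0 = d0, s02 = s02,
        fcThreshold = fcThreshold, alpha = alpha)
}

#' Four-way volcano classification
#'
#' `red`: |log2FC| >= log2(fcThreshold) and adjusted p < alpha;
#' `green`: fold-change condition only; `blue`: significance only;
#' `grey`: neither. The boundary `adjP == alpha` falls on the
#' non-significant side; the fold-change boundary is inclusive.
#'
#' @param log2FC numeric vector of log2 fold changes.
#' @param adjP matching vector of adjusted p-values.
#' @param fcThreshold fold-change threshold on the natural scale
#'   (default 2).
#' @param alpha significance level on adjusted p (default 0.05).
#' @return character vector of classes.
#' @export
classifyVolcano <- function(log2FC, adjP, fcThreshold = 2, alpha = 0.05) {
    bigFC <- abs(log2FC) >= log2(fcThreshold)
    sig <- adjP < alpha
    ifelse(bigFC & sig, "red",
           ifelse(bigFC, "green", ifelse(sig, "blue", "grey")))
}

#' Fit all pairwise contrasts for one or both factors
#'
#' Enumerates every unordered pair of levels of the requested factor(s)
#' and fits each with [fitContrast()].
#'
#' @param x an [IntensityExperiment-class].
#' @param factorName `"medium"`, `"donor"` or `"both"`.
#' @param ... passed to [fitContrast()].
#' @return named list of [ContrastResult-class] objects
#'   (`"<A>_vs_<B>"`).
#' @export
allContrasts <- function(x, factorName = "both", ...) {
    stopifnot(is(x, "IntensityExperiment"))
    facs <- if (factorName == "both") c("medium", "donor") else factorName
    out <- list()
    samples <- sampleAnnotation(x)
    for (f in facs) {
        levels <- unique(as.character(samples[[f]]))
        pairs <- utils::combn(levels, 2L)
        for (j in seq_len(ncol(pairs))) {
            nm <- paste0(pairs[1L, j], "_vs_", pairs[2L, j])
            out[[nm]] <- fitContrast(x, f, pairs[1L, j], pairs[2L, j], ...)
        }
    }
    out
}

.redGenes <- function(cr) cr@table$gene[cr@table$class == "red"]

.checkComplete <- function(contrasts, factorName) {
    sel <- Filter(function(cr) cr@factorName == factorName, contrasts)
    if (!length(sel)) return(sel)
    levels <- unique(unlist(lapply(sel, function(cr) c(cr@levelA, cr@levelB))))
    need <- choose(length(levels), 2L)
    if (length(sel) != need)
        stop(sprintf("incomplete contrast set for '%s': %d of %d pairs fitted",
                     factorName, length(sel), need))
    sel
}

#' Collect differentially expressed gene sets across contrasts
#'
#' The media DE set is the union, over all pairwise media contrasts, of
#' red-class genes (at least `fcThreshold`-fold change at adjusted
#' p < alpha); the line (donor) set likewise over donor contrasts; the
#' combined set is their union.
#'
#' @param contrasts list of [ContrastResult-class] objects covering all
#'   pairs of each factor present.
#' @return list with `mediaSet`, `lineSet`, `combinedSet` (character
#'   vectors, sorted) and `counts` (named sizes).
#' @export
collectDeSets <- function(contrasts) {
    media <- .checkComplete(contrasts, "medium")
    lines <- .checkComplete(contrasts, "donor")
    mediaSet <- sort(unique(unlist(lapply(media, .redGenes))))
    lineSet <- sort(unique(unlist(lapply(lines, .redGenes))))
    combined <- sort(union(mediaSet, lineSet))
    list(mediaSet = mediaSet, lineSet = lineSet, combinedSet = combined,
         counts = c(media = length(mediaSet), lines = length(lineSet),
                    combined = length(combined)))
}

#' Mean and SD of red-gene counts per pairwise comparison
#'
#' Enables a direct media-versus-donor comparison despite the unequal
#' number of pairwise comparisons: the arithmetic mean and sample SD
#' (n - 1 denominator) of the per-contrast red-gene counts.
#'
#' @param contrasts list of [ContrastResult-class] objects, or a numeric
#'   vector of per-contrast counts.
#' @param factorName factor to summarize when `contrasts` is a list.
#' @return list with `mean`, `sd` and the per-contrast `counts`.
#' @export
pairwiseSummary <- function(contrasts, factorName = NULL) {
    counts <- if (is.numeric(contrasts)) contrasts
    else {
        sel <- Filter(function(cr) cr@factorName == factorName, contrasts)
        vapply(sel, function(cr) length(.redGenes(cr)), numeric(1))
    }
    if (length(counts) < 2L)
        stop("insufficient data: >= 2 contrasts required")
    list(mean = mean(counts), sd = sd(counts), counts = counts)
}

#' Top fold-change subset of the significantly altered genes
#'
#' For each contrast of the factor, takes the `ceiling(fraction * n_c)`
#' red-class genes with largest |log2FC| (n_c = that contrast's red
#' count), then returns the union across contrasts. Selection is
#' per-contrast-then-union, not a fraction of the pooled union.
#'
#' @param contrasts list of [ContrastResult-class] objects.
#' @param factorName factor whose contrasts contribute (default: all).
#' @param fraction fraction of each contrast's red genes (default 0.05).
#' @return character vector of gene ids (sorted, unique).
#' @export
topFcSubset <- function(contrasts, factorName = NULL, fraction = 0.05) {
    sel <- if (is.null(factorName)) contrasts
           else Filter(function(cr) cr@factorName == factorName, contrasts)
    picks <- lapply(sel, function(cr) {
        tab <- cr@table[cr@table$class == "red", , drop = FALSE]
        if (!nrow(tab)) return(character())
        n <- ceiling(fraction * nrow(tab))
        tab <- tab[order(-abs(tab$log2FC), tab$adjP, tab$gene), , drop = FALSE]
        tab$gene[seq_len(n)]
    })
    sort(unique(unlist(picks)))
}

#' Top genes per contrast by fold change
#'
#' For each contrast, the `k` red-class genes of largest |log2FC|, with
#' their fold change (magnitude and sign) and adjusted p. Ties are broken
#' by smaller adjusted p, then gene id.
#'
#' @param contrasts list of [ContrastResult-class] objects.
#' @param k genes per contrast (default 3); contrasts with fewer red
#'   genes contribute all of them.
#' @return data.frame with columns `contrast`, `rank`, `gene`, `log2FC`,
#'   `FC` (= 2^|log2FC|), `direction`, `adjP`.
#' @export
topGenesTable <- function(contrasts, k = 3L) {
    rows <- lapply(names(contrasts), function(nm) {
        cr <- contrasts[[nm]]
        tab <- cr@table[cr@table$class == "red", , drop = FALSE]
        if (!nrow(tab)) return(NULL)
        tab <- tab[order(-abs(tab$log2FC), tab$adjP, tab$gene), , drop = FALSE]
        tab <- head(tab, k)
        data.frame(contrast = nm, rank = seq_len(nrow(tab)),
                   gene = tab$gene, log2FC = tab$log2FC,
                   FC = 2^abs(tab$log2FC),
                   direction = ifelse(tab$log2FC >= 0, "up", "down"),
                   adjP = tab$adjP, row.names = NULL)
    })
    do.call(rbind, rows)
}
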