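# Shared fixtures and independent oracles, built in code.

randomIntensityMatrix <- function(nGenes, nSamples, seed = 1) {
    set.seed(seed)
    m <- matrix(2^rnorm(nGenes * nSamples, 8, 2), nGenes, nSamples,
                dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    m
}

smallExperiment <- function(seed = 1, nGenes = 300, ...) {
    simulateExperiment(simConfig(seed = seed, nGenes = nGenes, ...))
}

# brute-force agglomerative clustering with complete linkage;
# returns sorted merge heights
bruteCompleteLinkageHeights <- function(d) {
    D <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(D)))
    heights <- numeric()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            cd <- max(D[clusters[[i]], clusters[[j]]])
            if (cd < bestD) { bestD <- cd; best <- c(i, j) }
        }
        heights <- c(heights, bestD)
        clusters[[best[1L]]] <- c(clusters[[best[1L]]],
                                  clusters[[best[2L]]])
        clusters[[best[2L]]] <- NULL
    }
    sort(heights)
}

# textbook pooled-variance two-sample t per gene
pooledTOracle <- function(xA, xB) {
    nA <- ncol(xA); nB <- ncol(xB)
    t(vapply(seq_len(nrow(xA)), function(g) {
        a <- xA[g, ]; b <- xB[g, ]
        sp2 <- ((nA - 1) * var(a) + (nB - 1) * var(b)) / (nA + nB - 2)
        tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
        c(t = tt, p = 2 * pt(-abs(tt), nA + nB - 2))
    }, numeric(2)))
}

# classic two-sample Kolmogorov-Smirnov statistic between hit and miss
# positions, signed by the direction of the largest deviation
ksEsOracle <- function(N, hitIdx) {
    pos <- seq_len(N)
    Nh <- length(hitIdx)
    walk <- cumsum(ifelse(pos %in% hitIdx, 1 / Nh, -1 / (N - Nh)))
    hi <- max(walk); lo <- min(walk)
    if (hi >= -lo) hi else lo
}
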