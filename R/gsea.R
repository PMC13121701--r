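#' Medium-versus-overall fold-change ranking
#'
#' The preranked-GSEA metric: per gene, the average raw expression over
#' the samples of one medium (across all donor lines) divided by the
#' overall average expression across all samples. Constant genes score
#' exactly 1. The list is sorted descending; ties are broken by gene id.
#'
#' @param x an [IntensityExperiment-class], or an intensity matrix with
#'   `samples` supplied.
#' @param medium the medium level to rank.
#' @param samples data.frame with a `medium` column (only for matrix
#'   input).
#' @return named numeric vector of metrics (names = gene ids), sorted
#'   descending.
#' @export
rankMetric <- function(x, medium, samples = NULL) {
    if (is(x, "IntensityExperiment")) {
        samples <- sampleAnnotation(x)
        x <- intensities(x)
    }
    stopifnot(is.matrix(x), !is.null(samples))
    sel <- which(as.character(samples$medium) == medium)
    if (!length(sel)) stop("unknown medium level: ", medium)
    overall <- rowMeans(x)
    if (any(overall <= 0)) stop("non-positive overall mean expression")
    metric <- rowMeans(x[, sel, drop = FALSE]) / overall
    ord <- order(-metric, rownames(x))
    setNames(metric[ord], rownames(x)[ord])
}

# ES at the walk extremes, given sorted hit positions. `absw` is
# |metric|^weight over the whole list. The walk's positive extreme sits
# just after a hit, the negative extreme just before one; both are
# evaluated in O(Nh).
.esFromHits <- function(absw, hit, N) {
    Nh <- length(hit)
    w <- absw[hit]
    tot <- sum(w)
    Phit <- if (tot > 0) cumsum(w) / tot else seq_len(Nh) / Nh
    missFrac <- (hit - seq_len(Nh)) / (N - Nh)
    after <- Phit - missFrac
    before <- c(0, Phit[-Nh]) - missFrac
    hi <- max(after)
    lo <- min(before)
    if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom: at a set member ("hit") the
#' sum increases by that gene's |metric|^weight divided by the summed hit
#' weights; at a non-member it decreases by 1/(N - Nhit). The enrichment
#' score is the walk's maximum deviation from zero (signed; a tie between
#' the positive and negative extremes resolves positive). With
#' `weight = 0` the score is the classic Kolmogorov-Smirnov statistic
#' between hit and miss positions.
#'
#' @param ranked named numeric vector sorted descending (see
#'   [rankMetric()]).
#' @param set character vector of member gene ids; the intersection with
#'   the ranked list must be non-empty and proper.
#' @param weight exponent on |metric| for hit increments (default 1).
#' @return list with `es` and `running` (the full walk, length N, for
#'   plotting).
#' @examples
#' r <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
#' enrichmentScore(r, "a")$es   #  1
#' enrichmentScore(r, "e")$es   # -1
#' @export
enrichmentScore <- function(ranked, set, weight = 1) {
    N <- length(ranked)
    isHit <- names(ranked) %in% set
    Nh <- sum(isHit)
    if (Nh == 0L) stop("undefined set: no members in the ranked list")
    if (Nh == N) stop("undefined set: set spans the entire ranked list")
    w <- abs(ranked)^weight
    tot <- sum(w[isHit])
    incr <- ifelse(isHit,
                   if (tot > 0) w / tot else 1 / Nh,
                   -1 / (N - Nh))
    if (tot == 0) incr[!isHit] <- -1 / (N - Nh)
    running <- cumsum(incr)
    hi <- max(running); lo <- min(running)
    es <- if (hi >= -lo) hi else lo
    list(es = es, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' For each set: the observed enrichment score on the ranked list; a
#' null distribution of scores from `nperm` gene-label permutations
#' (equivalently, hit positions drawn uniformly without replacement,
#' seeded); the normalized enrichment score NES = ES / mean(|null ES| of
#' matching sign); and the add-one nominal p-value
#' `(1 + #{matching-sign nulls with |null| >= |ES|}) /
#' (1 + #{matching-sign nulls})`, never exactly zero. A per-run
#' Benjamini-Hochberg threshold is computed across the nominal p-values
#' of all tests in the call and `passesFdr` set by `p <= threshold`;
#' when testing several media, pool their results and use
#' [bhThreshold()] across all set x medium tests.
#'
#' Sets with fewer than 10 matching-sign permutations are flagged
#' `unstable`.
#'
#' @param ranked named numeric vector sorted descending.
#' @param sets named list of character vectors.
#' @param weight hit-increment exponent (default 1).
#' @param nperm number of permutations (default 1000, minimum 100).
#' @param seed integer seed for the permutation stream.
#' @param alpha FDR level for the threshold (default 0.05).
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p`,
#'   `nMatchingSign`, `unstable`, `passesFdr`; the permutation count and
#'   seed are attached as attributes.
#' @export
gseaPreranked <- function(ranked, sets, weight = 1, nperm = 1000L,
                          seed = 1L, alpha = 0.05) {
    if (nperm < 100L) stop("nperm must be >= 100")
    if (weight < 0) stop("weight must be >= 0")
    set.seed(seed)
    N <- length(ranked)
    absw <- abs(ranked)^weight
    sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), integer(1))
    nullBySize <- list()
    for (Nh in unique(sizes[sizes > 0L & sizes < N])) {
        nullBySize[[as.character(Nh)]] <- vapply(seq_len(nperm), function(i)
            .esFromHits(absw, sort(sample.int(N, Nh)), N), numeric(1))
    }
    rows <- lapply(names(sets), function(nm) {
        Nh <- sizes[[nm]]
        if (Nh == 0L || Nh == N)
            stop("undefined set '", nm, "': ",
                 if (Nh == 0L) "no members in the ranked list"
                 else "set spans the entire ranked list")
        es <- enrichmentScore(ranked, sets[[nm]], weight)$es
        null <- nullBySize[[as.character(Nh)]]
        match <- null[sign(null) == sign(es) | es == 0]
        nMatch <- length(match)
        nes <- if (nMatch) es / mean(abs(match)) else NA_real_
        p <- (1 + sum(abs(match) >= abs(es))) / (1 + nMatch)
        data.frame(set = nm, size = Nh, es = es, nes = nes, p = p,
                   nMatchingSign = nMatch, unstable = nMatch < 10L,
                   row.names = NULL)
    })
    res <- do.call(rbind, rows)
    thr <- bhThreshold(res$p, alpha)
    res$passesFdr <- res$p <= thr
    attr(res, "nperm") <- nperm
    attr(res, "seed") <- seed
    attr(res, "bhThreshold") <- thr
    res
}

#' Benjamini-Hochberg p-value threshold
#'
#' The largest sorted p_(i) satisfying `p_(i) <= i * alpha / m`, or 0 if
#' none does; tests with `p <= threshold` are significant at FDR level
#' `alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return the threshold p-value.
#' @examples
#' bhThreshold(c(0.01, 0.02, 0.04, 0.5))  # 0.02
#' @export
bhThreshold <- function(p, alpha = 0.05) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] and contain no NA")
    sp <- sort(p)
    m <- length(sp)
    ok <- sp <= seq_len(m) * alpha / m
    if (any(ok)) sp[max(which(ok))] else 0
}
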