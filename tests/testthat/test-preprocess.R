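test_that("selectHousekeeping favours stable candidates and breaks ties lexicographically", {
    m <- matrix(100, 14, 12,
                dimnames = list(sprintf("hk%02d", 1:14),
                                sprintf("s%02d", 1:12)))
    # two candidates vary 10-fold across samples
    m["hk03", ] <- 100 * 10^((seq_len(12) - 1) / 11)
    m["hk11", ] <- 100 * 10^(rev(seq_len(12) - 1) / 11)
    sel <- selectHousekeeping(m, rownames(m), 12)
    expect_setequal(sel, setdiff(rownames(m), c("hk03", "hk11")))

    # all-constant candidates: first 12 ids lexicographically
    m2 <- matrix(50, 14, 12, dimnames = dimnames(m))
    expect_identical(selectHousekeeping(m2, rownames(m2), 12),
                     sort(rownames(m2))[1:12])
})

test_that("selectHousekeeping equals a brute-force log2-SD sort", {
    m <- randomIntensityMatrix(14, 12, seed = 7)
    sel <- selectHousekeeping(m, rownames(m), 12)
    sds <- apply(log2(m), 1, sd)
    oracle <- names(sort(sds))[1:12]
    expect_identical(sel, oracle)
    expect_error(selectHousekeeping(m, c("g0001", "nope"), 2), "nope")
})

test_that("housekeeping normalization removes multiplicative distortion", {
    m <- randomIntensityMatrix(50, 1, seed = 1)
    m <- cbind(A = m[, 1], B = 2 * m[, 1])
    res <- normalizeByHkg(m, rownames(m)[1:10])
    expect_equal(res$matrix[, "A"], res$matrix[, "B"])

    # already-balanced matrix is unchanged, factors all 1
    m3 <- matrix(c(1, 3, 3, 1), 2, 2,
                 dimnames = list(c("h1", "h2"), c("s1", "s2")))
    res3 <- normalizeByHkg(m3, c("h1", "h2"))
    expect_equal(res3$matrix, m3)
    expect_equal(unname(res3$factors), c(1, 1))
})

test_that("after normalization the per-sample HKG mean equals the grand mean, idempotently", {
    m <- randomIntensityMatrix(50, 6, seed = 3)
    hkg <- rownames(m)[1:8]
    res <- normalizeByHkg(m, hkg)
    hm <- colMeans(res$matrix[hkg, ])
    expect_true(all(abs(hm / mean(hm) - 1) < 1e-9))
    twice <- normalizeByHkg(res$matrix, hkg)
    expect_equal(twice$matrix, res$matrix, tolerance = 1e-9)
})

test_that("detectionLimit interpolates between closest ranks", {
    m <- matrix(1:100, 10, 10,
                dimnames = list(paste0("n", 1:10), paste0("s", 1:10)))
    expect_equal(detectionLimit(m, rownames(m), 0.95), 95.05)
    const <- matrix(7, 3, 4, dimnames = list(paste0("n", 1:3),
                                             paste0("s", 1:4)))
    expect_equal(detectionLimit(const, rownames(const), 0.95), 7)
    expect_error(detectionLimit(m, character(0)), "non-empty")
})

test_that("detectionLimit is invariant under sample and gene-order permutation", {
    m <- randomIntensityMatrix(12, 12, seed = 11)
    set.seed(1)
    ref <- detectionLimit(m, rownames(m)[1:5], 0.95)
    perm <- m[, sample(ncol(m))]
    expect_equal(detectionLimit(perm, sample(rownames(m)[1:5]), 0.95), ref)
})

test_that("the three-criterion filter applies strict thresholds", {
    m <- rbind(a = c(11, 11, 11, 11, rep(5, 8)),
               b = c(11, 11, 11, rep(9, 9)),
               c = c(31, rep(1, 11)),
               d = c(21, 21, rep(1, 10)),
               e = c(rep(10, 12)))   # boundary equality fails
    colnames(m) <- paste0("s", 1:12)
    keep <- filterExpressed(m, 10)
    expect_identical(unname(keep), c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("filterExpressed is monotone in the limit", {
    m <- randomIntensityMatrix(500, 12, seed = 5)
    limits <- c(0, 50, 100, 500, 2000)
    kept <- vapply(limits, function(L) sum(filterExpressed(m, L)),
                   numeric(1))
    expect_true(all(diff(kept) <= 0))
})

test_that("sex-gene exclusion removes chrY genes and XIST only", {
    m <- randomIntensityMatrix(3, 4, seed = 2)
    rownames(m) <- c("RPS4Y1", "XIST", "GAPDH")
    gi <- data.frame(symbol = rownames(m),
                     chromosome = c("Y", "X", "12"))
    si <- data.frame(donor = c("d1", "d1", "d2", "d2"),
                     medium = c("A", "B", "A", "B"))
    ie <- IntensityExperiment(m, si, gi)
    expect_identical(rownames(excludeSexGenes(ie)), "GAPDH")
    expect_setequal(rownames(excludeSexGenes(ie, invert = TRUE)),
                    c("RPS4Y1", "XIST"))
    # no sex genes: identity
    ie2 <- IntensityExperiment(m, si,
                               data.frame(symbol = c("A1", "B1", "C1"),
                                          chromosome = c("1", "2", "3")))
    expect_identical(dim(excludeSexGenes(ie2)), dim(ie2))
})

test_that("synthetic sex genes are counted against ground truth", {
    ie <- smallExperiment(seed = 4, nGenes = 300, nYGenes = 10)
    kept <- excludeSexGenes(ie)
    expect_identical(nrow(kept), 300L - 11L)
    expect_setequal(setdiff(rownames(ie), rownames(kept)),
                    names(simTruth(ie)$role)[simTruth(ie)$role %in%
                                                 c("y_linked", "xist")])
})

test_that("preprocess stage counts telescope and both limit conventions are recorded", {
    ie <- smallExperiment(seed = 6, nGenes = 500)
    pp <- preprocess(ie)
    r <- pp$report
    expect_identical(r@nInput - r@nFiltered - r@nSexExcluded, r@nRetained)
    expect_identical(nrow(pp$experiment), r@nRetained)
    expect_identical(length(r@hkgIds), 12L)
    expect_gt(r@detectionLimit, 0)
    expect_gt(r@detectionLimitRaw, 0)
    # filter ran on normalized values: every retained gene passes a criterion
    keep <- filterExpressed(pp$experiment, r@detectionLimit)
    expect_true(all(keep))
})
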