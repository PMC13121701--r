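test_that("adjustBH matches the hand-computed step-up adjustment", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.04, 0.5)),
                 c(0.04, 0.04, 4 * 0.04 / 3, 0.5))
    expect_equal(adjustBH(0.3), 0.3)
    expect_equal(adjustBH(rep(0.2, 5)), rep(0.2, 5))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
    p <- runif(50)
    expect_true(all(adjustBH(p) >= p))
})

test_that("volcano classes follow the four-way threshold rule", {
    expect_identical(classifyVolcano(1.5, 0.01), "red")
    expect_identical(classifyVolcano(0.5, 0.01), "blue")
    expect_identical(classifyVolcano(1.0, 0.05), "green")  # boundary p
    expect_identical(classifyVolcano(0.2, 0.9), "grey")
    # fc boundary is inclusive
    expect_identical(classifyVolcano(log2(2), 0.01), "red")
    expect_identical(classifyVolcano(-3, 0.001), "red")
})

test_that("a group compared against an identical copy gives FC 0 and p 1", {
    m <- randomIntensityMatrix(40, 3, seed = 2)
    lm2 <- log2(cbind(m, m))
    colnames(lm2) <- paste0("s", 1:6)
    samples <- data.frame(medium = rep(c("A", "B"), each = 3),
                          donor = rep(c("d1", "d2", "d3"), 2),
                          row.names = colnames(lm2))
    res <- fitContrast(lm2, "medium", "A", "B", samples = samples,
                       prior = list(d0 = 0, s02 = NA))
    tab <- contrastTable(res)
    expect_true(all(tab$log2FC == 0))
    expect_true(all(tab$p == 1))
})

test_that("with d0 = 0 the statistic equals the textbook pooled two-sample t", {
    set.seed(10)
    lm2 <- matrix(rnorm(60 * 6, 8), 60, 6,
                  dimnames = list(sprintf("g%02d", 1:60),
                                  sprintf("s%d", 1:6)))
    samples <- data.frame(medium = rep(c("A", "B"), each = 3),
                          donor = rep(c("d1", "d2", "d3"), 2),
                          row.names = colnames(lm2))
    res <- contrastTable(fitContrast(lm2, "medium", "A", "B",
                                     samples = samples,
                                     prior = list(d0 = 0, s02 = NA)))
    oracle <- pooledTOracle(lm2[, 1:3], lm2[, 4:6])
    expect_equal(res$t, unname(oracle[, "t"]), tolerance = 1e-10)
    expect_equal(res$p, unname(oracle[, "p"]), tolerance = 1e-10)
    expect_identical(unique(res$dfTotal), 4)
})

test_that("d0 = Inf shrinks every gene-wise variance to s0^2", {
    set.seed(11)
    lm2 <- matrix(rnorm(30 * 6, 8), 30, 6,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  sprintf("s%d", 1:6)))
    samples <- data.frame(medium = rep(c("A", "B"), each = 3),
                          donor = rep(c("d1", "d2", "d3"), 2))
    res <- contrastTable(fitContrast(lm2, "medium", "A", "B",
                                     samples = samples,
                                     prior = list(d0 = Inf, s02 = 0.3)))
    expect_true(all(res$s2Moderated == 0.3))
    expect_identical(unique(res$dfTotal), Inf)
})

test_that("moderation shrinks gene-wise variances monotonically toward s0^2", {
    set.seed(12)
    lm2 <- matrix(rnorm(200 * 6, 8, 1), 200, 6,
                  dimnames = list(sprintf("g%03d", 1:200),
                                  sprintf("s%d", 1:6)))
    samples <- data.frame(medium = rep(c("A", "B"), each = 3),
                          donor = rep(c("d1", "d2", "d3"), 2))
    res <- contrastTable(fitContrast(lm2, "medium", "A", "B",
                                     samples = samples, prior = "estimate"))
    prior <- estimateModerationPrior(res$s2, res$df[1])
    below <- res$s2 < prior$s02
    expect_true(all(res$s2Moderated[below] > res$s2[below]))
    expect_true(all(res$s2Moderated[!below] <= res$s2[!below]))
    # moderated |t| smaller than ordinary |t| iff s2 below the prior
    tOrd <- res$log2FC / sqrt(res$s2 * (2 / 3))
    expect_true(all(abs(res$t[below]) < abs(tOrd[below]) |
                        res$log2FC[below] == 0))
})

test_that("moment-matched prior and moderated t agree with an independent empirical-Bayes fit", {
    skip_if_not_installed("limma")
    set.seed(13)
    lm2 <- matrix(rnorm(500 * 6, 8, 1), 500, 6,
                  dimnames = list(sprintf("g%03d", 1:500),
                                  sprintf("s%d", 1:6)))
    # heteroscedastic genes so the prior is informative but finite
    lm2[1:100, ] <- lm2[1:100, ] * 3
    samples <- data.frame(medium = rep(c("A", "B"), each = 3),
                          donor = rep(c("d1", "d2", "d3"), 2))
    res <- contrastTable(fitContrast(lm2, "medium", "A", "B",
                                     samples = samples, prior = "estimate"))
    design <- stats::model.matrix(~ 0 + factor(samples$medium))
    colnames(design) <- c("A", "B")
    fit <- limma::lmFit(lm2, design)
    fit <- limma::contrasts.fit(
        fit, limma::makeContrasts(A - B, levels = design))
    fit <- limma::eBayes(fit)
    expect_equal(unname(res$t), unname(fit$t[, 1]), tolerance = 1e-6)
    expect_equal(unname(res$p), unname(fit$p.value[, 1]), tolerance = 1e-6)
    prior <- estimateModerationPrior(res$s2, res$df[1])
    expect_equal(prior$d0, fit$df.prior, tolerance = 1e-4)
    expect_equal(prior$s02, fit$s2.prior, tolerance = 1e-4)
})

test_that("swapping the contrast levels negates fold changes and preserves inference", {
    ie <- smallExperiment(seed = 14, nGenes = 250, sigmaMedium = 1)
    a <- contrastTable(fitContrast(ie, "medium", "EBM", "MCDB"))
    b <- contrastTable(fitContrast(ie, "medium", "MCDB", "EBM"))
    expect_equal(a$log2FC, -b$log2FC)
    expect_equal(a$p, b$p)
    expect_identical(a$class, b$class)
})

test_that("contrasts with fewer than two replicates per level are rejected", {
    m <- randomIntensityMatrix(20, 3, seed = 3)
    samples <- data.frame(medium = c("A", "A", "B"),
                          donor = c("d1", "d2", "d1"))
    expect_error(fitContrast(log2(m), "medium", "A", "B",
                             samples = samples),
                 "design error")
})

test_that("DE sets are unions of red genes and respect the union bound", {
    ie <- smallExperiment(seed = 15, nGenes = 400, sigmaMedium = 1.5,
                          sigmaDonor = 1)
    contrasts <- allContrasts(ie)
    sets <- collectDeSets(contrasts)
    redMedia <- unique(unlist(lapply(
        Filter(function(cr) cr@factorName == "medium", contrasts),
        function(cr) contrastTable(cr)$gene[contrastTable(cr)$class == "red"])))
    expect_setequal(sets$mediaSet, redMedia)
    expect_lte(length(sets$combinedSet),
               length(sets$mediaSet) + length(sets$lineSet))
    expect_setequal(sets$combinedSet, union(sets$mediaSet, sets$lineSet))
    # order invariance
    expect_identical(collectDeSets(rev(contrasts))$counts, sets$counts)
    # completeness check
    expect_error(collectDeSets(contrasts[-1]), "incomplete")
})

test_that("pairwiseSummary computes mean and sample SD of red counts", {
    expect_equal(pairwiseSummary(c(2, 4))[c("mean", "sd")],
                 list(mean = 3, sd = sqrt(2)))
    expect_equal(pairwiseSummary(c(5, 5, 5))$sd, 0)
    s <- pairwiseSummary(c(100, 200, 600))
    expect_equal(s$mean, 300)
    expect_equal(s$sd, sd(c(100, 200, 600)))
    expect_error(pairwiseSummary(7), "insufficient")
})

test_that("top fold-change subsets are selected per contrast, then unioned", {
    mkContrast <- function(genes, fc, adjP, factorName = "medium",
                           A = "X", B = "Y") {
        tab <- data.frame(gene = genes, log2FC = fc, meanA = 0, meanB = 0,
                          s2 = 1, df = 4, s2Moderated = 1, t = 0,
                          dfTotal = 4, p = adjP, adjP = adjP,
                          class = classifyVolcano(fc, adjP))
        new("ContrastResult", table = tab, factorName = factorName,
            levelA = A, levelB = B, d0 = 0, s02 = 1, fcThreshold = 2,
            alpha = 0.05)
    }
    genes <- sprintf("g%03d", 1:100)
    one <- mkContrast(genes, fc = seq(1, 6, length.out = 100),
                      adjP = rep(0.01, 100))
    top <- topFcSubset(list(one), fraction = 0.05)
    expect_identical(length(top), 5L)
    expect_setequal(top, genes[96:100])
    # shared top gene appears once in the union
    two <- mkContrast(genes[96:100], fc = 6, adjP = 0.01, A = "X", B = "Z")
    expect_setequal(topFcSubset(list(one, two), fraction = 0.05),
                    genes[96:100])

    tg <- topGenesTable(list(c1 = mkContrast(c("a", "b"), c(3, 4),
                                             c(0.01, 0.01))), k = 3)
    expect_identical(nrow(tg), 2L)           # truncation to available reds
    expect_identical(tg$gene[1], "b")        # largest |log2FC| first
    tied <- mkContrast(c("b", "a", "c"), fc = 3, adjP = c(0.03, 0.01, 0.01))
    expect_identical(topGenesTable(list(x = tied), k = 3)$gene,
                     c("a", "c", "b"))       # adjP then gene id
})

test_that("sex-linked genes flag the male-female contrasts in the quality-control analysis", {
    ie <- smallExperiment(seed = 16, nGenes = 400, nYGenes = 10,
                          sigmaMedium = 0, sigmaDonor = 0)
    qc <- contrastTable(fitContrast(ie, "donor", "D1302", "D1309"))
    sexGenes <- names(simTruth(ie)$role)[simTruth(ie)$role %in%
                                             c("y_linked", "xist")]
    expect_true(all(qc[sexGenes, "class"] == "red"))
    ff <- contrastTable(fitContrast(ie, "donor", "D1309", "D1314"))
    expect_true(all(ff[sexGenes, "class"] != "red"))
})
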