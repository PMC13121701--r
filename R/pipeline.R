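#' Run the full variance-attribution pipeline
#'
#' Orchestrates the fixed stage order simulate/load -> preprocess ->
#' differential expression -> structure -> GSEA on one configuration and
#' returns a machine-readable report. Rerunning with the same
#' configuration and seed reproduces all outputs.
#'
#' The configuration is a named list (or path to a YAML file with the
#' same fields):
#' \describe{
#'   \item{seed}{global seed; every random draw descends from it.}
#'   \item{simulate}{list of [simConfig()] arguments to generate the
#'     input; omit it to read real data instead.}
#'   \item{matrix, samples, genes}{TSV paths for real input (see
#'     [readExperiment()]).}
#'   \item{hkgK, percentile}{pre-processing settings (defaults 12,
#'     0.95).}
#'   \item{fcThreshold, alpha, topFraction}{DE settings (defaults 2,
#'     0.05, 0.05).}
#'   \item{gmt}{optional GMT path for GSEA and ORA; omit to skip those
#'     stages.}
#'   \item{gseaWeight, nperm}{GSEA settings (defaults 1, 1000).}
#'   \item{stages}{named logical toggles: `preprocess`, `de`,
#'     `structure`, `gsea`, `ora` (all default TRUE where their inputs
#'     exist); with everything off the report is a config echo.}
#'   \item{outDir}{optional output directory; stage outputs (normalized
#'     matrix, per-contrast tables, DE sets, Newick dendrogram, GSEA
#'     table, report JSON) are written there as TSV/JSON text.}
#' }
#'
#' @param config named list or YAML path.
#' @return the report, a nested list (also written as `report.json` when
#'   `outDir` is set): stage gene counts, DE-set sizes, pairwise
#'   summaries, purity by factor, PCA variance fractions, the GSEA
#'   table, config echo and seed.
#' @examples
#' rep <- runAll(list(seed = 11,
#'                    simulate = list(nGenes = 400, sigmaMedium = 2)))
#' rep$structure$purityByMedium
#' @export
runAll <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    defaults <- list(seed = 1L, hkgK = 12L, percentile = 0.95,
                     fcThreshold = 2, alpha = 0.05, topFraction = 0.05,
                     gseaWeight = 1, nperm = 1000L)
    config <- utils::modifyList(defaults, config)
    stages <- utils::modifyList(
        list(preprocess = TRUE, de = TRUE, structure = TRUE,
             gsea = TRUE, ora = TRUE),
        if (is.null(config$stages)) list() else config$stages)
    report <- list(package = "medivar",
                   version = as.character(utils::packageVersion("medivar")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "stages")])
    outDir <- config$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    emit <- function(df, name) {
        if (!is.null(outDir))
            write.table(df, file.path(outDir, name), sep = "\t",
                        quote = FALSE, row.names = FALSE)
    }
    set.seed(config$seed)

    ie <- NULL
    if (!is.null(config$simulate)) {
        simArgs <- utils::modifyList(list(seed = config$seed),
                                     config$simulate)
        ie <- simulateExperiment(do.call(simConfig, simArgs))
        report$input <- list(source = "simulated", nGenes = nrow(ie),
                             nSamples = ncol(ie))
    } else if (!is.null(config$matrix)) {
        ie <- readExperiment(config$matrix, config$samples, config$genes)
        report$input <- list(source = config$matrix, nGenes = nrow(ie),
                             nSamples = ncol(ie))
    }
    if (is.null(ie)) return(report)

    if (stages$preprocess) {
        pp <- tryCatch(preprocess(ie, hkgK = config$hkgK,
                                  percentile = config$percentile),
                       error = function(e)
                           stop("stage 'preprocess' failed: ",
                                conditionMessage(e)))
        ie <- pp$experiment
        r <- pp$report
        report$preprocess <- list(
            hkgIds = r@hkgIds, scaleFactors = as.list(r@scaleFactors),
            detectionLimit = r@detectionLimit,
            detectionLimitRaw = r@detectionLimitRaw,
            criterionCounts = r@criterionCounts,
            nInput = r@nInput, nFiltered = r@nFiltered,
            nSexExcluded = r@nSexExcluded, nRetained = r@nRetained)
        if (!is.null(outDir))
            writeIntensityMatrix(ie, file.path(outDir, "normalized_matrix.tsv"))
    }

    samples <- sampleAnnotation(ie)
    media <- unique(as.character(samples$medium))
    donors <- unique(as.character(samples$donor))
    contrasts <- NULL
    deSets <- NULL
    if (stages$de) {
        contrasts <- tryCatch(
            allContrasts(ie, "both", fcThreshold = config$fcThreshold,
                         alpha = config$alpha),
            error = function(e) stop("stage 'de' failed: ",
                                     conditionMessage(e)))
        deSets <- collectDeSets(contrasts)
        mediaSum <- pairwiseSummary(contrasts, "medium")
        donorSum <- pairwiseSummary(contrasts, "donor")
        report$de <- list(
            deSetSizes = as.list(deSets$counts),
            perContrastRed = lapply(contrasts,
                                    function(cr) length(.redGenes(cr))),
            mediaMeanRed = mediaSum$mean, mediaSdRed = mediaSum$sd,
            donorMeanRed = donorSum$mean, donorSdRed = donorSum$sd,
            topFcMedia = topFcSubset(contrasts, "medium",
                                     config$topFraction),
            topFcDonor = topFcSubset(contrasts, "donor",
                                     config$topFraction))
        for (nm in names(contrasts))
            emit(contrastTable(contrasts[[nm]]),
                 paste0("contrast_", nm, ".tsv"))
        emit(data.frame(gene = deSets$combinedSet,
                        inMediaSet = deSets$combinedSet %in% deSets$mediaSet,
                        inLineSet = deSets$combinedSet %in% deSets$lineSet),
             "de_sets.tsv")
        tg <- topGenesTable(contrasts)
        if (!is.null(tg)) emit(tg, "top_genes.tsv")
    }

    if (stages$structure) {
        z <- zscoreLog(ie)
        hc <- clusterSamples(z)
        report$structure <- list(
            purityByMedium = groupingPurity(hc, samples$medium,
                                            length(media)),
            purityByDonor = groupingPurity(hc, samples$donor,
                                           length(donors)))
        if (!is.null(outDir))
            dendrogramNewick(hc, file.path(outDir, "gwca_dendrogram.nwk"))
        if (!is.null(deSets) && length(deSets$combinedSet) >= 2L) {
            sub <- deSets$combinedSet
            sp <- spearmanMatrix(intensities(ie)[sub, , drop = FALSE])
            pca <- pcaSamples(z[sub, , drop = FALSE])
            report$structure$pcaR2 <- pca$r2
            report$structure$pcaCumulativeR2 <- sum(pca$r2)
            emit(data.frame(sample = rownames(sp), sp,
                            check.names = FALSE), "spearman_de_subset.tsv")
            emit(data.frame(sample = rownames(pca$scores), pca$scores,
                            check.names = FALSE), "pca_scores.tsv")
        }
    }

    if ((stages$gsea || stages$ora) && !is.null(config$gmt)) {
        sets <- if (is.character(config$gmt)) readGmt(config$gmt)
                else config$gmt
        if (stages$gsea) {
            gseaAll <- lapply(seq_along(media), function(i) {
                ranked <- rankMetric(ie, media[i])
                res <- gseaPreranked(ranked, sets,
                                     weight = config$gseaWeight,
                                     nperm = config$nperm,
                                     seed = config$seed + i,
                                     alpha = config$alpha)
                res$medium <- media[i]
                res
            })
            gsea <- do.call(rbind, gseaAll)
            thr <- bhThreshold(gsea$p, config$alpha)
            gsea$passesFdr <- gsea$p <= thr
            report$gsea <- list(bhThreshold = thr,
                                nTests = nrow(gsea),
                                nSignificant = sum(gsea$passesFdr),
                                table = gsea)
            emit(gsea, "gsea_results.tsv")
        }
        if (stages$ora && !is.null(deSets) &&
            length(deSets$combinedSet)) {
            background <- rownames(ie)
            oraMedia <- ora(intersect(deSets$mediaSet, background),
                            background, sets)
            report$ora <- list(
                media = oraMedia,
                categories = as.list(categorizeTerms(oraMedia,
                                                     alpha = config$alpha)))
            emit(oraMedia, "ora_media.tsv")
        }
    }

    if (!is.null(outDir))
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE,
                             pretty = TRUE)
    report
}
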