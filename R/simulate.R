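#' Configuration for the two-factor intensity simulator
#'
#' Builds and validates the parameter set for [simulateExperiment()]. The
#' defaults emulate the study design the package targets: three donor
#' lines (one male, two female) each cultured in four media, one array per
#' donor x medium cell, log-normal baselines, 14 housekeeping candidates,
#' 12 negative-control probes sitting at the fluorescence floor, ten
#' Y-linked genes and XIST. Residual log2 noise defaults to 0.25, the
#' scale implied by a median technical coefficient of variation of ~18%.
#'
#' Per-gene effects are drawn from centered normals per factor level and
#' re-centered across levels, so "fold change versus the overall average"
#' is well defined; only a configurable fraction of genes receives
#' non-zero effects.
#'
#' @param seed integer seed; the same config yields bit-identical output.
#' @param nGenes total number of genes (including control probes).
#' @param donors named character vector: names are donor labels, values
#'   their sex (`"male"` or `"female"`).
#' @param media character vector of medium labels.
#' @param sigmaMedium,sigmaDonor log2-scale SD of per-gene medium and
#'   donor effects (for affected genes).
#' @param sigmaNoise log2-scale residual SD.
#' @param baselineMean,baselineSd log2-scale distribution of gene
#'   baselines.
#' @param nHkg number of housekeeping candidate genes.
#' @param nNegative number of negative-control genes.
#' @param floorLevel intensity near which negative controls (and
#'   sex-silenced genes) sit; must be >= 1.
#' @param fracAffectedMedium,fracAffectedDonor fraction of ordinary genes
#'   receiving non-zero medium / donor effects.
#' @param nYGenes number of Y-linked genes (floored in female donors);
#'   one XIST gene (floored in male donors) is always included.
#' @param replicates arrays per donor x medium cell (default 1, the
#'   single-replicate design).
#' @param spike optional list `list(n=, medium=, log2fc=)` adding a fixed
#'   log2 effect to `n` otherwise-unaffected ordinary genes in one medium
#'   (a positive-control construction for recovery experiments).
#'
#' @return a validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 500)
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 2000L,
                      donors = c(D1302 = "male", D1309 = "female",
                                 D1314 = "female"),
                      media = c("EBM", "HIMV", "MCDB", "MCDB_S"),
                      sigmaMedium = 0.5,
                      sigmaDonor = 0.25,
                      sigmaNoise = 0.25,
                      baselineMean = 8,
                      baselineSd = 2,
                      nHkg = 14L,
                      nNegative = 12L,
                      floorLevel = 10,
                      fracAffectedMedium = 0.2,
                      fracAffectedDonor = 0.1,
                      nYGenes = 10L,
                      replicates = 1L,
                      spike = NULL) {
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                donors = donors, media = as.character(media),
                sigmaMedium = sigmaMedium, sigmaDonor = sigmaDonor,
                sigmaNoise = sigmaNoise, baselineMean = baselineMean,
                baselineSd = baselineSd, nHkg = as.integer(nHkg),
                nNegative = as.integer(nNegative), floorLevel = floorLevel,
                fracAffectedMedium = fracAffectedMedium,
                fracAffectedDonor = fracAffectedDonor,
                nYGenes = as.integer(nYGenes),
                replicates = as.integer(replicates), spike = spike)
    sds <- c(sigmaMedium = sigmaMedium, sigmaDonor = sigmaDonor,
             sigmaNoise = sigmaNoise, baselineSd = baselineSd)
    bad <- names(sds)[sds < 0]
    if (length(bad))
        stop("invalid SimConfig: ", bad[1L], " must be >= 0")
    fr <- c(fracAffectedMedium = fracAffectedMedium,
            fracAffectedDonor = fracAffectedDonor)
    bad <- names(fr)[fr < 0 | fr > 1]
    if (length(bad))
        stop("invalid SimConfig: ", bad[1L], " must lie in [0, 1]")
    if (cfg$nHkg + cfg$nNegative + cfg$nYGenes + 1L > cfg$nGenes)
        stop("invalid SimConfig: nHkg + nNegative + nYGenes + 1 (XIST) ",
             "must not exceed nGenes")
    if (is.null(names(donors)) || !all(donors %in% c("male", "female")))
        stop("invalid SimConfig: donors must be a named vector with values ",
             "'male'/'female'")
    if (floorLevel < 1)
        stop("invalid SimConfig: floorLevel must be >= 1")
    if (cfg$replicates < 1L)
        stop("invalid SimConfig: replicates must be >= 1")
    if (!is.null(spike)) {
        if (!all(c("n", "medium", "log2fc") %in% names(spike)) ||
            !spike$medium %in% media)
            stop("invalid SimConfig: spike needs n, medium (a known level) ",
                 "and log2fc")
    }
    structure(cfg, class = "SimConfig")
}

#' Simulate a two-factor microarray-like experiment with known truth
#'
#' Generates an [IntensityExperiment-class] in which the log2 intensity of
#' an ordinary gene g in sample (donor d, medium m) is
#' `baseline_g + mediumEffect_{g,m} + donorEffect_{g,d} + noise`.
#' Housekeeping candidates carry no effects and reduced noise;
#' negative controls fluctuate multiplicatively around `floorLevel`
#' (log2 SD 0.1); Y-linked genes sit at the floor in female-donor samples
#' and XIST at the floor in male-donor samples. Intensities are
#' `2^log2value`, clipped below at 1 so logs stay finite.
#'
#' The ground truth (per-gene effect vectors, differential-expression
#' labels per factor, and the control-gene role) is attached as
#' `simTruth(x)`.
#'
#' @param config a [simConfig()] object.
#' @return an [IntensityExperiment-class]; `simTruth()` on it returns a
#'   list with elements `role`, `baseline`, `mediumEffects` (genes x
#'   media), `donorEffects` (genes x donors), `deMedium`, `deDonor`,
#'   and the generating `config`.
#' @examples
#' ie <- simulateExperiment(simConfig(seed = 7, nGenes = 300))
#' table(simTruth(ie)$role)
#' @export
simulateExperiment <- function(config) {
    if (!inherits(config, "SimConfig"))
        config <- do.call(simConfig, as.list(config))
    set.seed(config$seed)
    nG <- config$nGenes
    media <- config$media
    donors <- names(config$donors)
    sex <- config$donors
    nOrd <- nG - config$nHkg - config$nNegative - config$nYGenes - 1L

    role <- c(rep("ordinary", nOrd),
              rep("housekeeping", config$nHkg),
              rep("negative", config$nNegative),
              rep("y_linked", config$nYGenes),
              "xist")
    geneId <- c(sprintf("G%05d", seq_len(nOrd)),
                sprintf("HKG%02d", seq_len(config$nHkg)),
                sprintf("NEG%02d", seq_len(config$nNegative)),
                sprintf("YG%02d", seq_len(config$nYGenes)),
                "XIST")
    chromosome <- c(sample(as.character(1:22), nOrd + config$nHkg +
                               config$nNegative, replace = TRUE),
                    rep("Y", config$nYGenes), "X")

    # sample layout: media outer, donors inner, replicates innermost
    grid <- expand.grid(replicate = seq_len(config$replicates),
                        donor = donors, medium = media,
                        stringsAsFactors = FALSE)
    sampleId <- paste(grid$medium, grid$donor, sep = "_")
    if (config$replicates > 1L)
        sampleId <- paste0(sampleId, "_r", grid$replicate)
    nS <- nrow(grid)

    baseline <- rnorm(nG, config$baselineMean, config$baselineSd)
    mediumEffects <- matrix(0, nG, length(media),
                            dimnames = list(geneId, media))
    donorEffects <- matrix(0, nG, length(donors),
                           dimnames = list(geneId, donors))
    ordIdx <- which(role == "ordinary")
    affM <- sort(sample(ordIdx, round(config$fracAffectedMedium * nOrd)))
    affD <- sort(sample(ordIdx, round(config$fracAffectedDonor * nOrd)))
    if (length(affM) && config$sigmaMedium > 0) {
        e <- matrix(rnorm(length(affM) * length(media), 0,
                          config$sigmaMedium), length(affM))
        mediumEffects[affM, ] <- e - rowMeans(e)
    }
    if (length(affD) && config$sigmaDonor > 0) {
        e <- matrix(rnorm(length(affD) * length(donors), 0,
                          config$sigmaDonor), length(affD))
        donorEffects[affD, ] <- e - rowMeans(e)
    }
    if (!is.null(config$spike)) {
        free <- setdiff(ordIdx, c(affM, affD))
        if (length(free) < config$spike$n)
            stop("not enough unaffected ordinary genes to spike")
        sp <- sort(sample(free, config$spike$n))
        mediumEffects[sp, config$spike$medium] <-
            mediumEffects[sp, config$spike$medium] + config$spike$log2fc
    }
    deMedium <- rowSums(mediumEffects != 0) > 0
    deDonor <- rowSums(donorEffects != 0) > 0

    logm <- matrix(0, nG, nS, dimnames = list(geneId, sampleId))
    hkgNoise <- 0.2 * config$sigmaNoise
    floorLog <- log2(config$floorLevel)
    for (j in seq_len(nS)) {
        m <- grid$medium[j]; d <- grid$donor[j]
        v <- baseline + mediumEffects[, m] + donorEffects[, d] +
            rnorm(nG, 0, config$sigmaNoise)
        hk <- role == "housekeeping"
        v[hk] <- baseline[hk] + rnorm(sum(hk), 0, hkgNoise)
        ng <- role == "negative"
        v[ng] <- floorLog + rnorm(sum(ng), 0, 0.1)
        yl <- role == "y_linked"
        xi <- role == "xist"
        if (sex[[d]] == "female")
            v[yl] <- floorLog + rnorm(sum(yl), 0, 0.1)
        else
            v[xi] <- floorLog + rnorm(sum(xi), 0, 0.1)
        logm[, j] <- v
    }
    intensity <- pmax(2^logm, 1.0)

    sampleInfo <- data.frame(donor = grid$donor, medium = grid$medium,
                             sex = unname(sex[grid$donor]),
                             row.names = sampleId)
    geneInfo <- data.frame(symbol = geneId, chromosome = chromosome,
                           hkg_candidate = role == "housekeeping",
                           negative_control = role == "negative",
                           role = role, row.names = geneId)
    ie <- IntensityExperiment(intensity, sampleInfo, geneInfo)
    metadata(ie)$simTruth <- list(role = setNames(role, geneId),
                                  baseline = setNames(baseline, geneId),
                                  mediumEffects = mediumEffects,
                                  donorEffects = donorEffects,
                                  deMedium = setNames(deMedium, geneId),
                                  deDonor = setNames(deDonor, geneId),
                                  config = config)
    ie
}
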