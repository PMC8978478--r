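## End-to-end orchestration: simulate -> reference/z-maps -> clusters ->
## tracts -> polygenic score -> association suites, with a manifest
## recording every parameter, seed and output digest.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: a 100-subject demo cohort on
#' a 32^3 grid of 2 mm voxels, subject noise SD 0.02 FA units, mask
#' threshold 0.2, cluster threshold |z| > 2 at 26-connectivity, the
#' 25/50/100/200 mm^3 volume ladder, plurality tract assignment, P_T =
#' 0.01 score threshold, and a score-linked molehill rate of
#' lambda0 = 3 with slope `prsEffect` per SD of score (sized so the score
#' explains roughly 0.8% of count variance at the baseline rate).
#'
#' @param ... Named overrides of any default.
#' @return A configuration list.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        nSubjects = 100L,
        gridShape = c(32L, 32L, 32L),
        voxelSize = c(2, 2, 2),
        noiseSD = 0.02,
        faThreshold = 0.2,
        zThreshold = 2,
        connectivity = 26,
        volumeThresholds = c(25, 50, 100, 200),
        rule = "plurality",
        atlas = "toy",
        nVariants = 200L,
        mafRange = c(0.05, 0.5),
        pThreshold = 0.01,
        excludeIds = character(),
        excludeRegions = NULL,
        lambda0 = 3,
        prsEffect = 0.16,
        bgPotholeRate = 3,
        bgMolehillRate = 3,
        sizeRange = c(4L, 28L),
        magnitude = 6,
        plantPolarity = "molehill",
        tractSuite = TRUE,
        tractPolarity = "molehill",
        tractThreshold = 25,
        seed = 1L)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown configuration field(s): ",
             paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

#' Load a pipeline configuration from YAML
#'
#' Unknown fields are rejected so typos surface as errors, not silent
#' defaults.
#'
#' @param path YAML file with any subset of [pipelineConfig()] fields.
#' @return A configuration list.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    do.call(pipelineConfig, raw)
}

.stageSeed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Run the full pothole/molehill pipeline
#'
#' Executes, in dependency order: cohort simulation (genotypes,
#' covariates, polygenic score, score-linked planted molehills, FA
#' volumes), reference mean/SD and z-maps, cluster detection and the
#' global count profile, tract assignment, and the association suites
#' (8-test genetic, 16-test descriptive, and optionally the 17-test tract
#' suite). Every stage's outputs are written under `outDir`, and
#' `manifest.yaml` records all parameters, the seed, and an md5 digest of
#' every output file. Reruns with an identical configuration and seed
#' produce byte-identical tables.
#'
#' @param config Configuration list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(nSubjects = 20,
#'                                   gridShape = c(16, 16, 16)),
#'                    outDir = tempfile("run"))
#' res$globalPRS
#' }
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = NULL) {
    if (!is.null(seed))
        config$seed <- as.integer(seed)
    if (identical(config$atlas, "none") || is.null(config$atlas)) {
        if (isTRUE(config$tractSuite))
            stop("tract suite requested but no atlas configured")
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(outDir, paste0(...))

    ## -- simulate ------------------------------------------------------
    template <- faTemplate(config$gridShape, config$voxelSize)
    geno <- simulateGenotypes(config$nSubjects, config$nVariants,
                              config$mafRange,
                              seed = .stageSeed(config$seed, 11L))
    covs <- simulateCovariates(config$nSubjects,
                               seed = .stageSeed(config$seed, 23L))
    selected <- selectVariants(geno$weights, config$pThreshold,
                               config$excludeIds, config$excludeRegions)
    scores <- computePRS(geno$dosages, selected,
                         pThreshold = config$pThreshold)
    planted <- plantPrsLinkedAnomalies(
        scaledScores(scores), template,
        lambda0 = config$lambda0, b = config$prsEffect,
        sizeRange = config$sizeRange, magnitude = config$magnitude,
        polarity = config$plantPolarity,
        bgPotholeRate = config$bgPotholeRate,
        bgMolehillRate = config$bgMolehillRate,
        connectivity = config$connectivity,
        seed = .stageSeed(config$seed, 37L))
    sim <- simulateCohort(config$nSubjects, template, config$noiseSD,
                          plants = planted$plants,
                          connectivity = config$connectivity,
                          seed = .stageSeed(config$seed, 53L))

    writeFACohort(sim$cohort, p("cohort_fa.nii.gz"))
    if (!identical(config$atlas, "none") && !is.null(config$atlas))
        writeTractAtlas(template$atlas, p("atlas.nii.gz"),
                        p("atlas_labels.tsv"))
    writeTableTSV(cbind(data.frame(subject = rownames(geno$dosages)),
                        as.data.frame(geno$dosages)),
                  p("dosages.tsv"))
    writeTableTSV(geno$weights, p("weights.tsv"))
    writeTableTSV(covs, p("covariates.tsv"))
    writeTableTSV(sim$truth, p("planted_truth.tsv"))
    writeTableTSV(data.frame(subject = names(rawScores(scores)),
                             raw = rawScores(scores),
                             standardized = scaledScores(scores),
                             nVariants = nVariantsUsed(scores)),
                  p("prs_scores.tsv"))

    ## -- reference and z-maps ------------------------------------------
    ref <- computeReference(sim$cohort)
    zmaps <- cohortZMaps(sim$cohort, faThreshold = config$faThreshold)
    writeReference(ref, p("reference_mean.nii.gz"), p("reference_sd.nii.gz"))
    writeZMaps(zmaps, p("zmaps.nii.gz"), p("wm_mask.nii.gz"))

    ## -- clusters and counts -------------------------------------------
    clusters <- detectClusters(zmaps, zThreshold = config$zThreshold,
                               connectivity = config$connectivity)
    profile <- clusterCountProfile(clusters, subjectIds(zmaps),
                                   config$volumeThresholds)
    writeTableTSV(clusters, p("clusters.tsv"))
    writeTableTSV(profile, p("count_profile.tsv"))

    ## -- tracts --------------------------------------------------------
    tcounts <- NULL
    if (isTRUE(config$tractSuite) ||
        (!identical(config$atlas, "none") && !is.null(config$atlas))) {
        tcounts <- tractCounts(clusters, template$atlas,
                               subjects = subjectIds(zmaps),
                               thresholds = config$volumeThresholds,
                               rule = config$rule)
        writeTableTSV(tcounts, p("tract_counts.tsv"))
    }

    ## -- associations --------------------------------------------------
    globalPRS <- runGlobalSuite(profile, covs, scores, suite = "prs")
    descriptive <- runGlobalSuite(profile, covs, suite = "descriptive")
    writeTableTSV(globalPRS, p("assoc_global_prs.tsv"))
    writeTableTSV(descriptive, p("assoc_descriptive.tsv"))
    tractAssoc <- NULL
    if (isTRUE(config$tractSuite)) {
        tractAssoc <- runTractSuite(tcounts, covs, scores, template$atlas,
                                    polarity = config$tractPolarity,
                                    thresholdMM3 = config$tractThreshold)
        writeTableTSV(tractAssoc, p("assoc_tract.tsv"))
    }

    ## -- manifest ------------------------------------------------------
    files <- sort(setdiff(list.files(outDir), "manifest.yaml"))
    digests <- as.list(tools::md5sum(file.path(outDir, files)))
    names(digests) <- files
    manifest <- list(
        package = "potholes",
        version = as.character(utils::packageVersion("potholes")),
        parameters = config[setdiff(names(config), "excludeRegions")],
        excludeRegions = if (is.null(config$excludeRegions)) list()
                         else as.list(config$excludeRegions),
        seed = config$seed,
        outputs = digests)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

    invisible(list(config = config, template = template, cohort = sim$cohort,
                   truth = sim$truth, covariates = covs, scores = scores,
                   reference = ref, zmaps = zmaps, clusters = clusters,
                   profile = profile, tractCountTable = tcounts,
                   globalPRS = globalPRS, descriptive = descriptive,
                   tractAssoc = tractAssoc, manifest = manifest,
                   outDir = outDir))
}
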