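## Synthetic cohorts with planted ground truth. The generator emulates the
## study design downstream stages assume: smooth tract-shaped high-FA
## template, independent Gaussian subject noise, contiguous planted
## anomalies of controlled size/polarity/magnitude, genotype dosages with
## GWAS-style weights, covariates, and a latent-score-linked anomaly rate.

.asPlantMatrix <- function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "integer"
    v
}

## grow a random connected voxel set of the requested size inside
## `eligible`; uses the current RNG stream
.randomConnectedRegion <- function(eligible, size, connectivity = 26,
                                   maxTries = 25L) {
    stopifnot(size >= 1L)
    off <- .neighborOffsets(connectivity)
    dm <- dim(eligible)
    ## seed only inside connected components large enough to host the
    ## plant; growth over all current neighbors then cannot stall
    comp <- labelComponents(eligible, connectivity)
    big <- as.integer(names(which(table(comp[comp > 0L]) >= size)))
    cand <- which(array(comp %in% big, dm))
    if (length(cand) < size)
        stop("no eligible connected region can host a plant of size ", size)
    for (try in seq_len(maxTries)) {
        seed <- cand[sample.int(length(cand), 1L)]
        cur <- arrayInd(seed, dm)
        taken <- seed
        while (nrow(cur) < size) {
            nb <- cur[rep(seq_len(nrow(cur)), each = nrow(off)), ,
                      drop = FALSE] +
                  off[rep(seq_len(nrow(off)), nrow(cur)), , drop = FALSE]
            ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
                  nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
                  nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
            nb <- nb[ok, , drop = FALSE]
            lin <- nb[, 1L] + (nb[, 2L] - 1L) * dm[1L] +
                (nb[, 3L] - 1L) * dm[1L] * dm[2L]
            keep <- eligible[lin] & !(lin %in% taken)
            if (!any(keep)) break
            lin <- unique(lin[keep])
            pick <- lin[sample.int(length(lin), 1L)]
            taken <- c(taken, pick)
            cur <- rbind(cur, arrayInd(pick, dm))
        }
        if (nrow(cur) == size)
            return(.asPlantMatrix(unname(cur)))
    }
    stop("could not grow a connected region of size ", size,
         " inside the eligible mask")
}

#' Build planted anomalies at random eligible locations
#'
#' For each requested plant, grows a random contiguous voxel set of the
#' given size inside the template's FA > 0.2 region, never overlapping an
#' earlier plant of the same subject.
#'
#' @param subjects Integer subject indices, one per plant (repeats allowed).
#' @param sizes Voxel counts, one per plant.
#' @param template Output of [faTemplate()].
#' @param polarity `"pothole"` or `"molehill"`, recycled over plants.
#' @param magnitude Anomaly shift in units of the subject noise SD
#'   (recycled). The expected planted-voxel z is approximately
#'   `+/- magnitude`.
#' @param connectivity Adjacency defining contiguity (default 26).
#' @param seed RNG seed.
#' @return A plant table: `subject` (index), `polarity`, `magnitude` and a
#'   `voxels` list-column of integer coordinate matrices.
#' @examples
#' tmpl <- faTemplate(c(16, 16, 16))
#' randomPlants(c(1, 1, 2), c(4, 7, 13), tmpl, seed = 3)
#' @export
randomPlants <- function(subjects, sizes, template,
                         polarity = "pothole", magnitude = 6,
                         connectivity = 26, seed = 1L) {
    stopifnot(length(subjects) == length(sizes))
    n <- length(subjects)
    polarity <- rep_len(polarity, n)
    magnitude <- rep_len(magnitude, n)
    withr::local_seed(seed)
    eligibleBase <- template$fa > 0.2
    used <- vector("list", 0L)
    voxels <- vector("list", n)
    for (i in seq_len(n)) {
        s <- as.character(subjects[i])
        eligible <- eligibleBase
        if (!is.null(used[[s]]))
            eligible[used[[s]]] <- FALSE
        v <- .randomConnectedRegion(eligible, sizes[i], connectivity)
        lin <- v[, 1L] + (v[, 2L] - 1L) * dim(eligible)[1L] +
            (v[, 3L] - 1L) * dim(eligible)[1L] * dim(eligible)[2L]
        used[[s]] <- c(used[[s]], lin)
        voxels[[i]] <- v
    }
    data.frame(subject = as.integer(subjects), polarity = polarity,
               magnitude = magnitude, voxels = I(voxels),
               stringsAsFactors = FALSE)
}

.validatePlants <- function(plants, template, nSubjects, connectivity) {
    if (is.null(plants) || nrow(plants) == 0L)
        return(invisible(NULL))
    dm <- dim(template$fa)
    eligible <- template$fa > 0.2
    if (!any(eligible))
        stop("template has no voxels with FA above 0.2; nothing to plant in")
    for (i in seq_len(nrow(plants))) {
        v <- .asPlantMatrix(plants$voxels[[i]])
        s <- plants$subject[i]
        if (s < 1L || s > nSubjects)
            stop("plant ", i, " targets subject ", s,
                 " outside the cohort (n = ", nSubjects, ")")
        if (any(v < 1L) || any(v[, 1L] > dm[1L]) || any(v[, 2L] > dm[2L]) ||
            any(v[, 3L] > dm[3L]))
            stop("plant ", i, " has voxels outside the grid")
        lin <- v[, 1L] + (v[, 2L] - 1L) * dm[1L] +
            (v[, 3L] - 1L) * dm[1L] * dm[2L]
        if (!all(eligible[lin]))
            stop("plant ", i, " extends outside the template FA > 0.2 region")
        m <- array(FALSE, dm)
        m[lin] <- TRUE
        if (max(labelComponents(m, connectivity)) != 1L)
            stop("plant ", i, " is not contiguous under ", connectivity,
                 "-connectivity")
    }
    bySubj <- split(seq_len(nrow(plants)), plants$subject)
    for (sname in names(bySubj)) {
        idx <- bySubj[[sname]]
        if (length(idx) < 2L) next
        lins <- lapply(idx, function(i) {
            v <- .asPlantMatrix(plants$voxels[[i]])
            v[, 1L] + (v[, 2L] - 1L) * dm[1L] +
                (v[, 3L] - 1L) * dm[1L] * dm[2L]
        })
        if (anyDuplicated(unlist(lins))) {
            pairs <- utils::combn(seq_along(idx), 2L)
            bad <- apply(pairs, 2L, function(p)
                length(intersect(lins[[p[1L]]], lins[[p[2L]]])) > 0L)
            off <- pairs[, bad, drop = FALSE]
            stop("overlapping plants for subject ", sname,
                 ": plant pairs ",
                 paste(apply(off, 2L, function(p)
                     paste(idx[p], collapse = "&")), collapse = ", "))
        }
    }
    invisible(NULL)
}

#' Simulate a cohort of FA volumes with planted anomalies
#'
#' Each subject volume is the template plus independent voxel-wise Gaussian
#' noise of SD `noiseSD`, clipped to \[0, 1\]. Planted voxels are
#' additionally shifted by `magnitude * noiseSD` (negative for potholes,
#' positive for molehills) before clipping. Identical `(spec, seed)` yields
#' bit-identical output.
#'
#' @param nSubjects Cohort size (>= 2).
#' @param template Output of [faTemplate()].
#' @param noiseSD Subject-level voxel noise SD in FA units (> 0).
#' @param plants Optional plant table from [randomPlants()] (columns
#'   `subject`, `polarity`, `magnitude`, `voxels`).
#' @param connectivity Adjacency used to validate plant contiguity.
#' @param seed RNG seed.
#' @return A list: `cohort` (an [FACohort-class]), `truth` (one row per
#'   plant: subject id and index, polarity, voxel count, volume in mm^3,
#'   magnitude), `template`.
#' @examples
#' sim <- simulateCohort(6, template = faTemplate(c(16, 16, 16)), seed = 1)
#' sim$cohort
#' @export
simulateCohort <- function(nSubjects, template = faTemplate(),
                           noiseSD = 0.02, plants = NULL,
                           connectivity = 26, seed = 1L) {
    stopifnot(nSubjects >= 2L, noiseSD > 0)
    .validatePlants(plants, template, nSubjects, connectivity)
    dm <- dim(template$fa)
    withr::local_seed(seed)
    data <- array(NA_real_, c(dm, nSubjects))
    for (i in seq_len(nSubjects))
        data[, , , i] <- template$fa + stats::rnorm(prod(dm), 0, noiseSD)
    if (!is.null(plants) && nrow(plants) > 0L) {
        for (i in seq_len(nrow(plants))) {
            v <- .asPlantMatrix(plants$voxels[[i]])
            sgn <- if (plants$polarity[i] == "pothole") -1 else 1
            idx <- cbind(v, plants$subject[i])
            data[idx] <- data[idx] + sgn * plants$magnitude[i] * noiseSD
        }
    }
    data[data < 0] <- 0
    data[data > 1] <- 1
    subjects <- sprintf("S%03d", seq_len(nSubjects))
    voxvol <- prod(template$voxelSize)
    truth <- if (is.null(plants) || nrow(plants) == 0L) {
        data.frame(subject = character(), subjectIndex = integer(),
                   polarity = character(), nVoxels = integer(),
                   volumeMM3 = numeric(), magnitude = numeric(),
                   stringsAsFactors = FALSE)
    } else {
        nv <- vapply(plants$voxels, nrow, integer(1L))
        data.frame(subject = subjects[plants$subject],
                   subjectIndex = plants$subject,
                   polarity = plants$polarity, nVoxels = nv,
                   volumeMM3 = nv * voxvol, magnitude = plants$magnitude,
                   stringsAsFactors = FALSE)
    }
    list(cohort = faCohort(data, template$voxelSize, subjects),
         truth = truth, template = template)
}

#' Simulate genotype dosages and GWAS-style weights
#'
#' Dosages are drawn per variant as Binomial(2, MAF) with MAF uniform over
#' `mafRange`; the weights table carries id, chromosome, position, effect
#' size (log-odds scale) and discovery p-value in the conventional
#' `ID CHR BP BETA P` layout. P-values are drawn as `runif(m)^3` so a
#' realistic minority fall below stringent inclusion thresholds.
#'
#' @param nSubjects Number of subjects.
#' @param nVariants Number of variants (>= 1).
#' @param mafRange Minor-allele-frequency interval, within (0, 0.5].
#' @param effectSD SD of the Gaussian effect-size distribution.
#' @param seed RNG seed.
#' @return A list: `dosages` (subjects x variants matrix, dimnames set)
#'   and `weights` (data.frame ID, CHR, BP, BETA, P, MAF).
#' @examples
#' g <- simulateGenotypes(20, nVariants = 10, seed = 2)
#' head(g$weights)
#' @export
simulateGenotypes <- function(nSubjects, nVariants = 200,
                              mafRange = c(0.05, 0.5), effectSD = 0.1,
                              seed = 1L) {
    if (nVariants < 1L)
        stop("nVariants must be at least 1")
    if (length(mafRange) != 2L || mafRange[1L] <= 0 || mafRange[2L] > 0.5 ||
        mafRange[1L] > mafRange[2L])
        stop("mafRange must lie within (0, 0.5]")
    withr::local_seed(seed)
    maf <- stats::runif(nVariants, mafRange[1L], mafRange[2L])
    dos <- matrix(stats::rbinom(nSubjects * nVariants, 2L,
                                rep(maf, each = nSubjects)),
                  nrow = nSubjects)
    ids <- sprintf("rs%06d", seq_len(nVariants))
    dimnames(dos) <- list(sprintf("S%03d", seq_len(nSubjects)), ids)
    weights <- data.frame(
        ID = ids,
        CHR = sample.int(22L, nVariants, replace = TRUE),
        BP = sample.int(250000000L, nVariants, replace = TRUE),
        BETA = stats::rnorm(nVariants, 0, effectSD),
        P = stats::runif(nVariants)^3,
        MAF = maf,
        stringsAsFactors = FALSE)
    list(dosages = dos, weights = weights)
}

#' Simulate the covariate table
#'
#' Age uniform on `ageRange` (years), sex Bernoulli(0.5) coded female = 1
#' / male = 0, ten standard-normal genetic principal components,
#' handedness Bernoulli(0.9) (right = 1), and a low/mid/high maternal
#' education category.
#'
#' @param nSubjects Number of subjects (>= 2).
#' @param ageRange Age interval in years (default 9-12).
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `age`, `sex`, `PC1`..`PC10`,
#'   `handedness`, `maternalEducation`.
#' @export
simulateCovariates <- function(nSubjects, ageRange = c(9, 12), seed = 1L) {
    if (nSubjects < 2L)
        stop("need at least 2 subjects")
    withr::local_seed(seed)
    pcs <- matrix(stats::rnorm(nSubjects * 10L), ncol = 10L)
    colnames(pcs) <- paste0("PC", 1:10)
    out <- data.frame(
        subject = sprintf("S%03d", seq_len(nSubjects)),
        age = stats::runif(nSubjects, ageRange[1L], ageRange[2L]),
        sex = stats::rbinom(nSubjects, 1L, 0.5),
        stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(pcs))
    out$handedness <- stats::rbinom(nSubjects, 1L, 0.9)
    out$maternalEducation <- sample(c("low", "mid", "high"), nSubjects,
                                    replace = TRUE,
                                    prob = c(0.1, 0.4, 0.5))
    out
}

#' Plant score-linked anomalies
#'
#' Draws each subject's anomaly count from Poisson(lambda0 + b * score)
#' — a linear rate link, matching the linear-regression analysis that will
#' estimate it — and places that many contiguous plants uniformly over the
#' template's eligible voxels. Negative rates are truncated to 0 when
#' `truncate` is on; otherwise they are an error.
#'
#' In addition to the score-linked anomalies, an optional background
#' process plants score-independent potholes and molehills at constant
#' Poisson rates, emulating the anomaly load every subject carries
#' regardless of genetic risk; the returned ground-truth counts cover the
#' score-linked plants only.
#'
#' @param scores Standardized per-subject scores (mean 0, SD 1).
#' @param template Output of [faTemplate()].
#' @param lambda0 Baseline anomaly rate (>= 0).
#' @param b Rate change per SD of score.
#' @param sizeRange Inclusive integer range of plant sizes in voxels.
#' @param magnitude Shift in noise-SD units (default 6).
#' @param polarity Planted polarity (default `"molehill"`).
#' @param bgPotholeRate,bgMolehillRate Poisson rates of the
#'   score-independent background plants (default 0: none).
#' @param truncate Truncate negative rates at 0 (default TRUE).
#' @param connectivity Adjacency for contiguity.
#' @param seed RNG seed.
#' @return A list: `plants` (table for [simulateCohort()], score-linked
#'   and background plants combined without overlap) and `counts`
#'   (integer per-subject ground-truth score-linked counts).
#' @examples
#' s <- scale(rnorm(8))[, 1]
#' plantPrsLinkedAnomalies(s, faTemplate(c(16, 16, 16)), lambda0 = 1,
#'                         b = 0.3, seed = 4)$counts
#' @export
plantPrsLinkedAnomalies <- function(scores, template, lambda0 = 3,
                                    b = 0.3, sizeRange = c(4L, 28L),
                                    magnitude = 6, polarity = "molehill",
                                    bgPotholeRate = 0, bgMolehillRate = 0,
                                    truncate = TRUE, connectivity = 26,
                                    seed = 1L) {
    stopifnot(lambda0 >= 0, bgPotholeRate >= 0, bgMolehillRate >= 0,
              length(scores) >= 2L)
    if (abs(mean(scores)) > 1e-6 || abs(stats::sd(scores) - 1) > 1e-6)
        stop("scores must be standardized (mean 0, SD 1)")
    lambda <- lambda0 + b * scores
    if (any(lambda < 0)) {
        if (!truncate)
            stop("negative anomaly rate for ", sum(lambda < 0),
                 " subject(s); enable truncation or reduce |b|")
        lambda <- pmax(lambda, 0)
    }
    n <- length(scores)
    withr::local_seed(seed)
    counts <- stats::rpois(n, lambda)
    bgPot <- stats::rpois(n, bgPotholeRate)
    bgMol <- stats::rpois(n, bgMolehillRate)
    subj <- c(rep(seq_len(n), counts), rep(seq_len(n), bgPot),
              rep(seq_len(n), bgMol))
    pol <- c(rep(polarity, sum(counts)), rep("pothole", sum(bgPot)),
             rep("molehill", sum(bgMol)))
    if (length(subj) == 0L) {
        plants <- data.frame(subject = integer(), polarity = character(),
                             magnitude = numeric(), voxels = I(list()),
                             stringsAsFactors = FALSE)
        return(list(plants = plants, counts = counts))
    }
    sizes <- sample(seq.int(sizeRange[1L], sizeRange[2L]), length(subj),
                    replace = TRUE)
    plants <- randomPlants(subj, sizes, template, polarity = pol,
                           magnitude = magnitude,
                           connectivity = connectivity,
                           seed = sample.int(2^30, 1L))
    list(plants = plants, counts = counts)
}
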