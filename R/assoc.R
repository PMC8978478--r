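## Association suite: OLS models of anomaly counts on sex, age and the
## polygenic score, covariate-adjusted, with delta-R^2 and BH-FDR control
## within each family of tests (16 descriptive, 8 genetic, 17 tract).

#' Fit one covariate-adjusted linear model for a count outcome
#'
#' Ordinary least squares of the count outcome on the exposure plus
#' covariates (counts are modeled on their natural scale, so betas are in
#' count units per exposure unit). Rows with any missing value among the
#' used columns are dropped listwise, and the reduced model for delta-R^2
#' (exposure dropped) is fit on exactly the same rows.
#'
#' @param data data.frame holding outcome, exposure and covariates.
#' @param outcome,exposure Column names; the exposure must be numeric and
#'   non-constant.
#' @param covariates Character vector of covariate column names.
#' @param standardizeOutcome Also scale the outcome to mean 0 / SD 1, the
#'   fully standardized convention (default FALSE: betas in count units).
#' @param family `"gaussian"` (OLS, the default the suites use) or
#'   `"poisson"` (log-link GLM sensitivity analysis; `deltaR2` is then the
#'   deviance-based pseudo-R^2 increment).
#' @return One-row data.frame: `exposure`, `beta`, `se`, `deltaR2`, `p`,
#'   `n`.
#' @examples
#' d <- data.frame(y = 1:10 * 2, x = 1:10)
#' fitLinear(d, "y", "x")
#' @export
fitLinear <- function(data, outcome, exposure, covariates = character(),
                      standardizeOutcome = FALSE,
                      family = c("gaussian", "poisson")) {
    family <- match.arg(family)
    cols <- c(outcome, exposure, covariates)
    missingCols <- setdiff(cols, names(data))
    if (length(missingCols))
        stop("data lacks column(s): ", paste(missingCols, collapse = ", "))
    d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
    if (!is.numeric(d[[exposure]]))
        stop("exposure column '", exposure, "' must be numeric")
    if (length(unique(d[[exposure]])) < 2L)
        stop("exposure column '", exposure, "' is constant")
    if (length(unique(d[[outcome]])) < 2L)
        stop("outcome column '", outcome,
             "' is constant; no variance to model")
    if (standardizeOutcome) {
        if (family == "poisson")
            stop("standardizeOutcome is incompatible with the Poisson family")
        d[[outcome]] <- as.vector(scale(d[[outcome]]))
    }
    fml <- stats::reformulate(c(exposure, covariates), response = outcome)
    redFml <- if (length(covariates))
        stats::reformulate(covariates, response = outcome)
    else stats::reformulate("1", response = outcome)
    if (family == "gaussian") {
        full <- stats::lm(fml, data = d)
        reduced <- stats::lm(redFml, data = d)
    } else {
        full <- stats::glm(fml, data = d, family = stats::poisson())
        reduced <- stats::glm(redFml, data = d, family = stats::poisson())
    }
    if (nrow(d) <= length(stats::coef(full)))
        stop("too few observations (n = ", nrow(d), ") for ",
             length(stats::coef(full)), " parameters")
    if (anyNA(stats::coef(full)))
        stop("rank-deficient design; aliased column(s): ",
             paste(names(stats::coef(full))[is.na(stats::coef(full))],
                   collapse = ", "))
    cf <- summary(full)$coefficients
    if (family == "gaussian") {
        dr2 <- summary(full)$r.squared - summary(reduced)$r.squared
        pcol <- "Pr(>|t|)"
    } else {
        nullDev <- full$null.deviance
        dr2 <- (1 - full$deviance / nullDev) -
            (1 - reduced$deviance / nullDev)
        pcol <- "Pr(>|z|)"
    }
    data.frame(exposure = exposure,
               beta = cf[exposure, "Estimate"],
               se = cf[exposure, "Std. Error"],
               deltaR2 = dr2,
               p = cf[exposure, pcol],
               n = nrow(d),
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1), after validating
#' the inputs lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return q-values, same length and order.
#' @examples
#' fdrBH(c(0.001, 0.02, 0.03, 0.04))
#' @export
fdrBH <- function(p) {
    if (length(p) == 0L)
        return(numeric(0))
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

.countsWide <- function(counts, subjects) {
    key <- paste(counts$polarity, counts$thresholdMM3, sep = "_")
    cells <- unique(data.frame(polarity = counts$polarity,
                               thresholdMM3 = counts$thresholdMM3))
    out <- data.frame(subject = subjects, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cells))) {
        sel <- counts$polarity == cells$polarity[i] &
            counts$thresholdMM3 == cells$thresholdMM3[i]
        v <- counts$count[sel][match(subjects, counts$subject[sel])]
        out[[paste(cells$polarity[i], cells$thresholdMM3[i], sep = "_")]] <- v
    }
    out
}

.scoreVector <- function(scores) {
    if (is(scores, "PolygenicScores")) {
        s <- scaledScores(scores)
        if (is.null(s))
            stop("scores must be standardized for the association suite")
        return(s)
    }
    if (is.numeric(scores) && !is.null(names(scores)))
        return(scores)
    stop("scores must be a PolygenicScores object or a named numeric vector")
}

.intersectSubjects <- function(countSubjects, covSubjects,
                               scoreSubjects = NULL, minOverlap = 0.5) {
    common <- intersect(countSubjects, covSubjects)
    if (!is.null(scoreSubjects))
        common <- intersect(common, scoreSubjects)
    if (length(common) < minOverlap * length(countSubjects))
        stop(sprintf(paste0("subject-id mismatch: only %d of %d count",
                            " subjects found in all inputs"),
                     length(common), length(countSubjects)))
    common
}

#' Global association suite
#'
#' `suite = "prs"` fits the 8 genetic models — the standardized polygenic
#' score against each polarity x volume-threshold global count, adjusted
#' for age, sex and the first 10 genetic principal components — and
#' corrects the 8 p-values jointly by BH-FDR. `suite = "descriptive"`
#' fits the 16 descriptive models (sex and age as exposures, each adjusted
#' for the other) with FDR over all 16. Additional sensitivity covariates
#' (e.g. `"maternalEducation"`) can be appended.
#'
#' @param counts Global count profile ([countProfile()] output).
#' @param covariates Covariate table ([simulateCovariates()] schema).
#' @param scores [PolygenicScores-class] or named standardized vector
#'   (required for the `"prs"` suite).
#' @param suite `"prs"` or `"descriptive"`.
#' @param extraCovariates Extra covariate column names.
#' @param standardizeOutcome Passed to [fitLinear()].
#' @param minOverlap Minimum tolerated fraction of count subjects present
#'   in all inputs before erroring.
#' @return data.frame with one row per test: exposure, polarity,
#'   thresholdMM3, scope, beta, se, deltaR2, p, q, n.
#' @export
runGlobalSuite <- function(counts, covariates, scores = NULL,
                           suite = c("prs", "descriptive"),
                           extraCovariates = character(),
                           standardizeOutcome = FALSE,
                           minOverlap = 0.5) {
    suite <- match.arg(suite)
    subjects <- unique(counts$subject)
    pcs <- paste0("PC", 1:10)
    if (suite == "prs") {
        s <- .scoreVector(scores)
        subjects <- .intersectSubjects(subjects, covariates$subject,
                                       names(s), minOverlap)
    } else {
        subjects <- .intersectSubjects(subjects, covariates$subject,
                                       minOverlap = minOverlap)
    }
    wide <- .countsWide(counts, subjects)
    d <- merge(wide, covariates, by = "subject", sort = FALSE)
    cells <- unique(counts[c("polarity", "thresholdMM3")])
    cells <- cells[order(cells$polarity, cells$thresholdMM3), ]
    fits <- list()
    if (suite == "prs") {
        d$prs <- s[d$subject]
        for (i in seq_len(nrow(cells))) {
            oc <- paste(cells$polarity[i], cells$thresholdMM3[i], sep = "_")
            f <- fitLinear(d, oc, "prs",
                           c("age", "sex", pcs, extraCovariates),
                           standardizeOutcome)
            f$polarity <- cells$polarity[i]
            f$thresholdMM3 <- cells$thresholdMM3[i]
            fits[[length(fits) + 1L]] <- f
        }
    } else {
        for (expo in c("sex", "age")) {
            other <- setdiff(c("sex", "age"), expo)
            for (i in seq_len(nrow(cells))) {
                oc <- paste(cells$polarity[i], cells$thresholdMM3[i],
                            sep = "_")
                f <- fitLinear(d, oc, expo, c(other, extraCovariates),
                               standardizeOutcome)
                f$polarity <- cells$polarity[i]
                f$thresholdMM3 <- cells$thresholdMM3[i]
                fits[[length(fits) + 1L]] <- f
            }
        }
    }
    out <- do.call(rbind, fits)
    out$scope <- "global"
    out$q <- fdrBH(out$p)
    out[c("exposure", "polarity", "thresholdMM3", "scope", "beta", "se",
          "deltaR2", "p", "q", "n")]
}

#' Tract-level association suite
#'
#' One model per atlas tract at a chosen polarity and volume threshold,
#' with the standardized polygenic score as exposure and age, sex and 10
#' principal components as covariates. Tracts flagged left or right in the
#' atlas additionally receive the handedness covariate; midline tracts do
#' not. BH-FDR is applied over all tract p-values (17 for the bundled toy
#' atlas).
#'
#' @param tcounts Tract count table from [tractCounts()].
#' @param covariates Covariate table; must contain `handedness` when the
#'   atlas has lateralized tracts (unless `requireHandedness = FALSE`).
#' @param scores [PolygenicScores-class] or named standardized vector.
#' @param atlas The [TractAtlas-class] the counts were computed against.
#' @param polarity,thresholdMM3 Which count cell to model.
#' @param extraCovariates Extra covariate column names for every model.
#' @param requireHandedness Error when handedness is missing but
#'   lateralized tracts are present (default TRUE).
#' @param standardizeOutcome,minOverlap As in [runGlobalSuite()].
#' @return data.frame with one row per tract: label, tract, laterality,
#'   beta, se, deltaR2, p, q, n.
#' @export
runTractSuite <- function(tcounts, covariates, scores, atlas,
                          polarity = "molehill", thresholdMM3 = 25,
                          extraCovariates = character(),
                          requireHandedness = TRUE,
                          standardizeOutcome = FALSE, minOverlap = 0.5) {
    stopifnot(is(atlas, "TractAtlas"))
    s <- .scoreVector(scores)
    labelIds <- sort(as.integer(names(tractNames(atlas))))
    lat <- tractLaterality(atlas)
    hasLateral <- any(lat %in% c("left", "right"))
    if (hasLateral && !("handedness" %in% names(covariates))) {
        if (requireHandedness)
            stop("atlas has lateralized tracts but covariates lack a ",
                 "'handedness' column (set requireHandedness = FALSE to ",
                 "skip the adjustment)")
    }
    sel <- tcounts$polarity == polarity &
        tcounts$thresholdMM3 == thresholdMM3
    tc <- tcounts[sel, , drop = FALSE]
    subjects <- .intersectSubjects(unique(tc$subject),
                                   covariates$subject, names(s),
                                   minOverlap)
    pcs <- paste0("PC", 1:10)
    fits <- list()
    for (lab in labelIds) {
        cnt <- tc$count[tc$label == lab][
            match(subjects, tc$subject[tc$label == lab])]
        d <- merge(data.frame(subject = subjects, y = cnt,
                              stringsAsFactors = FALSE),
                   covariates, by = "subject", sort = FALSE)
        d$prs <- s[d$subject]
        covs <- c("age", "sex", pcs, extraCovariates)
        if (lat[as.character(lab)] %in% c("left", "right") &&
            "handedness" %in% names(covariates))
            covs <- c(covs, "handedness")
        f <- fitLinear(d, "y", "prs", covs, standardizeOutcome)
        f$label <- lab
        f$tract <- tractNames(atlas)[as.character(lab)]
        f$laterality <- lat[as.character(lab)]
        fits[[length(fits) + 1L]] <- f
    }
    out <- do.call(rbind, fits)
    out$polarity <- polarity
    out$thresholdMM3 <- thresholdMM3
    out$scope <- "tract"
    out$q <- fdrBH(out$p)
    rownames(out) <- NULL
    out[c("label", "tract", "laterality", "polarity", "thresholdMM3",
          "scope", "beta", "se", "deltaR2", "p", "q", "n")]
}
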