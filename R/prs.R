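## Thresholded additive polygenic risk score. The engine assumes weights
## are already LD-pruned and dosages are harmonized to the weights' effect
## allele; it performs p-value thresholding, id/region exclusion, the
## additive dosage x effect sum, and standardization.

.checkWeights <- function(weights) {
    need <- c("ID", "CHR", "BP", "BETA", "P")
    if (!all(need %in% names(weights)))
        stop("weights must have columns ", paste(need, collapse = ", "))
    if (anyDuplicated(weights$ID))
        stop("variant ids must be unique")
    if (any(weights$P <= 0 | weights$P > 1))
        stop("p-values must lie in (0, 1]")
    invisible(weights)
}

#' Conventional extended-MHC exclusion region
#'
#' The major histocompatibility complex interval on chromosome 6 commonly
#' excluded in MS polygenic-score sensitivity analyses. Coordinates
#' (chr6:25-35 Mb) are a widely used convention, configurable wherever a
#' region list is accepted.
#'
#' @return data.frame with columns `CHR`, `start`, `end` (half-open
#'   \[start, end)).
#' @export
mhcRegion <- function() {
    data.frame(CHR = 6L, start = 25000000L, end = 35000000L)
}

#' Select score variants by p-value threshold and exclusions
#'
#' Keeps variants whose discovery p-value is strictly below `pThreshold`
#' (so p equal to the threshold is excluded), whose id is not in
#' `excludeIds`, and whose position falls in no exclusion region (regions
#' are half-open \[start, end) on the region's chromosome).
#'
#' @param weights data.frame with columns `ID`, `CHR`, `BP`, `BETA`, `P`.
#' @param pThreshold Inclusion threshold P_T in (0, 1] (default 0.01).
#' @param excludeIds Character vector of variant ids to drop.
#' @param excludeRegions data.frame (`CHR`, `start`, `end`) or NULL.
#' @return The selected subset of `weights` (possibly 0 rows).
#' @examples
#' w <- data.frame(ID = c("rs1", "rs2"), CHR = c(1, 6),
#'                 BP = c(100, 26e6), BETA = c(0.2, 0.5),
#'                 P = c(0.001, 0.002))
#' selectVariants(w, excludeRegions = mhcRegion())
#' @export
selectVariants <- function(weights, pThreshold = 0.01,
                           excludeIds = character(),
                           excludeRegions = NULL) {
    .checkWeights(weights)
    if (pThreshold <= 0 || pThreshold > 1)
        stop("pThreshold must lie in (0, 1]")
    keep <- weights$P < pThreshold & !(weights$ID %in% excludeIds)
    if (!is.null(excludeRegions) && nrow(excludeRegions) > 0L) {
        if (any(excludeRegions$start >= excludeRegions$end))
            stop("exclusion regions need start < end")
        for (r in seq_len(nrow(excludeRegions))) {
            inR <- weights$CHR == excludeRegions$CHR[r] &
                weights$BP >= excludeRegions$start[r] &
                weights$BP < excludeRegions$end[r]
            keep <- keep & !inR
        }
    }
    out <- weights[keep, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out) == 0L)
        warning("no variants pass the threshold/exclusion filters")
    out
}

#' Compute per-subject polygenic scores
#'
#' Raw score for subject i is `sum_j dosage[i, j] * BETA[j]` over the
#' selected variants; with `standardize = TRUE` (default) the scores are
#' additionally scaled to mean 0, SD 1 across the analyzed subjects, the
#' form entering the regression suite as "scaled beta" exposure.
#'
#' @param dosages Numeric subjects x variants matrix, values in \[0, 2\],
#'   with variant ids as column names and subject ids as row names.
#' @param weights Selected weights (see [selectVariants()]).
#' @param pThreshold Recorded threshold metadata (default 0.01).
#' @param standardize Standardize the scores (default TRUE).
#' @return A [PolygenicScores-class].
#' @examples
#' d <- matrix(c(0, 1, 2), ncol = 1,
#'             dimnames = list(paste0("S", 1:3), "rs1"))
#' w <- data.frame(ID = "rs1", CHR = 1, BP = 1, BETA = 0.5, P = 0.001)
#' rawScores(computePRS(d, w, standardize = FALSE))
#' @export
computePRS <- function(dosages, weights, pThreshold = 0.01,
                       standardize = TRUE) {
    .checkWeights(weights)
    if (is.null(colnames(dosages)))
        stop("dosage matrix must carry variant ids as column names")
    missing <- setdiff(weights$ID, colnames(dosages))
    if (length(missing))
        stop("dosage matrix lacks variant(s): ",
             paste(missing, collapse = ", "))
    if (any(dosages < 0 | dosages > 2))
        stop("dosages must lie in [0, 2]")
    if (is.null(rownames(dosages)))
        rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
    raw <- as.vector(dosages[, weights$ID, drop = FALSE] %*% weights$BETA)
    names(raw) <- rownames(dosages)
    std <- numeric(0)
    if (standardize) {
        s <- stats::sd(raw)
        if (length(raw) < 2L || s == 0)
            stop("raw scores have zero variance; cannot standardize")
        std <- (raw - mean(raw)) / s
        names(std) <- names(raw)
    }
    new("PolygenicScores", raw = raw, standardized = std,
        nVariantsUsed = nrow(weights), pThreshold = pThreshold)
}
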