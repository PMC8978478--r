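## Cohort reference images, white-matter mask and per-subject z-maps.

#' Voxel-wise cohort mean and SD images
#'
#' Computes the voxel-wise mean and sample SD (n - 1 denominator) of FA
#' across all subjects in the cohort. Every subject contributes to the
#' reference, including the subject whose z-map will later be computed
#' against it; see [cohortZMaps()] for the optional leave-one-out variant.
#'
#' @param cohort An [FACohort-class] with at least 2 subjects.
#' @param denominator `"n-1"` (sample SD, default) or `"n"` (population).
#' @return An [FAReference-class].
#' @examples
#' coh <- faCohort(array(runif(4 * 4 * 4 * 5), c(4, 4, 4, 5)))
#' computeReference(coh)
#' @export
computeReference <- function(cohort, denominator = c("n-1", "n")) {
    stopifnot(is(cohort, "FACohort"))
    denominator <- match.arg(denominator)
    n <- nSubjects(cohort)
    if (n < 2L)
        stop("reference SD is undefined for fewer than 2 subjects")
    dm <- gridShape(cohort)
    x <- matrix(cohort@data, ncol = n)
    mu <- rowMeans(x)
    ss <- rowSums((x - mu)^2)
    div <- if (denominator == "n-1") n - 1L else n
    new("FAReference",
        mean = array(mu, dm),
        sd = array(sqrt(ss / div), dm),
        nReference = as.integer(n),
        voxelSize = cohort@voxelSize)
}

#' White-matter analysis mask
#'
#' A voxel enters the mask iff its cohort mean FA strictly exceeds
#' `faThreshold` (default 0.2, the conventional white-matter cutoff for FA)
#' and its SD is strictly positive, so z-values are finite everywhere on
#' the mask.
#'
#' @param reference An [FAReference-class].
#' @param faThreshold Mean-FA cutoff (strict `>`).
#' @return Logical 3D array.
#' @export
wmMask <- function(reference, faThreshold = 0.2) {
    stopifnot(is(reference, "FAReference"))
    reference@mean > faThreshold & reference@sd > 0
}

#' z-transform one FA volume against a reference
#'
#' z = (FA - mean) / SD on the mask; off-mask voxels are `NA`.
#'
#' @param subjectFA 3D FA array on the reference grid.
#' @param reference An [FAReference-class].
#' @param mask Logical mask from [wmMask()]; computed from the reference
#'   when omitted.
#' @param faThreshold Passed to [wmMask()] when `mask` is missing.
#' @return 3D array of z-values, `NA` off mask.
#' @export
zTransform <- function(subjectFA, reference, mask = NULL,
                       faThreshold = 0.2) {
    stopifnot(is(reference, "FAReference"))
    if (!identical(dim(subjectFA), gridShape(reference)))
        stop(sprintf("subject grid %s does not match reference grid %s",
                     paste(dim(subjectFA), collapse = "x"),
                     paste(gridShape(reference), collapse = "x")))
    if (is.null(mask))
        mask <- wmMask(reference, faThreshold)
    z <- array(NA_real_, dim(subjectFA))
    z[mask] <- (subjectFA[mask] - reference@mean[mask]) / reference@sd[mask]
    z
}

#' Per-subject z-maps for a whole cohort
#'
#' Builds the cohort reference, the white-matter mask, and one z-map per
#' subject. With `leaveOneOut = TRUE` each subject's mean/SD reference is
#' recomputed from the other n - 1 subjects (the mask always comes from
#' the full-cohort reference so every subject shares one analysis domain).
#'
#' @param cohort An [FACohort-class].
#' @param faThreshold Mean-FA mask cutoff (strict), default 0.2.
#' @param leaveOneOut Exclude each subject from its own reference.
#' @param denominator SD denominator, see [computeReference()].
#' @return A [ZMapSet-class].
#' @examples
#' sim <- simulateCohort(10, template = faTemplate(c(16, 16, 16)), seed = 7)
#' zs <- cohortZMaps(sim$cohort)
#' zs
#' @export
cohortZMaps <- function(cohort, faThreshold = 0.2, leaveOneOut = FALSE,
                        denominator = c("n-1", "n")) {
    stopifnot(is(cohort, "FACohort"))
    denominator <- match.arg(denominator)
    n <- nSubjects(cohort)
    ref <- computeReference(cohort, denominator)
    mask <- wmMask(ref, faThreshold)
    dm <- gridShape(cohort)
    zarr <- array(NA_real_, c(dm, n))
    if (!leaveOneOut) {
        for (i in seq_len(n))
            zarr[, , , i] <- zTransform(cohort@data[, , , i, drop = TRUE],
                                        ref, mask)
    } else {
        if (n < 3L)
            stop("leave-one-out reference needs at least 3 subjects")
        x <- matrix(cohort@data, ncol = n)
        tot <- rowSums(x)
        totSq <- rowSums(x^2)
        div <- if (denominator == "n-1") n - 2L else n - 1L
        for (i in seq_len(n)) {
            mu <- (tot - x[, i]) / (n - 1L)
            ss <- pmax(totSq - x[, i]^2 - (n - 1L) * mu^2, 0)
            sdv <- sqrt(ss / div)
            zi <- array(NA_real_, dm)
            m <- mask & array(sdv > 0, dm)
            zi[m] <- (cohort@data[, , , i][m] - array(mu, dm)[m]) /
                array(sdv, dm)[m]
            zarr[, , , i] <- zi
        }
        mask <- mask & apply(!is.na(zarr), 1:3, all)
        zarr[array(rep(!mask, n), c(dm, n))] <- NA_real_
    }
    new("ZMapSet", data = zarr, mask = mask, voxelSize = cohort@voxelSize,
        subjects = cohort@subjects)
}
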