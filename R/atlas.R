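## Tract assignment: map each detected cluster onto a labeled atlas.

#' Assign a cluster to tract label(s)
#'
#' Under the default plurality rule the cluster goes to the single label
#' owning the most of its voxels (ties to the lowest label id; zero
#' overlap with any tract gives `NA`, "unassigned"), so each cluster is
#' counted exactly once and tract counts decompose the global count. The
#' `any_overlap` rule instead returns every label overlapped by at least
#' one voxel.
#'
#' @param voxels Integer coordinate matrix (one row per voxel), e.g. an
#'   element of the `voxels` column from [detectClusters()].
#' @param atlas A [TractAtlas-class] on the same grid.
#' @param rule `"plurality"` (default) or `"any_overlap"`.
#' @return Plurality: one integer label or `NA`; any_overlap: a sorted
#'   integer vector of labels (possibly empty).
#' @export
assignCluster <- function(voxels, atlas, rule = c("plurality",
                                                  "any_overlap")) {
    rule <- match.arg(rule)
    stopifnot(is(atlas, "TractAtlas"))
    v <- as.matrix(voxels)
    dm <- gridShape(atlas)
    if (any(v < 1L) || any(v[, 1L] > dm[1L]) || any(v[, 2L] > dm[2L]) ||
        any(v[, 3L] > dm[3L]))
        stop("cluster voxels fall outside the atlas grid ",
             paste(dm, collapse = "x"))
    labs <- atlas@labels[v]
    labs <- labs[labs != 0L]
    if (rule == "any_overlap")
        return(sort(unique(labs)))
    if (length(labs) == 0L)
        return(NA_integer_)
    tab <- table(labs)
    winners <- as.integer(names(tab)[tab == max(tab)])
    min(winners)
}

#' Per-tract pothole/molehill count table
#'
#' Crosses every atlas tract (plus an "unassigned" row) with polarity and
#' the volume-threshold ladder and counts the clusters assigned to each
#' cell. Under the plurality rule the tract counts plus the unassigned
#' count reproduce the global count exactly for every polarity and
#' threshold; under `any_overlap` a cluster can contribute to several
#' tracts.
#'
#' @param clusters Cluster table from [detectClusters()].
#' @param atlas A [TractAtlas-class].
#' @param subjects Subject ids to report (zero rows kept).
#' @param thresholds Volume thresholds in mm^3 (strict `>` filter).
#' @param rule Assignment rule, see [assignCluster()].
#' @param inclusive Use `>=` for the volume filter.
#' @return data.frame: `subject`, `label` (0 = unassigned), `tract`,
#'   `laterality`, `polarity`, `thresholdMM3`, `count`.
#' @export
tractCounts <- function(clusters, atlas,
                        subjects = unique(clusters$subject),
                        thresholds = c(25, 50, 100, 200),
                        rule = c("plurality", "any_overlap"),
                        inclusive = FALSE) {
    rule <- match.arg(rule)
    stopifnot(is(atlas, "TractAtlas"))
    labelIds <- as.integer(names(atlas@tractNames))
    assigned <- lapply(clusters$voxels, assignCluster, atlas = atlas,
                       rule = rule)
    if (length(subjects) == 0L)
        subjects <- character(0)
    grid <- expand.grid(subject = subjects,
                        label = c(labelIds, 0L),
                        polarity = c("pothole", "molehill"),
                        thresholdMM3 = thresholds,
                        stringsAsFactors = FALSE)
    cmp <- if (inclusive) `>=` else `>`
    hits <- function(s, lab, pol, thr) {
        sel <- clusters$subject == s & clusters$polarity == pol &
            cmp(clusters$volumeMM3, thr)
        if (!any(sel)) return(0L)
        a <- assigned[sel]
        if (rule == "plurality") {
            a <- unlist(a)
            if (lab == 0L) sum(is.na(a)) else sum(!is.na(a) & a == lab)
        } else {
            if (lab == 0L) sum(vapply(a, length, 1L) == 0L)
            else sum(vapply(a, function(x) lab %in% x, logical(1L)))
        }
    }
    grid$count <- as.integer(mapply(hits, grid$subject, grid$label,
                                    grid$polarity, grid$thresholdMM3))
    grid$tract <- ifelse(grid$label == 0L, "unassigned",
                         atlas@tractNames[as.character(grid$label)])
    grid$laterality <- ifelse(grid$label == 0L, "none",
                              atlas@laterality[as.character(grid$label)])
    grid <- grid[order(match(grid$subject, subjects), grid$label,
                       grid$polarity, grid$thresholdMM3),
                 c("subject", "label", "tract", "laterality", "polarity",
                   "thresholdMM3", "count")]
    rownames(grid) <- NULL
    grid
}
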