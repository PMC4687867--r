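# Exome coverage-pattern CNV: reference model, GC correction, log2 ratios.
#
# A pool of germline reference exomes defines, for every 120 bp capture
# interval, the expected (median) RPKM and its variance. A tumor sample is
# GC-corrected by aligning per-group coverage density peaks, then compared
# against the reference median as a per-interval log2 ratio, which is
# segmented downstream.

#' Learn the reference coverage model
#'
#' Per-interval median and sample variance (n - 1 denominator) of RPKM
#' across a pool of germline reference profiles. Intervals whose median is
#' below `min_median` RPKM in the pool, or zero in at least half the
#' references, are masked.
#'
#' @param reference_profiles list of >= 2 coverage profiles on an identical
#'   interval grid (data frames with `chrom`, `start`, `end`, `rpkm`).
#' @param min_median mask threshold on the median RPKM.
#' @return object of class `ref_coverage_model`: the interval grid plus
#'   `median`, `variance`, `mask` (TRUE = usable) and `n_references`.
#' @export
learn_reference_model <- function(reference_profiles, min_median = 1) {
    if (length(reference_profiles) < 2)
        stop("at least 2 reference profiles are required (variance undefined)")
    grid <- reference_profiles[[1]][, c("chrom", "start", "end")]
    for (p in reference_profiles[-1]) {
        if (!identical(p[, c("chrom", "start", "end")], grid))
            stop("reference profiles are on different interval grids")
    }
    rpkm <- sapply(reference_profiles, function(p) p$rpkm)
    med <- apply(rpkm, 1, median)
    v <- apply(rpkm, 1, var)
    nz <- rowMeans(rpkm > 0)
    mask <- med >= min_median & nz >= 0.5
    structure(list(intervals = grid, median = med, variance = v,
                   mask = mask, n_references = length(reference_profiles)),
              class = "ref_coverage_model")
}

#' @export
print.ref_coverage_model <- function(x, ...) {
    cat(sprintf("ref_coverage_model: %d intervals (%d usable), %d references\n",
                nrow(x$intervals), sum(x$mask), x$n_references))
    invisible(x)
}

# mode of a coverage distribution via kernel density (Silverman bandwidth)
.density_mode <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(median(x))
    d <- density(x, bw = "nrd0")
    d$x[which.max(d$y)]
}

#' GC-correct a coverage profile
#'
#' Intervals are grouped by GC bin (default width 0.02) and capture-pool
#' copy count; within each group the peak of the coverage kernel density is
#' computed and every interval is scaled by (global peak / group peak), so
#' all group peaks align. Groups smaller than `min_group` intervals are
#' merged into the nearest GC bin with the same pool copy count.
#'
#' @param profile coverage data frame with `gc`, `rpkm` and optionally
#'   `copies_in_pool`.
#' @param bin_width GC bin width.
#' @param min_group minimum intervals per group.
#' @return the profile with corrected `rpkm` (raw values kept as
#'   `rpkm_raw`) and a `correction` attribute (per-group factors).
#' @export
gc_correct <- function(profile, bin_width = 0.02, min_group = 20) {
    stopifnot(all(c("gc", "rpkm") %in% names(profile)))
    pool <- if ("copies_in_pool" %in% names(profile)) profile$copies_in_pool
            else rep(1L, nrow(profile))
    bin <- floor(profile$gc / bin_width)
    # merge undersized groups into the nearest GC bin within the same pool level
    for (pl in unique(pool)) {
        repeat {
            tb <- table(bin[pool == pl])
            small <- names(tb)[tb < min_group]
            if (length(small) == 0 || length(tb) == 1) break
            b <- as.integer(small[1])
            others <- as.integer(setdiff(names(tb), small[1]))
            nearest <- others[which.min(abs(others - b))]
            bin[pool == pl & bin == b] <- nearest
        }
    }
    grp <- paste(pool, bin, sep = "_")
    modes <- tapply(profile$rpkm, grp, .density_mode)
    global_mode <- .density_mode(profile$rpkm[pool == names(sort(table(pool),
                                                                 decreasing = TRUE))[1]])
    factor <- global_mode / modes
    corrected <- profile$rpkm * factor[grp]
    # pool copies > 1 sit at multiples of the haploid peak; after peak
    # alignment they are on the common scale
    out <- profile
    out$rpkm_raw <- profile$rpkm
    out$rpkm <- as.numeric(corrected)
    attr(out, "correction") <- data.frame(group = names(modes),
                                          mode = as.numeric(modes),
                                          factor = as.numeric(factor),
                                          stringsAsFactors = FALSE)
    out
}

#' Per-interval log2 coverage ratio against the reference model
#'
#' `log2((tumor + eps) / (median + eps))` on unmasked intervals. The
#' reference variance is propagated to the log2 scale (delta method) and
#' scaled by the reference/tumor mean-coverage ratio, giving the predicted
#' variance used to weight segmentation.
#'
#' @param tumor_profile coverage data frame (`chrom`, `start`, `end`,
#'   `rpkm`), GC-corrected.
#' @param model a `ref_coverage_model` on the same grid.
#' @param eps stabilizer in RPKM.
#' @return data frame `chrom`, `start`, `end`, `log2r`, `variance` on the
#'   model's unmasked intervals.
#' @export
log2_ratio <- function(tumor_profile, model, eps = 0.1) {
    stopifnot(inherits(model, "ref_coverage_model"))
    if (!identical(tumor_profile[, c("chrom", "start", "end")], model$intervals))
        stop("tumor profile is not on the model's interval grid")
    keep <- model$mask
    if (!any(keep)) stop("all intervals are masked in the reference model")
    t_rpkm <- tumor_profile$rpkm[keep]
    med <- model$median[keep]
    l2r <- log2((t_rpkm + eps) / (med + eps))
    # delta method: var(log2 X) ~ var(X) / (X ln2)^2, scaled for tumor depth
    depth_scale <- mean(med) / max(mean(t_rpkm), eps)
    v <- model$variance[keep] / ((med + eps)^2 * log(2)^2) * depth_scale
    # moderate the per-interval estimates (few references make raw sample
    # variances unstable; shrink toward the genome-wide median)
    df <- model$n_references - 1
    n0 <- 20
    v <- (df * v + n0 * median(v)) / (df + n0)
    v <- pmax(v, 1e-6)
    data.frame(chrom = tumor_profile$chrom[keep],
               start = tumor_profile$start[keep],
               end = tumor_profile$end[keep],
               log2r = l2r, variance = v,
               stringsAsFactors = FALSE)
}
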