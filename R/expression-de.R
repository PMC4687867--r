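# RPKM expression, correlation on log10 RPKM, fold-change DE.

#' RPKM from raw counts
#'
#' `RPKM_{g,s} = 1e9 * c_{g,s} / (L_g * N_s)` with gene exonic length `L_g`
#' in bp and total mapped reads `N_s`.
#'
#' @param counts genes x samples matrix of raw counts.
#' @param lengths per-gene exonic lengths (bp), aligned to the rows.
#' @param totals per-sample total mapped reads, aligned to the columns;
#'   defaults to the column sums.
#' @return RPKM matrix of the same shape.
#' @export
rpkm <- function(counts, lengths, totals = colSums(counts)) {
    counts <- as.matrix(counts)
    stopifnot(length(lengths) == nrow(counts), length(totals) == ncol(counts))
    if (any(lengths <= 0)) stop("gene lengths must be positive")
    if (any(totals <= 0)) stop("library totals must be positive")
    1e9 * sweep(sweep(counts, 1, lengths, "/"), 2, totals, "/")
}

#' Pearson correlation of two expression profiles on log10 RPKM
#'
#' Restricted to genes with positive RPKM in both samples.
#'
#' @param rpkm_a,rpkm_b RPKM vectors on a shared gene universe.
#' @param min_genes minimum shared expressed genes.
#' @return Pearson r, or `NA` with a warning when fewer than `min_genes`
#'   genes are expressed in both.
#' @export
expression_correlation <- function(rpkm_a, rpkm_b, min_genes = 10) {
    stopifnot(length(rpkm_a) == length(rpkm_b))
    keep <- rpkm_a > 0 & rpkm_b > 0 & is.finite(rpkm_a) & is.finite(rpkm_b)
    if (sum(keep) < min_genes) {
        warning("fewer than ", min_genes, " genes expressed in both samples")
        return(NA_real_)
    }
    stats::cor(log10(rpkm_a[keep]), log10(rpkm_b[keep]), method = "pearson")
}

#' Pairwise expression correlation matrix with summary
#'
#' @param rpkm_mat genes x samples RPKM matrix.
#' @param pairs optional two-column matrix/data frame of sample-id pairs to
#'   summarize (e.g. patient vs derived PDXs); defaults to all pairs.
#' @return list with `matrix` (samples x samples Pearson r on log10 RPKM)
#'   and `summary` (min/mean/max over the requested pairs).
#' @export
correlation_matrix <- function(rpkm_mat, pairs = NULL) {
    ids <- colnames(rpkm_mat)
    m <- matrix(NA_real_, ncol(rpkm_mat), ncol(rpkm_mat),
                dimnames = list(ids, ids))
    for (i in seq_along(ids)) {
        for (j in seq_along(ids)) {
            if (j < i) { m[i, j] <- m[j, i]; next }
            m[i, j] <- if (i == j) 1 else
                suppressWarnings(expression_correlation(rpkm_mat[, i], rpkm_mat[, j]))
        }
    }
    if (is.null(pairs)) {
        vals <- m[upper.tri(m)]
    } else {
        pairs <- as.matrix(pairs)
        vals <- m[cbind(match(pairs[, 1], ids), match(pairs[, 2], ids))]
    }
    list(matrix = m,
         summary = c(min = min(vals, na.rm = TRUE),
                     mean = mean(vals, na.rm = TRUE),
                     max = max(vals, na.rm = TRUE)))
}

#' Fold-change differential expression between two samples
#'
#' Genes are up-regulated when `(v2 + f) / (v1 + f) > threshold` and
#' down-regulated when the ratio is below `1 / threshold` (strict
#' inequalities; a ratio of exactly `threshold` is not called).
#'
#' @param rpkm_v1,rpkm_v2 named RPKM vectors on a shared gene universe.
#' @param threshold fold-change threshold (> 1).
#' @param floor pseudo-floor in RPKM units.
#' @return list with `up` and `down` (gene names), `ratio` (named vector)
#'   and `counts`.
#' @export
fold_change_de <- function(rpkm_v1, rpkm_v2, threshold = 2, floor = 0.1) {
    stopifnot(length(rpkm_v1) == length(rpkm_v2), threshold > 1)
    ratio <- (rpkm_v2 + floor) / (rpkm_v1 + floor)
    genes <- names(rpkm_v1) %||% as.character(seq_along(rpkm_v1))
    names(ratio) <- genes
    up <- genes[ratio > threshold]
    down <- genes[ratio < 1 / threshold]
    list(up = up, down = down, ratio = ratio,
         counts = c(n_up = length(up), n_down = length(down)))
}
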