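# Circular binary segmentation of log2 coverage ratios and CNV calling.

# Recursively segment one standardized sequence; returns integer breakpoint
# boundaries (segment end indexes, always including n).
.segment_recurse <- function(x, offset, alpha, nperm) {
    n <- length(x)
    if (n < 4) return(offset + n)
    res <- .cbs_perm_test(x, nperm, alpha)
    if (!res$significant) return(offset + n)
    i <- res$i; j <- res$j
    if (i == 0 && j == n) return(offset + n)
    bounds <- integer(0)
    if (i > 0) bounds <- c(bounds, .segment_recurse(x[seq_len(i)], offset, alpha, nperm))
    bounds <- c(bounds, .segment_recurse(x[(i + 1):j], offset + i, alpha, nperm))
    if (j < n) bounds <- c(bounds, .segment_recurse(x[(j + 1):n], offset + j, alpha, nperm))
    bounds
}

#' Segment a log2-ratio sequence by circular binary segmentation
#'
#' The sequence is standardized by the predicted per-interval variance and a
#' robust global scale, then recursively split: the maximal circular-arc
#' t statistic is tested against a permutation null and accepted breakpoints
#' divide the sequence. Segments shorter than `min_width` are merged into
#' the neighbor with the nearer mean. Operates per chromosome when `chrom`
#' is supplied.
#'
#' @param log2r numeric vector of per-interval log2 ratios, or a data frame
#'   from [log2_ratio()] (columns `chrom`, `start`, `end`, `log2r`,
#'   `variance`).
#' @param variances predicted per-interval variances (ignored for the data
#'   frame input); NULL for equal weights.
#' @param alpha significance level of the permutation test.
#' @param nperm permutations per test.
#' @param min_width minimum segment width in intervals.
#' @param chrom optional chromosome factor parallel to `log2r`.
#' @return data frame of segments: `chrom`, `start_idx`, `end_idx`
#'   (interval indexes, inclusive), `n_intervals`, `log2r`
#'   (inverse-variance-weighted mean), and genomic `start`/`end` when
#'   available.
#' @export
segment_cbs <- function(log2r, variances = NULL, alpha = 0.01, nperm = 1000,
                        min_width = 3, chrom = NULL) {
    coords <- NULL
    if (is.data.frame(log2r)) {
        coords <- log2r
        chrom <- log2r$chrom
        variances <- log2r$variance
        log2r <- log2r$log2r
    }
    n <- length(log2r)
    if (is.null(chrom)) chrom <- rep(".", n)
    if (is.null(variances)) variances <- rep(1, n)
    stopifnot(length(chrom) == n, length(variances) == n, all(variances > 0))

    segs <- list()
    for (cc in unique(chrom)) {
        idx <- which(chrom == cc)
        x <- log2r[idx] / sqrt(variances[idx])
        s <- mad(diff(x)) / sqrt(2)
        if (!is.finite(s) || s <= 0) s <- sd(x)
        if (!is.finite(s) || s <= 0) s <- 1
        x <- x / s
        m <- length(idx)
        if (m < 2 * min_width) {
            bounds <- m
        } else {
            bounds <- sort(unique(.segment_recurse(x, 0L, alpha, nperm)))
        }
        starts <- c(1L, head(bounds, -1) + 1L)
        seg <- data.frame(chrom = cc, start_idx = idx[starts],
                          end_idx = idx[bounds], stringsAsFactors = FALSE)
        seg <- .merge_short_segments(seg, log2r, variances, min_width)
        segs[[cc]] <- seg
    }
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out$n_intervals <- out$end_idx - out$start_idx + 1L
    out$log2r <- vapply(seq_len(nrow(out)), function(i) {
        r <- out$start_idx[i]:out$end_idx[i]
        w <- 1 / variances[r]
        sum(w * log2r[r]) / sum(w)
    }, numeric(1))
    if (!is.null(coords)) {
        out$start <- coords$start[out$start_idx]
        out$end <- coords$end[out$end_idx]
    }
    out
}

.merge_short_segments <- function(seg, log2r, variances, min_width) {
    wmean <- function(r) {
        w <- 1 / variances[r]
        sum(w * log2r[r]) / sum(w)
    }
    repeat {
        widths <- seg$end_idx - seg$start_idx + 1L
        if (nrow(seg) == 1 || all(widths >= min_width)) break
        i <- which.min(ifelse(widths < min_width, widths, Inf))
        mi <- wmean(seg$start_idx[i]:seg$end_idx[i])
        left <- if (i > 1) abs(mi - wmean(seg$start_idx[i - 1]:seg$end_idx[i - 1])) else Inf
        right <- if (i < nrow(seg)) abs(mi - wmean(seg$start_idx[i + 1]:seg$end_idx[i + 1])) else Inf
        if (left <= right) {
            seg$end_idx[i - 1] <- seg$end_idx[i]
        } else {
            seg$start_idx[i + 1] <- seg$start_idx[i]
        }
        seg <- seg[-i, , drop = FALSE]
    }
    seg
}

#' Median-zero normalization and anchor-chromosome re-centering
#'
#' Subtracts the median per-interval segmented value from all segment means
#' (so the genome-wide median log2 ratio is 0). In recenter mode, each
#' sample is additionally shifted so its anchor chromosome (default chr2,
#' assumed copy-neutral) has weighted mean log2 ratio 0, putting samples on
#' a common copy scale.
#'
#' @param segments segment data frame from [segment_cbs()], or a list of
#'   them (one per sample) for recentering.
#' @param recenter_anchor anchor chromosome name, or NULL to skip
#'   re-centering.
#' @return the normalized segment data frame (or list).
#' @export
normalize_and_recenter <- function(segments, recenter_anchor = NULL) {
    norm_one <- function(seg) {
        offset <- median(rep(seg$log2r, seg$n_intervals))
        seg$log2r <- seg$log2r - offset
        if (!is.null(recenter_anchor)) {
            anchor <- seg$chrom == recenter_anchor
            if (!any(anchor)) {
                message("anchor chromosome ", recenter_anchor,
                        " absent; falling back to the global median")
            } else {
                shift <- sum(seg$log2r[anchor] * seg$n_intervals[anchor]) /
                    sum(seg$n_intervals[anchor])
                seg$log2r <- seg$log2r - shift
            }
        }
        seg
    }
    if (is.data.frame(segments)) norm_one(segments) else lapply(segments, norm_one)
}

#' Call amplifications/deletions and annotate genes
#'
#' A segment is called amplified when its mean log2 ratio exceeds
#' `threshold` and deleted when it is below `-threshold` (strict
#' inequalities). A gene is called when any overlapping segment is called.
#'
#' @param segments segment data frame with genomic `start`/`end` columns.
#' @param genes data frame `chrom`, `start`, `end`, `gene` (0-based
#'   half-open, same coordinate system as the segments).
#' @param threshold absolute log2-ratio call threshold.
#' @return list with `segments` (plus `call` column), `gene_calls` (gene,
#'   call) and `counts` (n_amplified, n_deleted genes).
#' @export
call_and_annotate <- function(segments, genes = NULL, threshold = 0.5) {
    segments$call <- ifelse(segments$log2r > threshold, "amplified",
                     ifelse(segments$log2r < -threshold, "deleted", "neutral"))
    gene_calls <- NULL
    counts <- c(n_amplified = 0L, n_deleted = 0L)
    if (!is.null(genes) && nrow(genes) > 0) {
        gr_seg <- GenomicRanges::GRanges(
            segments$chrom,
            IRanges::IRanges(segments$start + 1L, segments$end))
        gr_gene <- GenomicRanges::GRanges(
            genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
        ov <- GenomicRanges::findOverlaps(gr_gene, gr_seg)
        call <- rep("neutral", nrow(genes))
        for (lvl in c("deleted", "amplified")) {
            hit <- unique(S4Vectors::queryHits(ov)[
                segments$call[S4Vectors::subjectHits(ov)] == lvl])
            call[hit] <- lvl
        }
        gene_calls <- data.frame(gene = genes$gene, call = call,
                                 stringsAsFactors = FALSE)
        counts <- c(n_amplified = sum(call == "amplified"),
                    n_deleted = sum(call == "deleted"))
    }
    list(segments = segments, gene_calls = gene_calls, counts = counts)
}
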