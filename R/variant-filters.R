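# Somatic variant filter chains.
#
# Three chains are applied at different points of the analysis:
#  * reporting: what is reported as a somatic mutation (germline-free,
#    exonic, high/moderate impact, absent from 1000 Genomes and ESP);
#  * concordance eligibility: what enters recall/precision and the VAF
#    concordance matrix (high/moderate impact, absent from the 1000 Genomes
#    European and African samples, zero germline reads, and a flanking
#    window that maps uniquely to the reference);
#  * purity eligibility: what enters the subclone/purity model (>= 50X,
#    outside called CNVs, not a dbSNP site, autosomal, at most one germline
#    alt read, unique flanking window).
#
# All chains fail closed: a missing annotation excludes the variant and is
# counted in the exclusion report.

.required_annotations <- c("impact", "exonic", "in_1000g", "in_1000g_eur",
                           "in_1000g_afr", "in_esp", "in_dbsnp",
                           "germline_alt_reads")

.annotation_complete <- function(variants, fields) {
    ok <- rep(TRUE, nrow(variants))
    for (f in fields) {
        if (!f %in% names(variants)) return(rep(FALSE, nrow(variants)))
        ok <- ok & !is.na(variants[[f]])
    }
    ok
}

#' Reporting filter for somatic variants
#'
#' Retains a variant iff it has zero germline alt reads, is exonic, has HIGH
#' or MODERATE impact, and is absent from both the 1000 Genomes project and
#' the Exome Sequencing Project.
#'
#' @param variants variant data frame (see [simulate_variant_table()] for
#'   the column contract).
#' @return the retained rows, with an `exclusions` attribute counting
#'   removals per clause.
#' @export
reporting_filter <- function(variants) {
    complete <- .annotation_complete(
        variants, c("impact", "exonic", "in_1000g", "in_esp", "germline_alt_reads"))
    germline_free <- complete & variants$germline_alt_reads == 0
    exonic <- complete & variants$exonic
    impact_ok <- complete & variants$impact %in% c("HIGH", "MODERATE")
    db_free <- complete & !variants$in_1000g & !variants$in_esp
    keep <- germline_free & exonic & impact_ok & db_free
    excl <- c(incomplete_annotation = sum(!complete),
              germline_reads = sum(complete & !germline_free),
              non_exonic = sum(complete & !exonic),
              low_modifier_impact = sum(complete & !impact_ok),
              population_database = sum(complete & !db_free))
    structure(variants[keep, , drop = FALSE], exclusions = excl)
}

#' Does the flanking window around a variant map uniquely?
#'
#' Extracts the `window`-bp sequence centered on the variant position and
#' scans the whole reference (both strands) by ungapped sliding comparison,
#' counting loci whose matching fraction reaches `identity_threshold`. The
#' window is unique iff exactly one locus (the site itself) attains the
#' threshold. Windows truncated at a chromosome end are compared at their
#' truncated length and flagged via attribute `truncated`.
#'
#' @param chrom,pos variant locus (1-based).
#' @param reference named character vector, `DNAStringSet` or FASTA path.
#' @param window window size in bp; odd so the variant is centered.
#' @param identity_threshold minimum matching fraction for a hit.
#' @return logical flag.
#' @export
window_maps_uniquely <- function(chrom, pos, reference, window = 101,
                                 identity_threshold = 0.90) {
    stopifnot(window %% 2 == 1)
    ref <- .as_sequences(reference)
    if (!chrom %in% names(ref)) stop("chromosome ", chrom, " not in reference")
    L <- nchar(ref[[chrom]])
    if (pos < 1 || pos > L) stop("position outside reference bounds")
    half <- (window - 1) / 2
    lo <- max(1, pos - half)
    hi <- min(L, pos + half)
    truncated <- (hi - lo + 1) < window
    win <- substring(ref[[chrom]], lo, hi)
    wlen <- nchar(win)
    max_mm <- wlen - ceiling(identity_threshold * wlen)
    pat <- Biostrings::DNAString(win)
    subjects <- Biostrings::DNAStringSet(ref)
    hits <- 0L
    for (i in seq_along(subjects)) {
        hits <- hits + Biostrings::countPattern(pat, subjects[[i]],
                                                max.mismatch = max_mm)
        hits <- hits + Biostrings::countPattern(Biostrings::reverseComplement(pat),
                                                subjects[[i]], max.mismatch = max_mm)
        if (hits > 1L) break
    }
    structure(hits == 1L, truncated = truncated)
}

#' Concordance-eligibility filter
#'
#' Variant keys eligible for recall/precision and VAF concordance: HIGH or
#' MODERATE impact, absent from the 1000 Genomes European and African
#' samples, zero germline alt reads, and a uniquely mapping flanking window.
#' Eligibility is decided once per variant identity key, over the union of
#' samples in which it was called.
#'
#' @param variants variant data frame (possibly multiple samples per key).
#' @param reference reference sequences for the uniqueness check.
#' @param window,identity_threshold passed to [window_maps_uniquely()].
#' @return character vector of eligible keys, with an `exclusions`
#'   attribute.
#' @export
concordance_eligibility <- function(variants, reference, window = 101,
                                    identity_threshold = 0.90) {
    keys <- variant_key(variants)
    first <- !duplicated(keys)
    v <- variants[first, , drop = FALSE]
    k <- keys[first]
    complete <- .annotation_complete(
        v, c("impact", "in_1000g_eur", "in_1000g_afr", "germline_alt_reads"))
    impact_ok <- complete & v$impact %in% c("HIGH", "MODERATE")
    db_free <- complete & !v$in_1000g_eur & !v$in_1000g_afr
    germline_free <- complete & v$germline_alt_reads == 0
    cand <- impact_ok & db_free & germline_free
    ref <- .as_sequences(reference)
    unique_ok <- rep(FALSE, nrow(v))
    out_of_bounds <- rep(FALSE, nrow(v))
    for (i in which(cand)) {
        if (!v$chrom[i] %in% names(ref) ||
            v$pos[i] < 1 || v$pos[i] > nchar(ref[[v$chrom[i]]])) {
            out_of_bounds[i] <- TRUE
            next
        }
        unique_ok[i] <- window_maps_uniquely(v$chrom[i], v$pos[i], ref,
                                             window, identity_threshold)
    }
    keep <- cand & unique_ok
    excl <- c(incomplete_annotation = sum(!complete),
              impact = sum(complete & !impact_ok),
              population_database = sum(complete & !db_free),
              germline_reads = sum(complete & !germline_free),
              out_of_bounds = sum(out_of_bounds),
              non_unique_window = sum(cand & !out_of_bounds & !unique_ok))
    structure(k[keep], exclusions = excl)
}

#' Purity-eligibility filter
#'
#' Variants admitted to the subclone/purity model: depth >= 50 in every
#' sample of interest, no overlap with a called CNV segment
#' (`|Log2R| >= 0.5`), not a dbSNP site, not on chrM or chrX, at most one
#' germline alt read, and a uniquely mapping flanking window. A variant not
#' covered by any segment is treated as copy-neutral (logged).
#'
#' @param variants variant data frame.
#' @param segments CNV segment data frame (`chrom`, `start`, `end`,
#'   `log2r`), 0-based half-open, or NULL for no CNV information.
#' @param reference reference sequences for the uniqueness check; NULL skips
#'   the check (logged).
#' @param min_depth minimum per-sample depth.
#' @param window,identity_threshold passed to [window_maps_uniquely()].
#' @return retained rows, with an `exclusions` attribute.
#' @export
purity_eligibility <- function(variants, segments = NULL, reference = NULL,
                               min_depth = 50, window = 101,
                               identity_threshold = 0.90) {
    keys <- variant_key(variants)
    depth <- variants$alt_reads + variants$ref_reads
    # depth is per-row (per sample); a key is eligible only if every row
    # passes, so aggregate the minimum per key
    min_depth_by_key <- tapply(depth, keys, min)
    depth_ok <- min_depth_by_key[keys] >= min_depth

    complete <- .annotation_complete(variants, c("in_dbsnp", "germline_alt_reads"))
    dbsnp_ok <- complete & !variants$in_dbsnp
    chrom_ok <- !(variants$chrom %in% c("chrM", "chrX", "M", "X"))
    germline_ok <- complete & variants$germline_alt_reads <= 1

    cnv_ok <- rep(TRUE, nrow(variants))
    uncovered <- 0L
    if (!is.null(segments) && nrow(segments) > 0) {
        called <- segments[abs(segments$log2r) >= 0.5, , drop = FALSE]
        covered <- rep(FALSE, nrow(variants))
        for (j in seq_len(nrow(segments))) {
            sg <- segments[j, ]
            covered <- covered | (variants$chrom == sg$chrom &
                                  variants$pos > sg$start &
                                  variants$pos <= sg$end)
        }
        uncovered <- sum(!covered)
        if (uncovered > 0)
            message(uncovered, " variant row(s) not covered by any segment; ",
                    "treated as copy-neutral")
        if (nrow(called) > 0) {
            for (j in seq_len(nrow(called))) {
                sg <- called[j, ]
                hit <- variants$chrom == sg$chrom &
                    variants$pos > sg$start & variants$pos <= sg$end
                cnv_ok[hit] <- FALSE
            }
        }
    }

    unique_ok <- rep(TRUE, nrow(variants))
    if (!is.null(reference)) {
        ref <- .as_sequences(reference)
        first <- !duplicated(keys)
        ok_by_key <- setNames(rep(TRUE, sum(first)), keys[first])
        cand_keys <- unique(keys[depth_ok & dbsnp_ok & chrom_ok & germline_ok & cnv_ok])
        for (k in cand_keys) {
            i <- match(k, keys)
            if (!variants$chrom[i] %in% names(ref) ||
                variants$pos[i] > nchar(ref[[variants$chrom[i]]])) {
                ok_by_key[k] <- FALSE
                next
            }
            ok_by_key[k] <- window_maps_uniquely(variants$chrom[i], variants$pos[i],
                                                 ref, window, identity_threshold)
        }
        unique_ok <- ok_by_key[keys]
    } else {
        message("no reference supplied; flanking-window uniqueness not checked")
    }

    keep <- depth_ok & dbsnp_ok & chrom_ok & germline_ok & cnv_ok & unique_ok
    excl <- c(incomplete_annotation = sum(!complete),
              low_depth = sum(!depth_ok),
              cnv_overlap = sum(depth_ok & !cnv_ok),
              dbsnp = sum(complete & !dbsnp_ok),
              sex_or_mito_chrom = sum(!chrom_ok),
              germline_reads = sum(complete & !germline_ok),
              non_unique_window = sum(!unique_ok),
              uncovered_by_segments = uncovered)
    structure(variants[keep, , drop = FALSE], exclusions = excl)
}
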