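# Isoform-specific expression from splice-junction reads (SRPM).
#
# Isoforms sharing upstream exons cannot be separated by exon coverage; each
# is quantified by its discriminating splice junction. For the androgen
# receptor, AR-V7 is measured by reads joining exon 3 to a cryptic exon in
# intron 3, and full-length AR by reads joining exon 4 to exon 5 (hg19
# coordinates). Counts are normalized by the sample's total splice reads
# (SRPM, splice reads per million).

#' Define a splice junction by its donor and acceptor exons
#'
#' Coordinates are 1-based inclusive; the donor exon must end before the
#' acceptor exon starts on the same chromosome.
#'
#' @param name unique junction name.
#' @param chrom chromosome.
#' @param donor_start,donor_end donor exon interval.
#' @param acceptor_start,acceptor_end acceptor exon interval.
#' @return one-row data frame.
#' @export
junction_definition <- function(name, chrom, donor_start, donor_end,
                                acceptor_start, acceptor_end) {
    stopifnot(donor_start <= donor_end, acceptor_start <= acceptor_end,
              donor_end < acceptor_start)
    data.frame(name = name, chrom = chrom,
               donor_start = donor_start, donor_end = donor_end,
               acceptor_start = acceptor_start, acceptor_end = acceptor_end,
               stringsAsFactors = FALSE)
}

#' Discriminating junctions for AR-V7 and full-length AR (hg19)
#'
#' AR-V7: exon 3 (chrX:66905852-66905968) spliced to the cryptic exon in
#' intron 3 (chrX:66914515-66915580). AR-FL: exon 4 (chrX:66931244-66931531)
#' spliced to exon 5 (chrX:66937320-66937464).
#'
#' @return two-row junction definition data frame.
#' @export
ar_junctions <- function() {
    rbind(
        junction_definition("AR-V7", "chrX", 66905852, 66905968, 66914515, 66915580),
        junction_definition("AR-FL", "chrX", 66931244, 66931531, 66937320, 66937464))
}

#' Count splice reads supporting a junction
#'
#' A spliced read supports a junction when its last aligned base before the
#' gap (donor end) falls inside the junction's donor exon and its first
#' aligned base after the gap (acceptor start) falls inside the acceptor
#' exon, on the same chromosome.
#'
#' @param splice_reads data frame `chrom`, `donor_end`, `acceptor_start`
#'   (one row per spliced alignment, 1-based).
#' @param junctions junction definition data frame (one or more rows).
#' @return named integer vector of counts, one per junction.
#' @export
count_junction_reads <- function(splice_reads, junctions) {
    counts <- integer(nrow(junctions))
    names(counts) <- junctions$name
    if (nrow(splice_reads) == 0) return(counts)
    for (j in seq_len(nrow(junctions))) {
        jd <- junctions[j, ]
        counts[j] <- sum(splice_reads$chrom == jd$chrom &
                         splice_reads$donor_end >= jd$donor_start &
                         splice_reads$donor_end <= jd$donor_end &
                         splice_reads$acceptor_start >= jd$acceptor_start &
                         splice_reads$acceptor_start <= jd$acceptor_end)
    }
    counts
}

#' Splice reads per million
#'
#' @param junction_count splice reads supporting the junction.
#' @param total_splice_reads total splice reads in the sample.
#' @return `junction_count / total_splice_reads * 1e6`; `NA` with a warning
#'   when the total is zero.
#' @export
srpm <- function(junction_count, total_splice_reads) {
    if (any(total_splice_reads <= 0)) {
        warning("SRPM undefined for zero total splice reads; returning NA")
        return(ifelse(total_splice_reads > 0,
                      junction_count / total_splice_reads * 1e6, NA_real_))
    }
    junction_count / total_splice_reads * 1e6
}

#' Isoform fold change between two SRPM values
#'
#' `(srpm_a + f) / (srpm_b + f)` with a small pseudo-floor `f` stabilizing
#' zero observations.
#'
#' @param srpm_a,srpm_b non-negative SRPM values.
#' @param floor pseudo-floor in SRPM units.
#' @return the ratio.
#' @export
isoform_fold_change <- function(srpm_a, srpm_b, floor = 0.1) {
    stopifnot(all(srpm_a >= 0), all(srpm_b >= 0), floor >= 0)
    (srpm_a + floor) / (srpm_b + floor)
}
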