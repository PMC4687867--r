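# File interchange: variant TSV/VCF mirror, interval BED.
#
# TSV is the canonical interchange format; a VCF mirror (per-sample AD/DP,
# annotation flags in INFO) is provided for interoperability. Coordinate
# conventions: variant tables and VCF are 1-based; BED output is 0-based
# half-open and says so in its header.

#' Write a variant table as TSV
#'
#' @param variants long-format variant data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
    con <- file(path, "w")
    writeLines("# coordinates: 1-based", con)
    close(con)
    suppressWarnings(write.table(variants, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    invisible(path)
}

#' Read a variant table TSV
#'
#' @param path path written by [write_variant_tsv()].
#' @return variant data frame.
#' @export
read_variant_tsv <- function(path) {
    read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write a variant table as a minimal VCF mirror
#'
#' Per-sample `AD` (ref,alt) and `DP`; annotations as INFO keys `IMPACT`,
#' `EXONIC`, `KG`, `KG_EUR`, `KG_AFR`, `ESP`, `DBSNP`, `GERMLINE_ALT`,
#' `CALLERS`. Samples in which a variant was not observed carry missing
#' genotype fields.
#'
#' @param variants long-format variant data frame.
#' @param path output path (uncompressed `.vcf`).
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
    keys <- variant_key(variants)
    uk <- unique(keys)
    samples <- sort(unique(variants$sample))
    hdr <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact class\">",
        "##INFO=<ID=EXONIC,Number=0,Type=Flag,Description=\"Exonic variant\">",
        "##INFO=<ID=KG,Number=0,Type=Flag,Description=\"Present in 1000 Genomes\">",
        "##INFO=<ID=KG_EUR,Number=0,Type=Flag,Description=\"Present in 1000 Genomes EUR\">",
        "##INFO=<ID=KG_AFR,Number=0,Type=Flag,Description=\"Present in 1000 Genomes AFR\">",
        "##INFO=<ID=ESP,Number=0,Type=Flag,Description=\"Present in the Exome Sequencing Project\">",
        "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"dbSNP site\">",
        "##INFO=<ID=GERMLINE_ALT,Number=1,Type=Integer,Description=\"Alt reads in the germline sample\">",
        "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Caller provenance (semicolon-separated)\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", samples), collapse = "\t"))
    lines <- character(length(uk))
    for (i in seq_along(uk)) {
        rows <- variants[keys == uk[i], , drop = FALSE]
        r1 <- rows[1, ]
        info <- c(paste0("IMPACT=", r1$impact),
                  if (isTRUE(r1$exonic)) "EXONIC",
                  if (isTRUE(r1$in_1000g)) "KG",
                  if (isTRUE(r1$in_1000g_eur)) "KG_EUR",
                  if (isTRUE(r1$in_1000g_afr)) "KG_AFR",
                  if (isTRUE(r1$in_esp)) "ESP",
                  if (isTRUE(r1$in_dbsnp)) "DBSNP",
                  paste0("GERMLINE_ALT=", r1$germline_alt_reads),
                  paste0("CALLERS=", gsub(";", ",", r1$caller)))
        gt <- vapply(samples, function(s) {
            rr <- rows[rows$sample == s, , drop = FALSE]
            if (nrow(rr) == 0) return(".:.")
            sprintf("%d,%d:%d", rr$ref_reads[1], rr$alt_reads[1],
                    rr$ref_reads[1] + rr$alt_reads[1])
        }, character(1))
        lines[i] <- paste(c(r1$chrom, r1$pos, ".", r1$ref, r1$alt, ".", "PASS",
                            paste(info, collapse = ";"), "AD:DP", gt),
                          collapse = "\t")
    }
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Read a variant VCF mirror back into the long table format
#'
#' Requires the `vcfR` package.
#'
#' @param path VCF path written by [write_variant_vcf()].
#' @return long-format variant data frame.
#' @export
read_variant_vcf <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- vcfR::extract.info(v, "IMPACT")
    galt <- as.integer(vcfR::extract.info(v, "GERMLINE_ALT"))
    callers <- gsub(",", ";", vcfR::extract.info(v, "CALLERS"))
    info_str <- vcfR::getINFO(v)
    flags <- lapply(c("EXONIC", "KG", "KG_EUR", "KG_AFR", "ESP", "DBSNP"),
                    function(f) grepl(paste0("(^|;)", f, "(;|$)"), info_str))
    ad <- vcfR::extract.gt(v, "AD")
    out <- list()
    for (s in colnames(ad)) {
        ok <- !is.na(ad[, s]) & ad[, s] != "."
        if (!any(ok)) next
        parts <- do.call(rbind, strsplit(ad[ok, s], ",", fixed = TRUE))
        out[[s]] <- data.frame(
            chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
            ref = fix$REF[ok], alt = fix$ALT[ok], sample = s,
            alt_reads = as.integer(parts[, 2]),
            ref_reads = as.integer(parts[, 1]),
            impact = info[ok], exonic = flags[[1]][ok],
            in_1000g = flags[[2]][ok], in_1000g_eur = flags[[3]][ok],
            in_1000g_afr = flags[[4]][ok], in_esp = flags[[5]][ok],
            in_dbsnp = flags[[6]][ok], germline_alt_reads = galt[ok],
            caller = callers[ok], stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write intervals as BED
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optional further columns (written as extra fields).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path) {
    con <- file(path, "w")
    writeLines("# coordinates: 0-based half-open (BED)", con)
    close(con)
    suppressWarnings(write.table(intervals, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, col.names = FALSE,
                                 append = TRUE))
    invisible(path)
}
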