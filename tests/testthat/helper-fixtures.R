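# Shared fixtures, all generated in code.

# A toy variant table: one violator per reporting-filter clause plus one
# clean variant, each in one sample.
toy_variant_table <- function() {
    base <- data.frame(
        chrom = "chr1", pos = 1000L + 100L * (0:5), ref = "A", alt = "T",
        sample = "S1", alt_reads = 30L, ref_reads = 70L, called = TRUE,
        impact = "HIGH", exonic = TRUE,
        in_1000g = FALSE, in_1000g_eur = FALSE, in_1000g_afr = FALSE,
        in_esp = FALSE, in_dbsnp = FALSE, germline_alt_reads = 0L,
        caller = "MuTect", stringsAsFactors = FALSE)
    base$impact[2] <- "MODIFIER"          # impact clause
    base$exonic[3] <- FALSE               # exonic clause
    base$in_1000g[4] <- TRUE              # 1000 Genomes clause
    base$in_esp[5] <- TRUE                # ESP clause
    base$germline_alt_reads[6] <- 2L      # germline clause
    base
}

# small random sequence (named, single chromosome)
random_genome <- function(len = 5000, seed = 1, name = "chr1") {
    set.seed(seed)
    setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""), name)
}

# mutate exactly n positions of a string (distinct sites, guaranteed changes)
mutate_n <- function(seq, n, seed = 1) {
    set.seed(seed)
    ch <- strsplit(seq, "")[[1]]
    idx <- sample(seq_along(ch), n)
    for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
}

# small cohort configuration for fast end-to-end runs
small_cohort_config <- function(seed = 11, ...) {
    samples <- data.frame(
        id = c("BL", "V1", "V2", "P1", "P2"),
        role = c("germline", "patient", "patient", "pdx", "pdx"),
        visit = c(NA, 1, 2, 1, 2),
        parent = c(NA, NA, NA, "V1", "V2"),
        stringsAsFactors = FALSE)
    args <- list(samples = samples, n_variants = 60,
                 intervals_per_chrom = c(chr1 = 150, chr2 = 120, chr3 = 120),
                 copy_events = data.frame(chrom = c("chr1", "chr3"),
                                          start = c(50L * 120L, 20L * 120L),
                                          end = c(60L * 120L, 80L * 120L),
                                          tumor_copies = c(39L, 1L)),
                 n_reads_per_pdx = 200, reference_length = 4000,
                 n_genes = 400, total_splice_reads = 1e5,
                 n_reference_profiles = 3, seed = seed)
    over <- list(...)
    args[names(over)] <- over
    do.call(cohort_config, args)
}
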