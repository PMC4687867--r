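# The three filter chains and the flanking-window uniqueness check.

test_that("reporting filter retains exactly the hand-enumerated survivors", {
    tab <- toy_variant_table()
    kept <- reporting_filter(tab)
    expect_equal(nrow(kept), 1)
    expect_equal(kept$pos, 1000L)
    excl <- attr(kept, "exclusions")
    expect_equal(unname(excl[c("low_modifier_impact", "non_exonic",
                               "population_database", "germline_reads")]),
                 c(1L, 1L, 2L, 1L))
    # idempotent and monotone
    expect_equal(nrow(reporting_filter(kept)), 1)
    # missing annotation fails closed
    tab$impact[1] <- NA
    expect_equal(nrow(reporting_filter(tab)), 0)
})

test_that("flanking-window uniqueness follows the 90% identity rule", {
    g <- random_genome(3000, seed = 5)
    expect_true(window_maps_uniquely("chr1", 1500, g))

    win <- substring(g[["chr1"]], 1450, 1550)  # 101 bp centered on 1500
    # tandem duplication: two perfect copies -> not unique
    dup <- setNames(paste0(g[["chr1"]], win), "chr1")
    expect_false(window_maps_uniquely("chr1", 1500, dup))
    # second copy at 88% identity (12 mismatches) -> still unique
    far <- setNames(paste0(g[["chr1"]], mutate_n(win, 12, seed = 6)), "chr1")
    expect_true(window_maps_uniquely("chr1", 1500, far))
    # second copy at exactly 10 mismatches (91/101 = 0.901 >= 0.90) -> not unique
    near <- setNames(paste0(g[["chr1"]], mutate_n(win, 10, seed = 6)), "chr1")
    expect_false(window_maps_uniquely("chr1", 1500, near))
    # 11 mismatches (90/101 = 0.891 < 0.90) -> unique again
    edge <- setNames(paste0(g[["chr1"]], mutate_n(win, 11, seed = 6)), "chr1")
    expect_true(window_maps_uniquely("chr1", 1500, edge))
    # reverse-complement copies are found too
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    duprc <- setNames(paste0(g[["chr1"]], rc), "chr1")
    expect_false(window_maps_uniquely("chr1", 1500, duprc))
    # window truncated at the chromosome end is flagged
    res <- window_maps_uniquely("chr1", 10, g)
    expect_true(attr(res, "truncated"))
    expect_error(window_maps_uniquely("chr1", 99999, g), "bounds")
})

test_that("concordance eligibility applies all four clauses per variant key", {
    g <- random_genome(4000, seed = 7)
    mk <- function(pos, ...) {
        row <- toy_variant_table()[1, ]
        row$pos <- pos
        over <- list(...)
        for (f in names(over)) row[[f]] <- over[[f]]
        row
    }
    tab <- rbind(mk(500),                                   # clean -> eligible
                 mk(700, impact = "LOW"),                    # impact clause
                 mk(900, in_1000g_eur = TRUE),               # EUR clause
                 mk(1100, in_1000g_afr = TRUE),              # AFR clause
                 mk(1300, germline_alt_reads = 1L))          # germline clause
    elig <- concordance_eligibility(tab, g)
    expect_identical(as.character(elig), variant_key(tab[1, ]))
    # a duplicated flanking window makes a clean variant ineligible
    win <- substring(g[["chr1"]], 1950, 2050)
    gdup <- setNames(paste0(g[["chr1"]], win), "chr1")
    tab2 <- rbind(mk(500), mk(2000))
    elig2 <- concordance_eligibility(tab2, gdup)
    expect_identical(as.character(elig2), variant_key(tab2[1, ]))
    expect_equal(unname(attr(elig2, "exclusions")["non_unique_window"]), 1L)
})

test_that("purity eligibility enforces its boundary conditions exactly", {
    g <- random_genome(6000, seed = 8)
    mk <- function(pos, alt_reads = 30L, ref_reads = 70L, chrom = "chr1", ...) {
        row <- toy_variant_table()[1, ]
        row$chrom <- chrom; row$pos <- pos
        row$alt_reads <- alt_reads; row$ref_reads <- ref_reads
        over <- list(...)
        for (f in names(over)) row[[f]] <- over[[f]]
        row
    }
    segs <- data.frame(chrom = "chr1", start = c(0L, 3000L), end = c(3000L, 6000L),
                       log2r = c(0.0, 0.6))
    tab <- rbind(
        mk(500),                                        # clean, depth 100
        mk(700, alt_reads = 15L, ref_reads = 34L),      # depth 49 -> out
        mk(900, alt_reads = 15L, ref_reads = 35L),      # depth 50 -> in
        mk(1100, in_dbsnp = TRUE),                      # dbSNP -> out
        mk(1300, germline_alt_reads = 1L),              # <= 1 allowed -> in
        mk(1500, germline_alt_reads = 2L),              # 2 -> out
        mk(1700, chrom = "chrX"),                       # chrX -> out
        mk(3500))                                       # |log2r| >= 0.5 -> out
    gX <- c(g, chrX = random_genome(3000, seed = 9)[[1]])
    kept <- suppressMessages(purity_eligibility(tab, segs, gX))
    expect_setequal(kept$pos, c(500L, 900L, 1300L))
    # segment at |log2r| = 0.49 does not exclude
    segs2 <- segs; segs2$log2r[2] <- 0.49
    kept2 <- suppressMessages(purity_eligibility(tab, segs2, gX))
    expect_true(3500L %in% kept2$pos)
    # idempotent
    again <- suppressMessages(purity_eligibility(kept, segs, gX))
    expect_equal(nrow(again), nrow(kept))
    # uncovered variants are treated as copy-neutral with a message
    expect_message(
        expect_message(purity_eligibility(mk(500, chrom = "chr9"),
                                          segs, reference = NULL),
                       "copy-neutral"),
        "uniqueness")
})
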