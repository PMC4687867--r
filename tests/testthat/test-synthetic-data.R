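# The cohort generator: determinism, expected VAFs, contamination labels,
# coverage expectations.

test_that("fixed seed reproduces every generator output bit-identically", {
    cfg <- small_cohort_config(seed = 42)
    a <- simulate_variant_table(cfg)
    b <- simulate_variant_table(cfg)
    expect_identical(a, b)

    refs <- simulate_references(length = 2000, seed = 5)
    r1 <- simulate_two_genome_reads(refs$graft, refs$host, 100, 0.1, 50, seed = 9)
    r2 <- simulate_two_genome_reads(refs$graft, refs$host, 100, 0.1, 50, seed = 9)
    expect_identical(r1, r2)

    iv <- make_intervals(c(chr1 = 50), seed = 3)
    expect_identical(simulate_coverage(iv, seed = 4), simulate_coverage(iv, seed = 4))
})

test_that("expected VAF is purity * prevalence / 2 on diploid loci", {
    # single tumor sample, no copy events, many variants
    samples <- data.frame(id = c("BL", "V1"), role = c("germline", "patient"),
                          visit = c(NA, 1), parent = c(NA, NA),
                          stringsAsFactors = FALSE)
    cfg <- cohort_config(samples = samples, n_variants = 10000,
                         pdx_private_rate = 0, p_chrx = 0, p_chrm = 0,
                         p_nonunique = 0, copy_events = data.frame(),
                         purity = c(V1 = 0.75), seed = 31)
    vt <- simulate_variant_table(cfg)
    v <- vt$variants
    tr <- vt$truth$variants
    clone <- tr$clone[match(variant_key(v), tr$key)]
    vaf <- v$alt_reads / (v$alt_reads + v$ref_reads)
    for (k in 1:3) {
        expected <- 0.75 * cfg$clone_prevalence[k, "V1"] / 2
        obs <- vaf[clone == k]
        se <- sd(obs) / sqrt(length(obs))
        expect_lt(abs(mean(obs) - expected), 3 * se + 1e-12)
    }
    # heterozygous clonal limit: purity 1, phi 1, exact mode -> VAF 0.5
    cfg1 <- cohort_config(samples = samples, n_variants = 50,
                          clone_prevalence = c(1, 1, 1), pdx_private_rate = 0,
                          p_chrx = 0, p_chrm = 0, p_nonunique = 0,
                          copy_events = data.frame(),
                          purity = c(V1 = 1), exact = TRUE, seed = 32)
    v1 <- simulate_variant_table(cfg1)$variants
    expect_true(all(v1$alt_reads / (v1$alt_reads + v1$ref_reads) == 0.5))
})

test_that("configs implying diploid VAF above 0.5 are rejected and fractions validated", {
    samples <- default_sample_sheet()
    expect_error(cohort_config(host_contamination = 1.2), "fractions")
    expect_error(cohort_config(clone_fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("no-noise cohort gives identical patient and PDX variant sets", {
    cfg <- small_cohort_config(seed = 21, host_contamination = 0,
                               pdx_private_rate = 0, exact = TRUE)
    vt <- simulate_variant_table(cfg)
    sets <- mutation_sets(vt$variants)
    expect_setequal(sets$P1, sets$V1)
    expect_setequal(sets$P2, sets$V2)
})

test_that("host-label fraction matches the planted contamination", {
    refs <- simulate_references(length = 3000, divergence = 0.05, seed = 6)
    sim <- simulate_two_genome_reads(refs$graft, refs$host, 10000, 0.08,
                                     100, 0, seed = 7)
    frac <- mean(sim$truth$origin == "host")
    expect_lt(abs(frac - 0.08), 3 * sqrt(0.08 * 0.92 / 10000))
    expect_true(all(simulate_two_genome_reads(refs$graft, refs$host, 200, 0,
                                              50, seed = 1)$truth$origin == "graft"))
    expect_true(all(simulate_two_genome_reads(refs$graft, refs$host, 200, 1,
                                              50, seed = 1)$truth$origin == "host"))
    expect_error(simulate_two_genome_reads(refs$graft, refs$host, 10, -0.1, 50),
                 "contamination")
})

test_that("coverage log2 expectations follow the purity-copy mixture", {
    iv <- make_intervals(c(chr1 = 200), seed = 2)
    ev <- data.frame(chrom = "chr1", start = 0L, end = 200L * 120L,
                     tumor_copies = 1L)
    # exact mode, flat GC: per-interval ratio against a diploid reference
    dip <- simulate_coverage(iv, NULL, purity = 1, depth = 100,
                             gc_bias_amplitude = 0, exact = TRUE, seed = 3)$profile
    del_pure <- simulate_coverage(iv, ev, purity = 1, depth = 100,
                                  gc_bias_amplitude = 0, exact = TRUE, seed = 3)$profile
    del_75 <- simulate_coverage(iv, ev, purity = 0.75, depth = 100,
                                gc_bias_amplitude = 0, exact = TRUE, seed = 3)$profile
    # RPKM renormalizes within sample; compare raw read ratios
    expect_equal(median(log2(del_pure$reads / dip$reads)), -1, tolerance = 1e-10)
    expect_equal(median(log2(del_75$reads / dip$reads)),
                 log2((0.75 * 1 + 0.25 * 2) / 2), tolerance = 1e-10)
    expect_error(simulate_coverage(iv[0, ]), "empty")
})

test_that("junction counts and expression pairs hit their planted targets", {
    j <- ar_junctions()
    sim0 <- simulate_junction_reads(j, c(0, 1e-4), 1e5, seed = 3)
    expect_equal(sim0$counts$count[1], 0)
    sim <- simulate_junction_reads(j, c(1e-5, 1e-4), 1e6, exact = TRUE, seed = 3)
    expect_equal(sim$counts$count[1], 10)
    expect_equal(srpm(sim$counts$count[1], sim$total_splice_reads), 10)
    expect_error(simulate_junction_reads(j, c(0.6, 0.6), 1e4), "proportions")

    ex <- simulate_expression(n_genes = 500, correlation = 1,
                              fold_changed_fraction = 0, count_noise = FALSE,
                              seed = 4)
    r <- expression_correlation(rpkm(ex$counts, ex$lengths, ex$totals)[, 1],
                                rpkm(ex$counts, ex$lengths, ex$totals)[, 2])
    expect_gt(r, 0.999)
})
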