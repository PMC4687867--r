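# Recall/precision set metrics, aggregation and VAF concordance.

test_that("recall and precision match direct set arithmetic", {
    P <- c("a", "b", "c", "d"); X <- c("a", "b", "c", "e")
    expect_equal(recall(P, X), 0.75)
    expect_equal(precision(P, X), 0.75)
    expect_equal(recall(P, c(P, "z")), 1.0)
    expect_equal(precision(c("q", "r"), c("s", "t")), 0.0)
    expect_warning(expect_true(is.na(recall(character(0), X))), "empty")
    expect_warning(expect_true(is.na(precision(P, character(0)))), "empty")
})

test_that("recall/precision agree with a brute-force oracle and satisfy duality", {
    set.seed(77)
    universe <- sprintf("v%03d", 1:60)
    brute_intersection <- function(P, X) {
        n <- 0L
        for (p in P) for (x in X) if (p == x) n <- n + 1L
        n
    }
    for (i in 1:200) {
        P <- sample(universe, sample(1:20, 1))
        X <- sample(universe, sample(1:20, 1))
        expect_equal(recall(P, X), brute_intersection(P, X) / length(P))
        expect_equal(precision(P, X), brute_intersection(P, X) / length(X))
        expect_equal(recall(P, X), precision(X, P))
        expect_true(recall(P, X) >= 0 && recall(P, X) <= 1)
        # both equal 1 iff the sets are equal
        if (recall(P, X) == 1 && precision(P, X) == 1) expect_setequal(P, X)
    }
})

test_that("per-PDX summary pairs lineages and aggregates correctly", {
    patient <- list(V1 = c("a", "b", "c", "d"), V2 = c("a", "b"))
    pdx <- list(P1 = c("a", "b", "c", "d"),          # identical
                P2 = c("a", "b", "c", "e", "f"))     # recall 0.75 vs V1
    lineage <- c(P1 = "V1", P2 = "V1")
    out <- concordance_summary(patient, pdx, lineage)
    expect_equal(out$table$recall, c(1, 0.75))
    expect_equal(out$table$precision, c(1, 0.6))
    expect_equal(out$aggregates$mean, c(mean(c(1, 0.75)), mean(c(1, 0.6))))
    expect_equal(out$aggregates$median, c(0.875, 0.8))
    expect_error(concordance_summary(patient, pdx, c(P1 = "V1")), "lineage")
    expect_error(concordance_summary(patient, pdx, c(P1 = "V1", P2 = "V9")),
                 "unknown patient")
})

test_that("PDX-private rate drives precision toward 1/(1+r) with recall near 1", {
    cfg <- small_cohort_config(seed = 19, pdx_private_rate = 0.5,
                               n_variants = 200)
    vt <- simulate_variant_table(cfg)
    sets <- mutation_sets(vt$variants)
    r <- recall(sets$V1, sets$P1)
    p <- precision(sets$V1, sets$P1)
    expect_gt(r, 0.95)
    expect_lt(abs(p - 1 / 1.5), 0.08)
})

test_that("VAF matrix marks missing calls and scores cross-sample spread", {
    tab <- rbind(
        data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T",
                   sample = c("S1", "S2", "S3"), alt_reads = 30L,
                   ref_reads = 70L, called = TRUE),
        data.frame(chrom = "chr1", pos = 20L, ref = "C", alt = "G",
                   sample = c("S1", "S2"), alt_reads = c(10L, 50L),
                   ref_reads = c(90L, 50L), called = TRUE),
        data.frame(chrom = "chr1", pos = 30L, ref = "G", alt = "A",
                   sample = "S1", alt_reads = 20L, ref_reads = 80L,
                   called = c(TRUE)))
    keys <- unique(variant_key(tab))
    out <- vaf_concordance(tab, keys)
    expect_equal(dim(out$vaf), c(3L, 3L))
    # identical counts across samples -> zero SD
    expect_equal(unname(out$score[1]), 0)
    expect_equal(unname(out$score[2]), sd(c(0.1, 0.5)))
    # a variant seen once has no spread estimate; its missing cells are NA
    expect_true(is.na(out$score[3]))
    expect_true(is.na(out$vaf["S2", keys[3]]))
})

test_that("stable planted clones keep per-variant VAF spread near sampling noise", {
    cfg <- small_cohort_config(seed = 23, pdx_private_rate = 0,
                               host_contamination = 0, n_variants = 150,
                               purity = c(V1 = 0.75, V2 = 0.75, P1 = 0.75,
                                          P2 = 0.75))
    vt <- simulate_variant_table(cfg)
    keys <- names(which(table(variant_key(vt$variants[vt$variants$called, ])) == 4))
    out <- vaf_concordance(vt$variants, keys)
    # binomial sampling SD at depth ~100 and VAF <= 0.375 is <= ~0.05;
    # stable clone frequencies should not add systematic spread
    expect_lt(median(out$score, na.rm = TRUE), 3 * sqrt(0.375 * 0.625 / 100))
})
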