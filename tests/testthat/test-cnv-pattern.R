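# Reference coverage model, GC correction, log2 ratios, segmentation, calls.

test_that("reference model computes per-interval median and n-1 variance", {
    grid <- data.frame(chrom = "chr1", start = c(0L, 120L), end = c(120L, 240L))
    mkp <- function(r) cbind(grid, rpkm = r)
    model <- learn_reference_model(list(mkp(c(2, 10)), mkp(c(4, 10)), mkp(c(6, 10))))
    expect_equal(model$median, c(4, 10))
    expect_equal(model$variance, c(4, 0))
    expect_error(learn_reference_model(list(mkp(c(2, 2)))), "at least 2")
    grid2 <- grid; grid2$start <- grid2$start + 1L
    expect_error(learn_reference_model(list(mkp(c(1, 1)), cbind(grid2, rpkm = c(1, 1)))),
                 "different interval grids")
    # identical references: zero variance, median equals the common profile
    m2 <- learn_reference_model(list(mkp(c(5, 7)), mkp(c(5, 7))))
    expect_equal(m2$variance, c(0, 0))
    expect_equal(m2$median, c(5, 7))
})

test_that("GC correction aligns group density peaks", {
    set.seed(33)
    # bias-free profile: correction factors all near 1
    prof <- data.frame(chrom = "chr1", start = 0:999 * 120L, end = 1:1000 * 120L,
                       gc = runif(1000, 0.3, 0.6),
                       copies_in_pool = 1L,
                       rpkm = rnorm(1000, 100, 5))
    out <- gc_correct(prof)
    expect_lt(max(abs(attr(out, "correction")$factor - 1)), 0.1)
    # two groups with modes ~50 and ~100: low group scaled toward x2
    prof2 <- prof
    low <- prof2$gc < 0.45
    prof2$rpkm <- ifelse(low, rnorm(1000, 50, 2), rnorm(1000, 100, 4))
    out2 <- gc_correct(prof2, bin_width = 0.15)
    ratio <- median(out2$rpkm[low]) / median(out2$rpkm[!low])
    expect_lt(abs(ratio - 1), 0.1)
    # planted smooth multiplicative bias is removed within 5%
    bias <- exp(0.8 * (prof$gc - 0.45))
    prof3 <- prof; prof3$rpkm <- prof$rpkm * bias
    out3 <- gc_correct(prof3)
    grp_mode <- tapply(out3$rpkm, floor(out3$gc / 0.05), median)
    expect_lt(diff(range(grp_mode)) / median(out3$rpkm), 0.1)
})

test_that("log2 ratios hit their closed forms", {
    grid <- data.frame(chrom = "chr1", start = 0:99 * 120L, end = 1:100 * 120L)
    refs <- lapply(1:3, function(i) cbind(grid, rpkm = rep(100, 100)))
    model <- learn_reference_model(refs)
    eq <- log2_ratio(cbind(grid, rpkm = rep(100, 100)), model)
    expect_equal(eq$log2r, rep(0, 100))
    dbl <- log2_ratio(cbind(grid, rpkm = rep(200, 100)), model, eps = 0)
    expect_equal(dbl$log2r, rep(1, 100))
    half <- log2_ratio(cbind(grid, rpkm = rep(50, 100)), model, eps = 0)
    expect_equal(half$log2r, rep(-1, 100))
    # masked intervals are excluded
    refs0 <- lapply(1:3, function(i) cbind(grid, rpkm = c(0.1, rep(100, 99))))
    m0 <- learn_reference_model(refs0)
    expect_equal(nrow(log2_ratio(cbind(grid, rpkm = rep(100, 100)), m0)), 99)
})

test_that("CBS recovers planted breakpoints and stays quiet on noise", {
    set.seed(44)
    x <- c(rnorm(200, 0, 0.2), rnorm(50, 1.5, 0.2), rnorm(250, 0, 0.2))
    seg <- segment_cbs(x, nperm = 1000)
    expect_equal(nrow(seg), 3)
    expect_lt(abs(seg$end_idx[1] - 200), 3)
    expect_lt(abs(seg$end_idx[2] - 250), 3)
    expect_lt(max(abs(seg$log2r - c(0, 1.5, 0))), 0.1)
    # constant sequence: one segment
    expect_equal(nrow(segment_cbs(rep(0.3, 100), nperm = 200)), 1)
    # short sequence: single segment, no error
    expect_equal(nrow(segment_cbs(c(0.1, 0.2), nperm = 100)), 1)
})

test_that("normalization removes uniform shifts and recentering aligns the anchor", {
    set.seed(55)
    x <- c(rnorm(150, 0.3, 0.1), rnorm(50, 1.3, 0.1))
    seg <- segment_cbs(x, nperm = 500)
    norm <- normalize_and_recenter(seg)
    # median interval value sits at zero: the majority (baseline) segment is 0
    expect_lt(abs(norm$log2r[1]), 0.05)
    # already-centred input is unchanged
    expect_equal(normalize_and_recenter(norm)$log2r, norm$log2r)
    # two samples differing in chr2 mean: second is shifted to match
    mk <- function(shift) data.frame(chrom = c("chr1", "chr2"),
                                     start_idx = c(1L, 101L),
                                     end_idx = c(100L, 200L),
                                     n_intervals = c(100L, 100L),
                                     log2r = c(0.0, shift))
    out <- normalize_and_recenter(list(a = mk(0), b = mk(0.2)),
                                  recenter_anchor = "chr2")
    expect_equal(out$b$log2r[2] - out$a$log2r[2], 0)
    expect_message(normalize_and_recenter(mk(0.1)[1, ], recenter_anchor = "chr9"),
                   "absent")
})

test_that("calls use strict thresholds and gene annotation counts planted events", {
    seg <- data.frame(chrom = "chr1", start = c(0L, 1200L, 2400L),
                      end = c(1200L, 2400L, 3600L),
                      log2r = c(0.5, 0.51, -0.51), n_intervals = 10L)
    out <- call_and_annotate(seg)
    expect_equal(out$segments$call, c("neutral", "amplified", "deleted"))
    genes <- data.frame(chrom = "chr1", start = 0:5 * 600L, end = 1:6 * 600L,
                        gene = paste0("g", 1:6))
    out2 <- call_and_annotate(seg, genes)
    expect_equal(unname(out2$counts), c(2L, 2L))
    expect_equal(out2$gene_calls$call,
                 c("neutral", "neutral", "amplified", "amplified",
                   "deleted", "deleted"))
})

test_that("pipeline calls are invariant to a constant scaling of the tumor profile", {
    set.seed(66)
    iv <- make_intervals(c(chr1 = 300), seed = 2)
    ev <- data.frame(chrom = "chr1", start = 100L * 120L, end = 140L * 120L,
                     tumor_copies = 6L)
    refs <- lapply(1:3, function(i)
        simulate_coverage(iv, NULL, depth = 100, gc_bias_amplitude = 0,
                          seed = 100 + i)$profile)
    model <- learn_reference_model(refs)
    tum <- simulate_coverage(iv, ev, purity = 1, depth = 100,
                             gc_bias_amplitude = 0, seed = 7)$profile
    run <- function(p) {
        seg <- segment_cbs(log2_ratio(p, model, eps = 0), nperm = 500)
        call_and_annotate(normalize_and_recenter(seg))$segments$call
    }
    tum2 <- tum; tum2$rpkm <- tum2$rpkm * 3
    set.seed(1); a <- run(tum)
    set.seed(1); b <- run(tum2)
    expect_identical(a, b)
    expect_true("amplified" %in% a)
})
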