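# k-mer index construction and the five-category read classification.

test_that("index enumerates canonical windows, deduplicated, N-aware", {
    # independent oracle: enumerate windows by hand and canonicalize via a
    # simple base-R reverse complement
    rc <- function(s) {
        comp <- chartr("ACGT", "TGCA", s)
        paste(rev(strsplit(comp, "")[[1]]), collapse = "")
    }
    seq <- "ACGTACGT"
    k <- 4
    windows <- substring(seq, 1:5, 4:8)
    oracle <- sort(unique(pmin(windows, vapply(windows, rc, character(1)))))
    expect_error(build_kmer_index(seq, k = 9), "k >= 11")
    expect_identical(sort(unique(canonical_kmers(windows))), oracle)

    withN <- paste0(strrep("A", 15), "N", strrep("C", 15))
    idxN <- build_kmer_index(withN, k = 12)
    expect_false(any(grepl("N", idxN$kmers)))
    # no k-mer spans the N: only the A-run and C-run windows survive
    expect_true(all(idxN$kmers %in% canonical_kmers(c(strrep("A", 12), strrep("C", 12)))))
    expect_error(build_kmer_index("ACGT", k = 11), "empty")
})

test_that("category rules follow the graft/host/both/neither/ambiguous counts", {
    set.seed(10)
    g_unique <- random_genome(600, seed = 101, name = "g")
    h_unique <- random_genome(600, seed = 202, name = "h")
    shared <- random_genome(600, seed = 303, name = "s")
    gi <- build_kmer_index(paste0(g_unique, shared), 25, "graft")
    hi <- build_kmer_index(paste0(h_unique, shared), 25, "host")

    reads <- c(g = substring(g_unique, 100, 199),
               h = substring(h_unique, 100, 199),
               b = substring(shared, 100, 199),
               n = random_genome(100, seed = 404),
               a = paste0(substring(g_unique, 300, 349),
                          substring(h_unique, 300, 349)))
    cls <- classify_reads(reads, gi, hi)
    expect_equal(cls$category, c("graft", "host", "both", "neither", "ambiguous"))
    # identical references: nothing is specific
    same <- build_kmer_index(paste0(g_unique, shared), 25, "host")
    cls2 <- classify_reads(reads, gi, same)
    expect_true(all(cls2$category %in% c("both", "neither")))
})

test_that("mate pairs classify on the k-mer union and short reads fall to neither", {
    g <- random_genome(500, seed = 1, name = "g")
    h <- random_genome(500, seed = 2, name = "h")
    gi <- build_kmer_index(g, 25); hi <- build_kmer_index(h, 25)
    # mate 1 graft-specific, mate 2 host-specific -> ambiguous pair
    cls <- classify_reads(substring(g, 1, 60), gi, hi,
                          mates = substring(h, 1, 60))
    expect_equal(cls$category, "ambiguous")
    expect_message(cls_short <- classify_reads(c(x = "ACGTACGT"), gi, hi),
                   "shorter than k")
    expect_equal(cls_short$category, "neither")
    expect_equal(attr(cls_short, "n_short"), 1)
})

test_that("index swap exchanges graft and host and fixes the other categories", {
    refs <- simulate_references(length = 3000, divergence = 0.05, seed = 8)
    gi <- build_kmer_index(refs$graft, 25, "graft")
    hi <- build_kmer_index(refs$host, 25, "host")
    sim <- simulate_two_genome_reads(refs$graft, refs$host, 400, 0.3, 80,
                                     seed = 12)
    a <- classify_reads(sim$reads, gi, hi)
    b <- classify_reads(sim$reads, hi, gi)
    swap <- c(graft = "host", host = "graft", both = "both",
              neither = "neither", ambiguous = "ambiguous")
    expect_identical(unname(swap[a$category]), b$category)
})

test_that("batch summary proportions sum to one and host exclusion retains the rest", {
    refs <- simulate_references(length = 3000, divergence = 0.05, seed = 9)
    gi <- build_kmer_index(refs$graft, 25); hi <- build_kmer_index(refs$host, 25)
    sim <- simulate_two_genome_reads(refs$graft, refs$host, 500, 0.1, 80, seed = 3)
    cls <- classify_reads(sim$reads, gi, hi)
    sm <- classify_batch(cls)
    expect_equal(sum(sm$proportion), 1)
    kept <- exclude_host(sim$reads, cls)
    expect_setequal(names(kept),
                    cls$read_id[cls$category != "host"])
    # all-graft input: nothing removed
    g_only <- sim$reads[sim$truth$origin == "graft"]
    kept_g <- exclude_host(g_only, cls)
    expect_length(kept_g, length(g_only))
    expect_error(exclude_host(c(zzz = "ACGT"), cls), "no classification")
    # empty read set: empty summary, no error
    empty <- classify_reads(character(0), gi, hi)
    expect_equal(nrow(empty), 0)
    expect_equal(sum(classify_batch(empty)$n), 0)
})

test_that("no specific-evidence leakage from diverged references at zero error", {
    refs <- simulate_references(length = 5000, divergence = 0.05, seed = 14)
    gi <- build_kmer_index(refs$graft, 25); hi <- build_kmer_index(refs$host, 25)
    sim <- simulate_two_genome_reads(refs$graft, refs$host, 2000, 0.2, 100,
                                     error_rate = 0, seed = 15)
    cls <- classify_reads(sim$reads, gi, hi)
    host_truth <- sim$truth$origin == "host"
    expect_equal(sum(host_truth & cls$category == "graft"), 0)
    expect_equal(sum(!host_truth & cls$category == "host"), 0)
})
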