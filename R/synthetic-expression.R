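# Synthetic splice-junction reads and correlated expression profiles.

#' Simulate splice-junction read counts
#'
#' Junction-spanning read counts are multinomial over the defined junctions
#' plus a remainder bucket of other splice reads, given per-junction
#' proportions of the sample's total splice reads. A read-level table is also
#' emitted: each planted read's donor end and acceptor start are drawn
#' uniformly inside the defining exons, plus background spliced reads at
#' unrelated coordinates, so junction counting can be exercised from reads.
#'
#' @param junctions junction definition data frame (see
#'   [junction_definition()]).
#' @param proportions per-junction proportions of total splice reads; sum
#'   must be <= 1.
#' @param total_splice_reads total splice reads in the sample.
#' @param n_background background spliced reads to add to the read table.
#' @param exact if TRUE, counts are rounded expectations rather than
#'   multinomial draws.
#' @param seed integer seed.
#' @return list with `counts` (junction, count), `total_splice_reads`, and
#'   `reads` (chrom, donor_end, acceptor_start per spliced read).
#' @export
simulate_junction_reads <- function(junctions, proportions, total_splice_reads,
                                    n_background = 500, exact = FALSE, seed = 1) {
    if (total_splice_reads < 0) stop("total_splice_reads must be non-negative")
    if (any(proportions < 0) || sum(proportions) > 1 + 1e-12)
        stop("proportions must be non-negative and sum to <= 1")
    stopifnot(nrow(junctions) == length(proportions))
    set.seed(seed)
    if (exact) {
        counts <- round(proportions * total_splice_reads)
    } else {
        p <- c(proportions, 1 - sum(proportions))
        draw <- rmultinom(1, total_splice_reads, p)[, 1]
        counts <- draw[seq_along(proportions)]
    }
    reads <- list()
    for (j in seq_len(nrow(junctions))) {
        if (counts[j] == 0) next
        jd <- junctions[j, ]
        reads[[j]] <- data.frame(
            chrom = jd$chrom,
            donor_end = sample(seq(jd$donor_start, jd$donor_end), counts[j],
                               replace = TRUE),
            acceptor_start = sample(seq(jd$acceptor_start, jd$acceptor_end),
                                    counts[j], replace = TRUE),
            stringsAsFactors = FALSE)
    }
    if (n_background > 0) {
        bg_start <- sample.int(1e6, n_background) + 2e8
        reads[[length(reads) + 1]] <- data.frame(
            chrom = "chr1", donor_end = bg_start,
            acceptor_start = bg_start + sample(100:10000, n_background,
                                               replace = TRUE),
            stringsAsFactors = FALSE)
    }
    reads <- if (length(reads) > 0) do.call(rbind, reads)
             else data.frame(chrom = character(0), donor_end = integer(0),
                             acceptor_start = integer(0))
    list(counts = data.frame(junction = junctions$name, count = counts,
                             stringsAsFactors = FALSE),
         total_splice_reads = total_splice_reads,
         reads = reads)
}

#' Simulate a correlated expression profile pair
#'
#' Log10 expression is bivariate normal with the target Pearson correlation;
#' a planted fraction of genes receives a fold change of `de_fold` (up or
#' down) in the second sample. Counts are Poisson around the implied
#' expected counts given gene lengths and library sizes, so RPKM computed
#' downstream recovers the planted profile.
#'
#' @param n_genes number of genes.
#' @param correlation target Pearson correlation of log10 RPKM in `[-1, 1]`.
#' @param fold_changed_fraction fraction of genes planted as fold-changed.
#' @param seed integer seed.
#' @param de_fold planted fold change (> 1).
#' @param up_share fraction of planted genes that go up in sample 2.
#' @param mean_log10,sd_log10 location/scale of baseline log10 RPKM.
#' @param lib_size total mapped reads per sample.
#' @param count_noise if FALSE, counts are exact expectations.
#' @return list with `counts` (genes x 2 matrix), `lengths`, `totals`,
#'   and `truth` (per-gene DE status: "up", "down" or "none").
#' @export
simulate_expression <- function(n_genes = 5000, correlation = 0.93,
                                fold_changed_fraction = 0, seed = 1,
                                de_fold = 4, up_share = 0.6,
                                mean_log10 = 1, sd_log10 = 0.6,
                                lib_size = 2e7, count_noise = TRUE) {
    if (correlation < -1 || correlation > 1)
        stop("correlation must be in [-1, 1]")
    set.seed(seed)
    z <- rnorm(n_genes)
    e <- rnorm(n_genes)
    la <- mean_log10 + sd_log10 * z
    lb <- mean_log10 + sd_log10 * (correlation * z + sqrt(1 - correlation^2) * e)
    de <- rep("none", n_genes)
    n_de <- round(fold_changed_fraction * n_genes)
    if (n_de > 0) {
        idx <- sample.int(n_genes, n_de)
        up <- idx[seq_len(round(up_share * n_de))]
        down <- setdiff(idx, up)
        lb[up] <- la[up] + log10(de_fold)
        lb[down] <- la[down] - log10(de_fold)
        de[up] <- "up"; de[down] <- "down"
    }
    lengths <- sample(500:5000, n_genes, replace = TRUE)
    rpkm_a <- 10^la
    rpkm_b <- 10^lb
    mu_a <- rpkm_a * lengths * lib_size / 1e9
    mu_b <- rpkm_b * lengths * lib_size / 1e9
    counts <- cbind(A = if (count_noise) rpois(n_genes, mu_a) else round(mu_a),
                    B = if (count_noise) rpois(n_genes, mu_b) else round(mu_b))
    rownames(counts) <- sprintf("gene_%05d", seq_len(n_genes))
    list(counts = counts,
         lengths = setNames(lengths, rownames(counts)),
         totals = c(A = lib_size, B = lib_size),
         truth = data.frame(gene = rownames(counts), de = de,
                            stringsAsFactors = FALSE))
}

#' Simulate a multi-sample cohort expression matrix
#'
#' The two visits share a common tumor profile up to a small biological
#' drift plus the planted differential expression (sequential biopsies of
#' one tumor are near-replicates apart from treatment effects). Patient
#' samples track their visit profile closely; PDX samples carry additional
#' graft noise calibrated so the patient-to-PDX log10-RPKM Pearson
#' correlation hits the configured target. Each PDX inherits its parent
#' visit's profile.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples), `lengths`, `totals`,
#'   `truth`.
#' @export
simulate_expression_cohort <- function(config, seed = config$seed + 3L) {
    set.seed(seed)
    samples <- config$samples[config$samples$role != "germline", ]
    n_genes <- config$n_genes
    mean_log10 <- 1; sd_log10 <- 0.6
    r_patient <- 0.998                       # patient sample vs visit profile
    r_drift <- 0.998                         # visit 2 vs visit 1 profile
    r_pdx <- min(1, config$expression_correlation / r_patient)

    # planted DE between visit profiles
    de <- rep("none", n_genes)
    shift <- rep(0, n_genes)
    n_de <- round(config$fold_changed_fraction * n_genes)
    if (n_de > 0) {
        idx <- sample.int(n_genes, n_de)
        up <- idx[seq_len(round(config$de_up_share * n_de))]
        down <- setdiff(idx, up)
        shift[up] <- log10(config$de_fold)
        shift[down] <- -log10(config$de_fold)
        de[up] <- "up"; de[down] <- "down"
    }
    z1 <- rnorm(n_genes)
    z2 <- if (config$exact) z1
          else r_drift * z1 + sqrt(1 - r_drift^2) * rnorm(n_genes)
    latent <- list(`1` = z1, `2` = z2 + shift / sd_log10)
    lengths <- sample(500:5000, n_genes, replace = TRUE)
    lib_size <- 2e7
    counts <- matrix(0, n_genes, nrow(samples),
                     dimnames = list(sprintf("gene_%05d", seq_len(n_genes)),
                                     samples$id))
    for (i in seq_len(nrow(samples))) {
        zv <- latent[[as.character(samples$visit[i])]]
        r <- if (samples$role[i] == "pdx") r_pdx else r_patient
        if (config$exact) r <- 1
        lx <- mean_log10 +
            sd_log10 * (r * zv + sqrt(1 - r^2) * rnorm(n_genes))
        mu <- 10^lx * lengths * lib_size / 1e9
        counts[, i] <- if (config$exact) round(mu) else rpois(n_genes, mu)
    }
    list(counts = counts,
         lengths = setNames(lengths, rownames(counts)),
         totals = setNames(rep(lib_size, ncol(counts)), colnames(counts)),
         truth = data.frame(gene = rownames(counts), de = de,
                            stringsAsFactors = FALSE))
}
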