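# Synthetic paired patient/PDX cohort with full ground truth.
#
# The default configuration emulates a serially sampled metastatic prostate
# tumor study: one germline blood sample, two patient tumor biopsies taken
# before and after treatment (visits 1 and 2), and ten PDX models derived
# from those biopsies over two mouse generations. Three subclones persist at
# stable cellular prevalences across all tumor samples; tumor purity is 0.75
# and 0.76 in the two biopsies and higher in the PDXs (engraftment strips
# human stroma, and mouse stroma is removed as host reads).

#' Default cohort sample sheet
#'
#' One germline, two patient visits, ten PDXs (six derived from visit 1 and
#' four from visit 2, across two mouse generations).
#'
#' @return data frame with `id`, `role`, `visit`, `parent`.
#' @export
default_sample_sheet <- function() {
    data.frame(
        id = c("BL", "V1", "V2",
               "V1_PDX_A", "V1_PDX_B", "V1_PDX_C",
               "V1_PDX_AA", "V1_PDX_BA", "V1_PDX_CA",
               "V2_PDX_A", "V2_PDX_AA1", "V2_PDX_AA2", "V2_PDX_AB"),
        role = c("germline", "patient", "patient", rep("pdx", 10)),
        visit = c(NA, 1, 2, rep(1, 6), rep(2, 4)),
        parent = c(NA, NA, NA, rep("V1", 6), rep("V2", 4)),
        stringsAsFactors = FALSE
    )
}

#' Cohort simulation configuration
#'
#' Collects every knob of the synthetic cohort. Defaults describe the study
#' conditions the package is designed around: 3 subclones at stable
#' prevalences (clonal plus two subclonal populations), purity 0.75/0.76 in
#' the patient biopsies and 0.98 in PDXs, 8% host read contamination, a
#' PDX-private false-call rate of 0.5, an AR-like 39-copy focal amplification
#' and a TP53-like broad single-copy loss, and an expression correlation
#' target of 0.93 between samples.
#'
#' @param n_subclones number of subclones.
#' @param clone_prevalence K-vector (recycled per tumor sample) or K x sample
#'   matrix of cellular prevalences in `[0, 1]`.
#' @param clone_fractions fraction of somatic variants belonging to each
#'   clone; sums to 1.
#' @param purity named per-tumor-sample purity, or NULL for defaults.
#' @param n_variants number of true somatic variants.
#' @param mean_depth mean sequencing depth at variant loci.
#' @param min_alt_reads minimum alt reads for a variant to be "called".
#' @param host_contamination host (mouse) read fraction in PDX read sets.
#' @param pdx_private_rate expected PDX-private false calls per true variant.
#' @param samples sample sheet (see [default_sample_sheet()]).
#' @param copy_events data frame `chrom`, `start`, `end`, `tumor_copies`.
#' @param intervals_per_chrom named integer vector of 120 bp capture
#'   intervals per chromosome.
#' @param interval_width capture interval width (bp).
#' @param coverage_depth mean reads per interval in coverage simulation.
#' @param dispersion gamma-Poisson overdispersion of interval coverage.
#' @param gc_bias_amplitude scale of the per-sample smooth GC bias.
#' @param n_reference_profiles number of germline-like coverage references.
#' @param n_genes genes in the expression matrix.
#' @param expression_correlation target patient/PDX Pearson correlation of
#'   log10 RPKM.
#' @param fold_changed_fraction fraction of genes planted as >= `de_fold`
#'   fold-changed between visits.
#' @param de_fold planted fold-change effect size.
#' @param de_up_share fraction of planted DE genes that are up-regulated.
#' @param junction_proportions matrix (junction x sample) of splice-read
#'   proportions, or NULL for AR-V7/AR-FL defaults with a 6.25 / 4.71 visit-1
#'   to visit-2 ratio.
#' @param total_splice_reads total splice reads per sample.
#' @param n_reads_per_pdx reads simulated per PDX for classification.
#' @param read_len read length.
#' @param read_error_rate per-base sequencing error rate.
#' @param reference_length length of the classification reference sequences.
#' @param reference_divergence graft/host per-base divergence.
#' @param impact_probs,p_1000g,p_esp,p_dbsnp,p_exonic,germline_probs,p_chrx,p_chrm,p_nonunique
#'   annotation proportions for simulated variants.
#' @param exact if TRUE, depths and read counts are deterministic expected
#'   values (no Poisson/binomial noise) — the identity cohort.
#' @param seed integer seed; fully determines all outputs.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subclones = 3,
                          clone_prevalence = c(1.0, 0.53, 0.21),
                          clone_fractions = c(0.5, 0.3, 0.2),
                          purity = NULL,
                          n_variants = 200,
                          mean_depth = 100,
                          min_alt_reads = 2,
                          host_contamination = 0.08,
                          pdx_private_rate = 0.5,
                          samples = default_sample_sheet(),
                          copy_events = NULL,
                          intervals_per_chrom = c(chr1 = 800, chr2 = 600, chr3 = 600),
                          interval_width = 120,
                          coverage_depth = 100,
                          dispersion = 0.02,
                          gc_bias_amplitude = 0.2,
                          n_reference_profiles = 4,
                          n_genes = 5000,
                          expression_correlation = 0.93,
                          fold_changed_fraction = 0.04,
                          de_fold = 4,
                          de_up_share = 0.6,
                          junction_proportions = NULL,
                          total_splice_reads = 1e6,
                          n_reads_per_pdx = 2000,
                          read_len = 100,
                          read_error_rate = 0.001,
                          reference_length = 20000,
                          reference_divergence = 0.05,
                          impact_probs = c(HIGH = 0.15, MODERATE = 0.60,
                                           LOW = 0.15, MODIFIER = 0.10),
                          p_1000g = 0.05, p_esp = 0.04, p_dbsnp = 0.10,
                          p_exonic = 0.90,
                          germline_probs = c(`0` = 0.90, `1` = 0.07, `2` = 0.03),
                          p_chrx = 0.04, p_chrm = 0.01, p_nonunique = 0.03,
                          exact = FALSE,
                          seed = 7) {
    tumor_ids <- samples$id[samples$role != "germline"]
    if (is.null(purity)) {
        purity <- setNames(rep(0.98, length(tumor_ids)), tumor_ids)
        purity[samples$id[samples$role == "patient" & samples$visit == 1]] <- 0.75
        purity[samples$id[samples$role == "patient" & samples$visit == 2]] <- 0.76
    }
    if (is.null(dim(clone_prevalence))) {
        clone_prevalence <- matrix(rep(clone_prevalence, length(tumor_ids)),
                                   nrow = n_subclones,
                                   dimnames = list(NULL, tumor_ids))
    }
    if (is.null(copy_events)) {
        w <- interval_width
        copy_events <- data.frame(
            chrom = c("chr1", "chr3"),
            start = c(300L * w, 100L * w),
            end = c(320L * w, 400L * w),
            tumor_copies = c(39L, 1L),
            stringsAsFactors = FALSE
        )
    }
    cfg <- list(n_subclones = n_subclones, clone_prevalence = clone_prevalence,
                clone_fractions = clone_fractions, purity = purity,
                n_variants = n_variants, mean_depth = mean_depth,
                min_alt_reads = min_alt_reads,
                host_contamination = host_contamination,
                pdx_private_rate = pdx_private_rate, samples = samples,
                copy_events = copy_events,
                intervals_per_chrom = intervals_per_chrom,
                interval_width = interval_width,
                coverage_depth = coverage_depth, dispersion = dispersion,
                gc_bias_amplitude = gc_bias_amplitude,
                n_reference_profiles = n_reference_profiles,
                n_genes = n_genes,
                expression_correlation = expression_correlation,
                fold_changed_fraction = fold_changed_fraction,
                de_fold = de_fold, de_up_share = de_up_share,
                junction_proportions = junction_proportions,
                total_splice_reads = total_splice_reads,
                n_reads_per_pdx = n_reads_per_pdx, read_len = read_len,
                read_error_rate = read_error_rate,
                reference_length = reference_length,
                reference_divergence = reference_divergence,
                impact_probs = impact_probs, p_1000g = p_1000g, p_esp = p_esp,
                p_dbsnp = p_dbsnp, p_exonic = p_exonic,
                germline_probs = germline_probs, p_chrx = p_chrx,
                p_chrm = p_chrm, p_nonunique = p_nonunique,
                exact = exact, seed = as.integer(seed))
    class(cfg) <- "cohort_config"
    validate_cohort_config(cfg)
    cfg
}

#' Validate a cohort configuration
#'
#' Checks that all fractions lie in `[0, 1]` and that no diploid locus can be
#' pushed past the heterozygous VAF ceiling of 0.5.
#'
#' @param config a `cohort_config`.
#' @return the config, invisibly; errors on violation.
#' @export
validate_cohort_config <- function(config) {
    stopifnot(inherits(config, "cohort_config"))
    fr <- c(config$purity, as.vector(config$clone_prevalence),
            config$host_contamination, config$clone_fractions)
    if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
    if (abs(sum(config$clone_fractions) - 1) > 1e-8)
        stop("clone_fractions must sum to 1")
    tumor_ids <- colnames(config$clone_prevalence)
    for (s in tumor_ids) {
        vaf <- config$purity[[s]] * config$clone_prevalence[, s] / 2
        if (any(vaf > 0.5 + 1e-12))
            stop("config implies diploid VAF > 0.5 in sample ", s)
    }
    if (nrow(config$clone_prevalence) != config$n_subclones)
        stop("clone_prevalence must have n_subclones rows")
    invisible(config)
}

# genome coordinate space shared by variants and coverage intervals
.cohort_chrom_lengths <- function(config) {
    auto <- config$intervals_per_chrom * config$interval_width
    c(auto, chrX = 6000L, chrM = 2000L)
}

#' Simulate the cohort's somatic variant table
#'
#' Every true variant belongs to one subclone; in sample `s` with purity
#' `p_s` and clone prevalence `phi_ks`, its expected VAF on a diploid locus
#' is `p_s * phi_ks / 2` (adjusted for tumor copy number inside planted copy
#' events). Depths are Poisson around `mean_depth` and alt reads binomial.
#' Each PDX additionally receives private false calls at rate
#' `pdx_private_rate` per true variant, modeling residual host-read
#' contamination and clonal drift. Annotation fields (impact class,
#' population-database flags, dbSNP, exonic status, germline alt reads) are
#' drawn per the configured proportions; a small fraction of variants is
#' planted inside a duplicated genome segment so the flanking-window
#' uniqueness filter has true positives.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `variants` (long data frame, one row per variant x
#'   tumor sample carrying read counts, a `called` flag and annotations),
#'   `genome` (named character vector of synthetic chromosome sequences) and
#'   `truth` (per-variant clone labels, private-call provenance, planted
#'   uniqueness flags, plus the purity/prevalence used).
#' @export
simulate_variant_table <- function(config, seed = config$seed) {
    validate_cohort_config(config)
    set.seed(seed)
    chrom_len <- .cohort_chrom_lengths(config)
    bases <- c("A", "C", "G", "T")
    genome <- vapply(chrom_len, function(L)
        paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))

    # duplicated segment: copy chr1[2001..2600] onto the tail of chr2 so
    # windows inside it map twice at 100% identity
    dup_src <- c(2001L, 2600L)
    seg <- substring(genome[["chr1"]], dup_src[1], dup_src[2])
    L2 <- chrom_len[["chr2"]]
    substring(genome[["chr2"]], L2 - 700L, L2 - 700L + nchar(seg) - 1L) <- seg

    n <- config$n_variants
    tumor <- config$samples[config$samples$role != "germline", ]
    tumor_ids <- tumor$id

    # loci
    autos <- setdiff(names(chrom_len), c("chrX", "chrM"))
    p_auto <- (1 - config$p_chrx - config$p_chrm) / length(autos)
    chrom <- sample(names(chrom_len), n, replace = TRUE,
                    prob = c(rep(p_auto, length(autos)), config$p_chrx, config$p_chrm))
    pos <- integer(n)
    nonunique <- runif(n) < config$p_nonunique
    for (i in seq_len(n)) {
        if (nonunique[i]) {
            chrom[i] <- "chr1"
            pos[i] <- sample(seq(dup_src[1] + 60L, dup_src[2] - 60L), 1)
        } else {
            repeat {
                p <- sample(seq(200L, chrom_len[[chrom[i]]] - 200L), 1)
                # keep ordinary variants out of the duplicated copies
                in_dup <- (chrom[i] == "chr1" && p >= dup_src[1] && p <= dup_src[2]) ||
                          (chrom[i] == "chr2" && p >= L2 - 700L && p <= L2 - 700L + 600L)
                if (!in_dup) { pos[i] <- p; break }
            }
        }
    }
    key_seen <- paste(chrom, pos)
    dup_loci <- duplicated(key_seen)
    while (any(dup_loci)) {
        for (i in which(dup_loci))
            pos[i] <- sample(seq(200L, chrom_len[[chrom[i]]] - 200L), 1)
        key_seen <- paste(chrom, pos)
        dup_loci <- duplicated(key_seen)
    }
    ref <- substring(genome[chrom], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)

    clone <- sample.int(config$n_subclones, n, replace = TRUE,
                        prob = config$clone_fractions)
    impact <- sample(names(config$impact_probs), n, replace = TRUE,
                     prob = config$impact_probs)
    in_1000g <- runif(n) < config$p_1000g
    in_1000g_eur <- in_1000g & runif(n) < 0.6
    in_1000g_afr <- in_1000g & runif(n) < 0.4
    in_esp <- runif(n) < config$p_esp
    in_dbsnp <- runif(n) < config$p_dbsnp
    exonic <- runif(n) < config$p_exonic
    germ <- as.integer(sample(names(config$germline_probs), n, replace = TRUE,
                              prob = config$germline_probs))
    callers <- c("SomaticSniper", "JointSNVMix2", "MuTect")
    caller <- vapply(seq_len(n), function(i)
        paste(sort(sample(callers, sample(1:3, 1))), collapse = ";"), character(1))

    # copy number at each locus (tumor copies; diploid elsewhere)
    copies <- rep(2L, n)
    for (e in seq_len(nrow(config$copy_events))) {
        ev <- config$copy_events[e, ]
        hit <- chrom == ev$chrom & pos > ev$start & pos <= ev$end
        copies[hit] <- ev$tumor_copies
    }

    rows <- vector("list", length(tumor_ids) + 1)
    for (si in seq_along(tumor_ids)) {
        s <- tumor_ids[si]
        p <- config$purity[[s]]
        phi <- config$clone_prevalence[clone, s]
        vaf <- ifelse(copies == 2L,
                      p * phi / 2,
                      p * phi / (p * copies + (1 - p) * 2))
        if (config$exact) {
            depth <- rep(config$mean_depth, n)
            alt_reads <- round(vaf * depth)
        } else {
            depth <- rpois(n, config$mean_depth)
            alt_reads <- rbinom(n, depth, vaf)
        }
        rows[[si]] <- data.frame(
            chrom = chrom, pos = pos, ref = ref, alt = alt, sample = s,
            alt_reads = alt_reads, ref_reads = depth - alt_reads,
            called = alt_reads >= config$min_alt_reads,
            impact = impact, exonic = exonic,
            in_1000g = in_1000g, in_1000g_eur = in_1000g_eur,
            in_1000g_afr = in_1000g_afr, in_esp = in_esp, in_dbsnp = in_dbsnp,
            germline_alt_reads = germ, caller = caller,
            stringsAsFactors = FALSE)
    }

    # PDX-private false calls
    pdx_ids <- tumor$id[tumor$role == "pdx"]
    priv_rows <- list()
    priv_truth <- list()
    for (s in pdx_ids) {
        n_priv <- if (config$exact) round(config$pdx_private_rate * n)
                  else rpois(1, config$pdx_private_rate * n)
        if (n_priv == 0) next
        pchrom <- sample(autos, n_priv, replace = TRUE)
        ppos <- vapply(pchrom, function(cc)
            sample(seq(200L, chrom_len[[cc]] - 200L), 1), integer(1),
            USE.NAMES = FALSE)
        pref <- substring(genome[pchrom], ppos, ppos)
        palt <- vapply(pref, function(r) sample(setdiff(bases, r), 1), character(1),
                       USE.NAMES = FALSE)
        pvaf <- runif(n_priv, 0.10, 0.40)
        pdepth <- if (config$exact) rep(config$mean_depth, n_priv)
                  else rpois(n_priv, config$mean_depth)
        palt_reads <- pmax(if (config$exact) round(pvaf * pdepth)
                           else rbinom(n_priv, pdepth, pvaf), config$min_alt_reads)
        priv_rows[[s]] <- data.frame(
            chrom = pchrom, pos = ppos, ref = pref, alt = palt, sample = s,
            alt_reads = palt_reads, ref_reads = pdepth - palt_reads,
            called = TRUE,
            impact = sample(c("HIGH", "MODERATE"), n_priv, replace = TRUE),
            exonic = TRUE, in_1000g = FALSE, in_1000g_eur = FALSE,
            in_1000g_afr = FALSE, in_esp = FALSE, in_dbsnp = FALSE,
            germline_alt_reads = 0L,
            caller = sample(callers, n_priv, replace = TRUE),
            stringsAsFactors = FALSE)
        priv_truth[[s]] <- data.frame(
            key = variant_key(pchrom, ppos, pref, palt),
            clone = 0L, private_in = s, nonunique = FALSE,
            stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                                 priv_rows))
    rownames(variants) <- NULL

    truth_variants <- rbind(
        data.frame(key = variant_key(chrom, pos, ref, alt), clone = clone,
                   private_in = NA_character_, nonunique = nonunique,
                   stringsAsFactors = FALSE),
        do.call(rbind, priv_truth))
    list(variants = variants, genome = genome,
         truth = list(variants = truth_variants,
                      purity = config$purity,
                      clone_prevalence = config$clone_prevalence))
}

#' Per-sample sets of called variant keys
#'
#' @param variants long variant table (from [simulate_variant_table()] or a
#'   filter chain) with `sample` and `called` columns; rows lacking a
#'   `called` column are treated as called.
#' @return named list of character vectors of variant keys.
#' @export
mutation_sets <- function(variants) {
    called <- if ("called" %in% names(variants)) variants$called else TRUE
    v <- variants[called, , drop = FALSE]
    split(variant_key(v), v$sample)
}
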