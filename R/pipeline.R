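# End-to-end cohort simulation and fidelity pipeline.

#' Simulate a complete paired patient/PDX cohort
#'
#' Generates, under one seed, every input the fidelity pipeline consumes:
#' the somatic variant table with annotations and germline counts, the
#' synthetic genome it lives on, graft/host classification references and
#' per-PDX read sets, the capture interval grid with germline reference and
#' tumor coverage profiles (with planted copy events), a gene annotation,
#' splice-junction reads for the AR-V7/AR-FL junctions, and a correlated
#' expression matrix — plus the full ground truth, kept separate from the
#' pipeline inputs.
#'
#' @param config a [cohort_config()].
#' @return object of class `pdx_cohort`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
    validate_cohort_config(config)
    base <- config$seed
    samples <- config$samples
    tumor_ids <- samples$id[samples$role != "germline"]
    pdx_ids <- samples$id[samples$role == "pdx"]

    vt <- simulate_variant_table(config, seed = base)

    refs <- simulate_references(n_chrom = 1, length = config$reference_length,
                                divergence = config$reference_divergence,
                                seed = base + 1L)
    reads <- list()
    for (i in seq_along(pdx_ids)) {
        reads[[pdx_ids[i]]] <- simulate_two_genome_reads(
            refs$graft, refs$host, config$n_reads_per_pdx,
            config$host_contamination, config$read_len,
            config$read_error_rate, seed = base + 100L + i)
    }

    intervals <- make_intervals(config$intervals_per_chrom,
                                config$interval_width, seed = base + 2L)
    genes <- make_genes(intervals)
    cov_refs <- lapply(seq_len(config$n_reference_profiles), function(i)
        simulate_coverage(intervals, NULL, purity = 1,
                          depth = config$coverage_depth,
                          dispersion = config$dispersion,
                          gc_bias_amplitude = config$gc_bias_amplitude,
                          exact = config$exact, seed = base + 200L + i)$profile)
    cov_tumors <- list()
    cov_truth <- NULL
    for (i in seq_along(tumor_ids)) {
        s <- tumor_ids[i]
        sim <- simulate_coverage(intervals, config$copy_events,
                                 purity = config$purity[[s]],
                                 depth = config$coverage_depth,
                                 dispersion = config$dispersion,
                                 gc_bias_amplitude = config$gc_bias_amplitude,
                                 exact = config$exact, seed = base + 300L + i)
        cov_tumors[[s]] <- sim$profile
        cov_truth <- sim$truth  # copies identical across tumor samples
    }

    junctions <- ar_junctions()
    prop <- config$junction_proportions
    if (is.null(prop)) {
        visit <- samples$visit[match(tumor_ids, samples$id)]
        prop <- rbind(
            `AR-V7` = ifelse(visit == 1, 50e-6, 8e-6),
            `AR-FL` = ifelse(visit == 1, 120e-6, 120e-6 / 4.71))
        colnames(prop) <- tumor_ids
    }
    splice <- list()
    for (i in seq_along(tumor_ids)) {
        s <- tumor_ids[i]
        splice[[s]] <- simulate_junction_reads(
            junctions, prop[, s], config$total_splice_reads,
            exact = config$exact, seed = base + 400L + i)
    }

    expression <- simulate_expression_cohort(config, seed = base + 3L)

    structure(list(
        config = config,
        samples = samples,
        variants = vt$variants,
        genome = vt$genome,
        class_references = refs,
        reads = lapply(reads, `[[`, "reads"),
        intervals = intervals,
        genes = genes,
        coverage = list(references = cov_refs, tumors = cov_tumors),
        junctions = junctions,
        splice = splice,
        expression = expression[c("counts", "lengths", "totals")],
        truth = list(variants = vt$truth$variants,
                     purity = vt$truth$purity,
                     clone_prevalence = vt$truth$clone_prevalence,
                     read_origin = lapply(reads, `[[`, "truth"),
                     coverage = cov_truth,
                     junction_proportions = prop,
                     expression_de = expression$truth)
    ), class = "pdx_cohort")
}

#' Tile the interval grid into a gene annotation
#'
#' Consecutive capture intervals are grouped into genes (default 5 intervals,
#' i.e. 600 bp, per gene) so CNV calls can be summarized at gene level.
#'
#' @param intervals interval grid.
#' @param intervals_per_gene intervals per gene.
#' @return data frame `chrom`, `start`, `end`, `gene` (0-based half-open).
#' @export
make_genes <- function(intervals, intervals_per_gene = 5) {
    out <- lapply(unique(intervals$chrom), function(cc) {
        iv <- intervals[intervals$chrom == cc, ]
        grp <- (seq_len(nrow(iv)) - 1L) %/% intervals_per_gene
        data.frame(chrom = cc,
                   start = tapply(iv$start, grp, min),
                   end = tapply(iv$end, grp, max),
                   gene = sprintf("%s_g%04d", cc, unique(grp) + 1L),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Configuration of the noise-free identity cohort
#'
#' Every stochastic component is switched off: no host contamination, no
#' PDX-private calls, exact expected read counts, flat GC bias, no
#' dispersion, no planted differential expression and no sequencing errors.
#' On this cohort the pipeline must report recall = precision = 1,
#' correlation = 1 and zero DE calls.
#'
#' @param seed integer seed.
#' @param ... further overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
identity_cohort_config <- function(seed = 7, ...) {
    cohort_config(host_contamination = 0, pdx_private_rate = 0,
                  read_error_rate = 0, dispersion = 0,
                  gc_bias_amplitude = 0, fold_changed_fraction = 0,
                  exact = TRUE, seed = seed, ...)
}

# ---------------------------------------------------------------------------
# Cohort serialization and the manifest

#' Write a cohort to disk with a manifest
#'
#' Serializes every pipeline input as plain text (TSV/FASTA/BED) under `dir`
#' and writes `manifest.yaml` describing samples, lineage and file paths.
#' Ground truth goes under `truth/` and is not referenced by the manifest.
#'
#' @param cohort a `pdx_cohort`.
#' @param dir output directory (created if needed).
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
    stopifnot(inherits(cohort, "pdx_cohort"))
    for (d in c("", "reads", "coverage", "splice", "expression", "truth"))
        dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)

    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$genome),
                                file.path(dir, "genome.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$class_references$graft),
                                file.path(dir, "graft_ref.fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$class_references$host),
                                file.path(dir, "host_ref.fa"))
    write_variant_tsv(cohort$variants, file.path(dir, "variants.tsv"))
    write_variant_vcf(cohort$variants, file.path(dir, "variants.vcf"))
    write_bed(cohort$intervals, file.path(dir, "intervals.bed"))
    write_bed(cohort$genes, file.path(dir, "genes.bed"))
    write_tsv(cohort$junctions, file.path(dir, "junctions.tsv"))

    manifest <- list(
        genome = "genome.fa", graft_reference = "graft_ref.fa",
        host_reference = "host_ref.fa", variants = "variants.tsv",
        intervals = "intervals.bed", genes = "genes.bed",
        junctions = "junctions.tsv",
        samples = lapply(seq_len(nrow(cohort$samples)), function(i)
            as.list(cohort$samples[i, ])),
        params = list(seed = cohort$config$seed),
        coverage_references = character(0),
        coverage = list(), reads = list(), splice_reads = list(),
        splice_totals = list(),
        expression = list(counts = "expression/counts.tsv",
                          lengths = "expression/lengths.tsv",
                          totals = "expression/totals.tsv"))

    for (i in seq_along(cohort$coverage$references)) {
        p <- sprintf("coverage/reference_%02d.tsv", i)
        write_tsv(cohort$coverage$references[[i]], file.path(dir, p))
        manifest$coverage_references <- c(manifest$coverage_references, p)
    }
    for (s in names(cohort$coverage$tumors)) {
        p <- sprintf("coverage/%s.tsv", s)
        write_tsv(cohort$coverage$tumors[[s]], file.path(dir, p))
        manifest$coverage[[s]] <- p
    }
    for (s in names(cohort$reads)) {
        p <- sprintf("reads/%s.fa", s)
        write_reads_fasta(cohort$reads[[s]], file.path(dir, p))
        manifest$reads[[s]] <- p
    }
    for (s in names(cohort$splice)) {
        p <- sprintf("splice/%s.tsv", s)
        write_tsv(cohort$splice[[s]]$reads, file.path(dir, p))
        manifest$splice_reads[[s]] <- p
        manifest$splice_totals[[s]] <- cohort$splice[[s]]$total_splice_reads
    }
    write_tsv(data.frame(gene = rownames(cohort$expression$counts),
                         cohort$expression$counts, check.names = FALSE),
              file.path(dir, "expression/counts.tsv"))
    write_tsv(data.frame(gene = names(cohort$expression$lengths),
                         length = cohort$expression$lengths),
              file.path(dir, "expression/lengths.tsv"))
    write_tsv(data.frame(sample = names(cohort$expression$totals),
                         total = cohort$expression$totals),
              file.path(dir, "expression/totals.tsv"))

    write_tsv(cohort$truth$variants, file.path(dir, "truth/variants.tsv"))
    write_tsv(cohort$truth$coverage, file.path(dir, "truth/coverage.tsv"))
    for (s in names(cohort$truth$read_origin))
        write_tsv(cohort$truth$read_origin[[s]],
                  file.path(dir, sprintf("truth/reads_%s.tsv", s)))

    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    invisible(file.path(dir, "manifest.yaml"))
}

#' Load a cohort from a manifest
#'
#' @param manifest path to a `manifest.yaml` written by [write_cohort()].
#' @return a `pdx_cohort` (without ground truth or configuration).
#' @export
read_cohort <- function(manifest) {
    m <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
    dir <- if (is.character(manifest)) dirname(manifest) else "."
    rp <- function(p) file.path(dir, p)
    samples <- do.call(rbind, lapply(m$samples, function(s)
        data.frame(id = s$id, role = s$role,
                   visit = s$visit %||% NA_integer_,
                   parent = s$parent %||% NA_character_,
                   stringsAsFactors = FALSE)))
    genome <- as.character(Biostrings::readDNAStringSet(rp(m$genome)))
    names(genome) <- sub(" .*", "", names(genome))
    read_cov <- function(p) read_tsv(rp(p), comment.char = "#")
    counts_df <- read_tsv(rp(m$expression$counts))
    counts <- as.matrix(counts_df[, -1, drop = FALSE])
    rownames(counts) <- counts_df$gene
    lengths_df <- read_tsv(rp(m$expression$lengths))
    totals_df <- read_tsv(rp(m$expression$totals))
    bed_cols <- c("chrom", "start", "end", "gc", "copies_in_pool")
    intervals <- read.delim(rp(m$intervals), header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    names(intervals) <- bed_cols[seq_len(ncol(intervals))]
    genes <- read.delim(rp(m$genes), header = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
    names(genes) <- c("chrom", "start", "end", "gene")
    structure(list(
        config = NULL, samples = samples,
        variants = read_variant_tsv(rp(m$variants)),
        genome = genome,
        class_references = list(
            graft = as.character(Biostrings::readDNAStringSet(rp(m$graft_reference))),
            host = as.character(Biostrings::readDNAStringSet(rp(m$host_reference)))),
        reads = lapply(m$reads, function(p)
            as.character(Biostrings::readDNAStringSet(rp(p)))),
        intervals = intervals, genes = genes,
        coverage = list(references = lapply(m$coverage_references, read_cov),
                        tumors = lapply(m$coverage, read_cov)),
        junctions = read_tsv(rp(m$junctions)),
        splice = {
            sp <- lapply(names(m$splice_reads), function(s)
                list(reads = read_tsv(rp(m$splice_reads[[s]])),
                     total_splice_reads = m$splice_totals[[s]]))
            names(sp) <- names(m$splice_reads)
            sp
        },
        expression = list(counts = counts,
                          lengths = setNames(lengths_df$length, lengths_df$gene),
                          totals = setNames(totals_df$total, totals_df$sample)),
        truth = NULL), class = "pdx_cohort")
}

#' Validate a cohort manifest
#'
#' Checks the structural invariants: exactly one germline sample, every PDX
#' has a lineage parent resolving to a patient sample, and (for file-backed
#' manifests) every referenced file exists.
#'
#' @param manifest path to `manifest.yaml`, a manifest list, or a
#'   `pdx_cohort`.
#' @return data frame of issues (zero rows when valid), with attribute
#'   `valid`.
#' @export
validate_manifest <- function(manifest) {
    issues <- character(0)
    dir <- "."
    if (inherits(manifest, "pdx_cohort")) {
        samples <- manifest$samples
        files <- character(0)
    } else {
        m <- if (is.character(manifest)) {
            dir <- dirname(manifest)
            tryCatch(yaml::read_yaml(manifest), error = function(e)
                stop("cannot parse manifest: ", conditionMessage(e)))
        } else manifest
        samples <- tryCatch(
            do.call(rbind, lapply(m$samples, function(s)
                data.frame(id = s$id, role = s$role,
                           visit = s$visit %||% NA_integer_,
                           parent = s$parent %||% NA_character_,
                           stringsAsFactors = FALSE))),
            error = function(e) NULL)
        if (is.null(samples))
            return(structure(data.frame(issue = "manifest has no usable samples block"),
                             valid = FALSE))
        files <- c(m$genome, m$graft_reference, m$host_reference, m$variants,
                   m$intervals, m$genes, m$junctions,
                   unlist(m$coverage_references), unlist(m$coverage),
                   unlist(m$reads), unlist(m$splice_reads),
                   unlist(m$expression))
    }
    n_germ <- sum(samples$role == "germline")
    if (n_germ == 0) issues <- c(issues, "no germline sample")
    if (n_germ > 1) issues <- c(issues, "duplicate germline samples")
    patients <- samples$id[samples$role == "patient"]
    for (i in which(samples$role == "pdx")) {
        p <- samples$parent[i]
        if (is.na(p) || !(p %in% patients))
            issues <- c(issues,
                        sprintf("PDX %s has a dangling lineage parent (%s)",
                                samples$id[i], p))
    }
    if (anyDuplicated(samples$id))
        issues <- c(issues, "duplicate sample ids")
    for (f in files) {
        if (is.character(f) && !file.exists(file.path(dir, f)))
            issues <- c(issues, sprintf("missing file: %s", f))
    }
    structure(data.frame(issue = issues, stringsAsFactors = FALSE),
              valid = length(issues) == 0)
}

# ---------------------------------------------------------------------------
# The pipeline

#' Run the full fidelity pipeline on a cohort
#'
#' Stages, in order: graft/host read classification and host removal;
#' variant filtering (reporting, concordance eligibility); recall/precision
#' and VAF concordance; exome CNV (GC correction, reference model, log2
#' ratios, segmentation, normalization, gene calls); subclone/purity
#' estimation across all tumor samples; splice-isoform SRPM and fold
#' changes; expression correlation and fold-change DE. Results are written
#' as TSV/JSON under `out_dir` together with a machine-readable run log.
#'
#' @param cohort a `pdx_cohort` or the path to a `manifest.yaml`.
#' @param out_dir output directory.
#' @param seed integer seed for the stochastic stages (segmentation
#'   permutations, EM restarts).
#' @param k k-mer length for read classification.
#' @param nperm,alpha,min_width segmentation parameters.
#' @param recenter_anchor anchor chromosome for cross-sample re-centering.
#' @param kmax maximum number of subclones tried.
#' @param top_n_vaf variants in the VAF concordance matrix.
#' @return the consolidated fidelity report (list), invisibly; the same
#'   content is written to `report.json`.
#' @export
run_pipeline <- function(cohort, out_dir, seed = 7L, k = 25, nperm = 1000,
                         alpha = 0.01, min_width = 3,
                         recenter_anchor = "chr2", kmax = 5, top_n_vaf = 60) {
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    val <- validate_manifest(cohort)
    if (!attr(val, "valid"))
        stop("invalid cohort manifest:\n  ", paste(val$issue, collapse = "\n  "))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seed)
    samples <- cohort$samples
    tumor_ids <- samples$id[samples$role != "germline"]
    pdx_ids <- samples$id[samples$role == "pdx"]
    patient_ids <- samples$id[samples$role == "patient"]
    v1 <- patient_ids[samples$visit[match(patient_ids, samples$id)] == 1][1]
    v2 <- patient_ids[samples$visit[match(patient_ids, samples$id)] == 2][1]
    outputs <- character(0)
    report <- list()

    # -- stage: read classification --------------------------------------
    if (length(cohort$reads) > 0) {
        graft_idx <- build_kmer_index(cohort$class_references$graft, k, "graft")
        host_idx <- build_kmer_index(cohort$class_references$host, k, "host")
        per_pdx <- list()
        for (s in names(cohort$reads)) {
            cls <- classify_reads(cohort$reads[[s]], graft_idx, host_idx)
            sm <- classify_batch(cls)
            sm$sample <- s
            per_pdx[[s]] <- sm
        }
        class_tab <- do.call(rbind, per_pdx)
        rownames(class_tab) <- NULL
        avg <- tapply(class_tab$proportion, class_tab$category, mean)
        avg <- avg[c("graft", "host", "both", "neither", "ambiguous")]
        write_tsv(class_tab, file.path(out_dir, "read_classification.tsv"))
        outputs <- c(outputs, "read_classification.tsv")
        report$read_classification <- list(per_sample = class_tab,
                                           average_proportions = as.list(avg))
    }

    # -- stage: variant filters ------------------------------------------
    called <- cohort$variants[cohort$variants$called %||% TRUE, , drop = FALSE]
    reported <- reporting_filter(called)
    eligible <- concordance_eligibility(called, cohort$genome)
    write_variant_tsv(reported, file.path(out_dir, "reported_variants.tsv"))
    outputs <- c(outputs, "reported_variants.tsv")
    report$filters <- list(
        n_called_rows = nrow(called),
        n_reported_rows = nrow(reported),
        reporting_exclusions = as.list(attr(reported, "exclusions")),
        n_concordance_eligible = length(eligible),
        concordance_exclusions = as.list(attr(eligible, "exclusions")))

    # -- stage: concordance ----------------------------------------------
    sets <- mutation_sets(called)
    sets <- lapply(sets, function(kk) kk[kk %in% eligible])
    lineage <- setNames(samples$parent[match(pdx_ids, samples$id)], pdx_ids)
    conc <- concordance_summary(sets[patient_ids], sets[pdx_ids], lineage)
    sel <- select_top_variants(called, eligible, patient_ids, top_n_vaf)
    vafm <- vaf_concordance(called, sel)
    write_tsv(conc$table, file.path(out_dir, "recall_precision.tsv"))
    write_tsv(data.frame(sample = rownames(vafm$vaf), vafm$vaf,
                         check.names = FALSE),
              file.path(out_dir, "vaf_matrix.tsv"))
    outputs <- c(outputs, "recall_precision.tsv", "vaf_matrix.tsv")
    report$concordance <- list(table = conc$table, aggregates = conc$aggregates,
                               vaf_n_variants = length(sel),
                               vaf_mean_sd = mean(vafm$score, na.rm = TRUE))

    # -- stage: CNV -------------------------------------------------------
    ref_corr <- lapply(cohort$coverage$references, gc_correct)
    model <- learn_reference_model(ref_corr)
    seg_list <- list()
    l2r_list <- list()
    for (s in names(cohort$coverage$tumors)) {
        corr <- gc_correct(cohort$coverage$tumors[[s]])
        l2r <- log2_ratio(corr, model)
        l2r_list[[s]] <- l2r
        seg_list[[s]] <- segment_cbs(l2r, alpha = alpha, nperm = nperm,
                                     min_width = min_width)
    }
    seg_list <- normalize_and_recenter(seg_list, recenter_anchor)
    gene_counts <- list()
    all_segs <- list()
    for (s in names(seg_list)) {
        res <- call_and_annotate(seg_list[[s]], cohort$genes)
        seg_s <- res$segments
        seg_s$sample <- s
        all_segs[[s]] <- seg_s
        gene_counts[[s]] <- data.frame(sample = s,
                                       n_amplified = res$counts[["n_amplified"]],
                                       n_deleted = res$counts[["n_deleted"]],
                                       stringsAsFactors = FALSE)
    }
    seg_tab <- do.call(rbind, all_segs)
    rownames(seg_tab) <- NULL
    gene_tab <- do.call(rbind, gene_counts)
    rownames(gene_tab) <- NULL
    write_tsv(seg_tab, file.path(out_dir, "cnv_segments.tsv"))
    write_tsv(gene_tab, file.path(out_dir, "cnv_gene_counts.tsv"))
    outputs <- c(outputs, "cnv_segments.tsv", "cnv_gene_counts.tsv")
    report$cnv <- list(gene_counts = gene_tab,
                       n_segments = as.list(table(seg_tab$sample)))

    # -- stage: clonality -------------------------------------------------
    clon_rows <- cohort$variants[cohort$variants$sample %in% tumor_ids, ,
                                 drop = FALSE]
    keys_called <- unique(variant_key(clon_rows[clon_rows$called %||% TRUE, ]))
    clon_rows <- clon_rows[variant_key(clon_rows) %in% keys_called, , drop = FALSE]
    # only keys observed in every tumor sample enter the joint model
    kc <- table(variant_key(clon_rows))
    full_keys <- names(kc)[kc == length(tumor_ids)]
    clon_rows <- clon_rows[variant_key(clon_rows) %in% full_keys, , drop = FALSE]
    elig <- purity_eligibility(clon_rows, segments = seg_tab,
                               reference = cohort$genome)
    ekeys <- unique(variant_key(elig))
    report$clonality <- list(n_eligible = length(ekeys))
    if (length(ekeys) >= 10) {
        alt <- matrix(0L, length(ekeys), length(tumor_ids),
                      dimnames = list(ekeys, tumor_ids))
        depth <- alt
        ek <- variant_key(elig)
        alt[cbind(match(ek, ekeys), match(elig$sample, tumor_ids))] <- elig$alt_reads
        depth[cbind(match(ek, ekeys), match(elig$sample, tumor_ids))] <-
            elig$alt_reads + elig$ref_reads
        model_sc <- select_k(alt, depth, K_max = kmax, seed = seed)
        traj <- clone_frequency_trajectories(model_sc, alt, depth, tumor_ids)
        write_tsv(traj, file.path(out_dir, "clone_trajectories.tsv"))
        write_tsv(data.frame(sample = names(model_sc$purity),
                             purity = model_sc$purity),
                  file.path(out_dir, "purity.tsv"))
        outputs <- c(outputs, "clone_trajectories.tsv", "purity.tsv")
        report$clonality <- c(report$clonality,
            list(K = model_sc$K,
                 purity = as.list(model_sc$purity),
                 bic_table = model_sc$score_table,
                 trajectories = traj))
    }

    # -- stage: splice isoforms ------------------------------------------
    if (length(cohort$splice) > 0) {
        srpm_rows <- list()
        for (s in names(cohort$splice)) {
            cnt <- count_junction_reads(cohort$splice[[s]]$reads, cohort$junctions)
            srpm_rows[[s]] <- data.frame(
                sample = s, junction = names(cnt), count = as.integer(cnt),
                srpm = srpm(cnt, cohort$splice[[s]]$total_splice_reads),
                stringsAsFactors = FALSE)
        }
        srpm_tab <- do.call(rbind, srpm_rows)
        rownames(srpm_tab) <- NULL
        fc <- list()
        for (j in unique(srpm_tab$junction)) {
            a <- srpm_tab$srpm[srpm_tab$sample == v1 & srpm_tab$junction == j]
            b <- srpm_tab$srpm[srpm_tab$sample == v2 & srpm_tab$junction == j]
            if (length(a) == 1 && length(b) == 1)
                fc[[j]] <- isoform_fold_change(a, b)
        }
        write_tsv(srpm_tab, file.path(out_dir, "srpm.tsv"))
        outputs <- c(outputs, "srpm.tsv")
        report$isoform <- list(srpm = srpm_tab, fold_change_v1_v2 = fc)
    }

    # -- stage: expression ------------------------------------------------
    rpkm_mat <- rpkm(cohort$expression$counts, cohort$expression$lengths,
                     cohort$expression$totals)
    pairs <- do.call(rbind, lapply(pdx_ids, function(x)
        c(samples$parent[match(x, samples$id)], x)))
    corr <- correlation_matrix(rpkm_mat, pairs)
    de <- fold_change_de(rpkm_mat[, v1], rpkm_mat[, v2])
    write_tsv(data.frame(sample = rownames(corr$matrix), corr$matrix,
                         check.names = FALSE),
              file.path(out_dir, "correlation_matrix.tsv"))
    write_tsv(data.frame(gene = names(de$ratio), ratio = de$ratio,
                         call = ifelse(names(de$ratio) %in% de$up, "up",
                               ifelse(names(de$ratio) %in% de$down, "down",
                                      "none"))),
              file.path(out_dir, "de_genes.tsv"))
    outputs <- c(outputs, "correlation_matrix.tsv", "de_genes.tsv")
    report$expression <- list(correlation_summary = as.list(corr$summary),
                              de_counts = as.list(de$counts))

    # -- consolidated report and run log ---------------------------------
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns")
    run_log <- list(package = "pdxfid",
                    version = as.character(packageVersion("pdxfid")),
                    seed = seed,
                    params = list(k = k, nperm = nperm, alpha = alpha,
                                  min_width = min_width,
                                  recenter_anchor = recenter_anchor,
                                  kmax = kmax, top_n_vaf = top_n_vaf),
                    outputs = c(outputs, "report.json"))
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(report)
}
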