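# Tumor-vs-xenograft somatic mutation concordance metrics.

#' Recall of a xenograft mutation set against the patient set
#'
#' `|P intersect X| / |P|`: the fraction of patient-tissue somatic mutations
#' rediscovered in the xenograft.
#'
#' @param P patient mutation keys (character vector; duplicates ignored).
#' @param X xenograft mutation keys.
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when `P` is empty.
#' @export
recall <- function(P, X) {
    P <- unique(P); X <- unique(X)
    if (length(P) == 0) {
        warning("recall undefined for empty patient set; returning NA")
        return(NA_real_)
    }
    sum(P %in% X) / length(P)
}

#' Precision of a xenograft mutation set against the patient set
#'
#' `|P intersect X| / |X|`: the fraction of xenograft calls also present in
#' the patient tissue.
#'
#' @inheritParams recall
#' @return fraction in `[0, 1]`, or `NA` (with a warning) when `X` is empty.
#' @export
precision <- function(P, X) {
    P <- unique(P); X <- unique(X)
    if (length(X) == 0) {
        warning("precision undefined for empty xenograft set; returning NA")
        return(NA_real_)
    }
    sum(X %in% P) / length(X)
}

#' Per-PDX recall/precision table with aggregates
#'
#' Pairs each PDX with its originating visit's patient mutation set and
#' reports recall and precision per PDX plus mean and median aggregates.
#'
#' @param patient_sets named list of patient mutation-key vectors (names are
#'   patient sample ids).
#' @param pdx_sets named list of PDX mutation-key vectors.
#' @param lineage named character vector mapping each PDX id to its patient
#'   sample id.
#' @return list with `table` (pdx, patient, recall, precision) and
#'   `aggregates` (mean/median of each metric).
#' @export
concordance_summary <- function(patient_sets, pdx_sets, lineage) {
    missing <- setdiff(names(pdx_sets), names(lineage))
    if (length(missing) > 0)
        stop("no lineage parent for PDX(s): ", paste(missing, collapse = ", "))
    bad <- setdiff(unname(lineage[names(pdx_sets)]), names(patient_sets))
    if (length(bad) > 0)
        stop("lineage points at unknown patient sample(s): ",
             paste(unique(bad), collapse = ", "))
    tab <- do.call(rbind, lapply(names(pdx_sets), function(x) {
        pt <- lineage[[x]]
        data.frame(pdx = x, patient = pt,
                   recall = recall(patient_sets[[pt]], pdx_sets[[x]]),
                   precision = precision(patient_sets[[pt]], pdx_sets[[x]]),
                   stringsAsFactors = FALSE)
    }))
    list(table = tab,
         aggregates = data.frame(
             metric = c("recall", "precision"),
             mean = c(mean(tab$recall, na.rm = TRUE),
                      mean(tab$precision, na.rm = TRUE)),
             median = c(median(tab$recall, na.rm = TRUE),
                        median(tab$precision, na.rm = TRUE)),
             stringsAsFactors = FALSE))
}

#' Select variants for the VAF concordance matrix
#'
#' Defaults to the top `n` eligible variants by total depth in the patient
#' samples.
#'
#' @param variants variant data frame (with `sample`, read counts).
#' @param eligible_keys keys passing [concordance_eligibility()].
#' @param patient_samples patient sample ids used for the depth ranking.
#' @param n number of variants to select.
#' @return character vector of selected keys.
#' @export
select_top_variants <- function(variants, eligible_keys, patient_samples, n = 60) {
    keys <- variant_key(variants)
    v <- variants[keys %in% eligible_keys & variants$sample %in% patient_samples, ]
    if (nrow(v) == 0) return(character(0))
    depth <- tapply(v$alt_reads + v$ref_reads, variant_key(v), sum)
    names(sort(depth, decreasing = TRUE))[seq_len(min(n, length(depth)))]
}

#' VAF concordance matrix
#'
#' Variant allele fraction per (sample x variant), with `NA` where a variant
#' was not called in a sample, plus a per-variant across-sample standard
#' deviation as the concordance score.
#'
#' @param variants variant data frame with `sample`, `alt_reads`,
#'   `ref_reads` and (optionally) `called`.
#' @param keys variant keys to include (columns of the matrix).
#' @return list with `vaf` (samples x variants matrix) and `score`
#'   (per-variant SD over samples where the variant was called).
#' @export
vaf_concordance <- function(variants, keys) {
    called <- if ("called" %in% names(variants)) variants$called else TRUE
    v <- variants[called, , drop = FALSE]
    vk <- variant_key(v)
    v <- v[vk %in% keys, , drop = FALSE]
    vk <- vk[vk %in% keys]
    samples <- sort(unique(v$sample))
    m <- matrix(NA_real_, length(samples), length(keys),
                dimnames = list(samples, keys))
    depth <- v$alt_reads + v$ref_reads
    vaf <- ifelse(depth > 0, v$alt_reads / depth, NA_real_)
    m[cbind(match(v$sample, samples), match(vk, keys))] <- vaf
    score <- apply(m, 2, function(col) {
        col <- col[!is.na(col)]
        if (length(col) < 2) NA_real_ else sd(col)
    })
    list(vaf = m, score = score)
}
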