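# Synthetic two-genome read simulation for testing graft/host classification.

#' Simulate a diverged graft/host reference pair
#'
#' Draws a random graft genome and derives the host genome from it by
#' independent per-base substitution, which leaves conserved stretches shared
#' by both references (the realistic situation for human/mouse exomes, where
#' conserved sequence produces "both" k-mers).
#'
#' @param n_chrom number of sequences.
#' @param length length of each sequence (bp).
#' @param divergence per-base substitution probability between graft and host.
#' @param seed integer seed.
#' @return list with `graft` and `host`, each a named character vector.
#' @export
simulate_references <- function(n_chrom = 1, length = 20000, divergence = 0.05,
                                seed = 1) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    graft <- vapply(seq_len(n_chrom), function(i)
        paste(sample(bases, length, replace = TRUE), collapse = ""), character(1))
    host <- vapply(graft, function(s) .mutate_sequence(s, divergence), character(1),
                   USE.NAMES = FALSE)
    names(graft) <- names(host) <- paste0("chr", seq_len(n_chrom))
    list(graft = graft, host = host)
}

.mutate_sequence <- function(seq, rate) {
    if (rate <= 0) return(seq)
    bases <- c("A", "C", "G", "T")
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit) > 0) {
        for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1)
    }
    paste(ch, collapse = "")
}

#' Simulate reads from a graft/host genome mixture
#'
#' Each read originates from the host with probability `contamination`,
#' otherwise from the graft; positions are uniform, strand is random, and
#' substitution errors are applied at `error_rate`. True origins are returned
#' separately and are never visible to the classifier.
#'
#' @param graft_ref,host_ref named character vectors (or `DNAStringSet`/FASTA
#'   path) of reference sequences.
#' @param n_reads number of reads.
#' @param contamination host fraction in `[0, 1]`.
#' @param read_len read length; must not exceed the shortest reference
#'   sequence.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return list with `reads` (named character vector) and `truth` (data frame
#'   `read_id`, `origin` in graft/host).
#' @export
simulate_two_genome_reads <- function(graft_ref, host_ref, n_reads,
                                      contamination, read_len = 100,
                                      error_rate = 0, seed = 1) {
    if (contamination < 0 || contamination > 1)
        stop("contamination must be in [0, 1]")
    graft_ref <- .as_sequences(graft_ref)
    host_ref <- .as_sequences(host_ref)
    if (length(graft_ref) == 0 || length(host_ref) == 0)
        stop("both references must be non-empty")
    if (read_len > min(nchar(c(graft_ref, host_ref))))
        stop("read_len exceeds the shortest reference sequence")
    set.seed(seed)
    origin <- ifelse(runif(n_reads) < contamination, "host", "graft")
    reads <- character(n_reads)
    for (i in seq_len(n_reads)) {
        ref <- if (origin[i] == "host") host_ref else graft_ref
        seq <- ref[[sample.int(length(ref), 1)]]
        start <- sample.int(nchar(seq) - read_len + 1, 1)
        r <- substring(seq, start, start + read_len - 1)
        if (runif(1) < 0.5)
            r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
        if (error_rate > 0) r <- .mutate_sequence(r, error_rate)
        reads[i] <- r
    }
    ids <- sprintf("read_%06d", seq_len(n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, origin = origin,
                            stringsAsFactors = FALSE))
}

#' Write reads to a FASTA file
#'
#' @param reads named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads), path)
    invisible(path)
}
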