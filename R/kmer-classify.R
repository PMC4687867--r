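# Graft/host read classification against two reference k-mer indexes.
#
# A read is classified by counting its canonical k-mers that are specific to
# the graft (human) reference, specific to the host (mouse) reference, shared
# by both, or absent from both. Only "host" reads are removed downstream;
# "both", "neither" and "ambiguous" reads are retained so that as much
# graft-derived signal as possible reaches the analysis.

#' Build a canonical k-mer index from a reference
#'
#' Extracts every k-length window from the reference sequences, drops windows
#' containing ambiguous bases, collapses strands (a k-mer is stored as the
#' lexicographic minimum of itself and its reverse complement) and
#' deduplicates.
#'
#' @param reference a `Biostrings::DNAStringSet`, a character vector of
#'   sequences, or the path to a FASTA file.
#' @param k k-mer length, at least 11. Default 25.
#' @param label `"graft"` or `"host"`; informational.
#' @return an object of class `kmer_index` with elements `k`, `kmers`
#'   (sorted character vector of canonical k-mers) and `label`.
#' @export
build_kmer_index <- function(reference, k = 25, label = "graft") {
    stopifnot(k >= 11)
    seqs <- .as_sequences(reference)
    if (length(seqs) == 0 || all(nchar(seqs) == 0))
        stop("reference is empty")
    kmers <- unlist(lapply(seqs, .extract_kmers, k = k), use.names = FALSE)
    if (length(kmers) == 0)
        stop("k = ", k, " exceeds every reference sequence; index would be empty")
    kmers <- unique(canonical_kmers(kmers))
    structure(list(k = k, kmers = sort(kmers), label = label),
              class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
    cat(sprintf("kmer_index: %d canonical %d-mers (%s)\n",
                length(x$kmers), x$k, x$label))
    invisible(x)
}

.as_sequences <- function(x) {
    if (inherits(x, "DNAStringSet")) return(as.character(x))
    if (is.character(x) && length(x) == 1 && file.exists(x) &&
        grepl("\\.(fa|fasta|fna)(\\.gz)?$", x))
        return(as.character(Biostrings::readDNAStringSet(x)))
    setNames(as.character(x), names(x))
}

# All k-windows of one sequence; windows spanning a non-ACGT base are dropped.
.extract_kmers <- function(seq, k) {
    seq <- toupper(seq)
    n <- nchar(seq)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1)
    km <- substring(seq, starts, starts + k - 1)
    km[!grepl("[^ACGT]", km)]
}

#' Canonical (strand-collapsed) form of k-mers
#'
#' @param kmers character vector of equal-length nucleotide strings.
#' @return the per-element lexicographic minimum of each k-mer and its
#'   reverse complement.
#' @export
canonical_kmers <- function(kmers) {
    if (length(kmers) == 0) return(character(0))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    ifelse(kmers <= rc, kmers, rc)
}

#' Classify reads as graft, host, both, neither or ambiguous
#'
#' For each read (or mate pair, classified jointly on the union of both
#' mates' k-mers) counts canonical k-mers found only in the graft index (g),
#' only in the host index (h), in both (b) or in neither (z), then applies:
#' g>0 & h=0 -> graft; h>0 & g=0 -> host; g=h=0 & b>0 -> both;
#' all zero -> neither; g>0 & h>0 -> ambiguous. Reads shorter than k yield no
#' k-mers and fall in "neither" (counted in the `n_short` attribute).
#'
#' @param reads named character vector or `DNAStringSet` of read sequences.
#' @param graft_idx,host_idx `kmer_index` objects built with the same k.
#' @param mates optional second-mate sequences, parallel to `reads`.
#' @return data frame with one row per read: `read_id`, `category`, and the
#'   k-mer counts `g`, `h`, `b`, `z`.
#' @export
classify_reads <- function(reads, graft_idx, host_idx, mates = NULL) {
    stopifnot(inherits(graft_idx, "kmer_index"), inherits(host_idx, "kmer_index"))
    if (graft_idx$k != host_idx$k)
        stop("graft and host indexes were built with different k")
    k <- graft_idx$k
    reads <- .as_sequences(reads)
    ids <- names(reads) %||% as.character(seq_along(reads))
    if (is.null(names(reads))) names(reads) <- ids
    if (length(reads) == 0) {
        return(structure(data.frame(read_id = character(0), category = character(0),
                                    g = integer(0), h = integer(0),
                                    b = integer(0), z = integer(0)),
                         n_short = 0L))
    }
    if (!is.null(mates)) {
        mates <- .as_sequences(mates)
        stopifnot(length(mates) == length(reads))
    }

    km_list <- lapply(seq_along(reads), function(i) {
        km <- .extract_kmers(reads[[i]], k)
        if (!is.null(mates)) km <- c(km, .extract_kmers(mates[[i]], k))
        unique(km)
    })
    nk <- lengths(km_list)
    all_km <- canonical_kmers(unlist(km_list, use.names = FALSE))
    idx <- rep.int(seq_along(reads), nk)

    in_g <- all_km %in% graft_idx$kmers
    in_h <- all_km %in% host_idx$kmers
    g <- as.integer(.count_by(in_g & !in_h, idx, length(reads)))
    h <- as.integer(.count_by(!in_g & in_h, idx, length(reads)))
    b <- as.integer(.count_by(in_g & in_h, idx, length(reads)))
    z <- as.integer(.count_by(!in_g & !in_h, idx, length(reads)))

    category <- rep("neither", length(reads))
    category[g > 0 & h == 0] <- "graft"
    category[h > 0 & g == 0] <- "host"
    category[g == 0 & h == 0 & b > 0] <- "both"
    category[g > 0 & h > 0] <- "ambiguous"

    n_short <- sum(nk == 0)
    if (n_short > 0)
        message(n_short, " read(s) shorter than k = ", k, " classified as 'neither'")
    structure(data.frame(read_id = ids, category = category,
                         g = g, h = h, b = b, z = z,
                         stringsAsFactors = FALSE),
              n_short = n_short)
}

.count_by <- function(flag, idx, n) {
    out <- numeric(n)
    if (any(flag)) {
        tb <- tabulate(idx[flag], nbins = n)
        out <- tb
    }
    out
}

#' Summarize read-category counts and proportions for a sample
#'
#' @param reads read sequences (see [classify_reads()]), or an existing
#'   classification data frame.
#' @param graft_idx,host_idx `kmer_index` objects (ignored when `reads` is
#'   already a classification).
#' @param mates optional mate sequences.
#' @return data frame with one row per category (graft, host, both, neither,
#'   ambiguous): `category`, `n`, `proportion` (summing to 1).
#' @export
classify_batch <- function(reads, graft_idx = NULL, host_idx = NULL, mates = NULL) {
    cls <- if (is.data.frame(reads) && "category" %in% names(reads)) reads
           else classify_reads(reads, graft_idx, host_idx, mates)
    cats <- c("graft", "host", "both", "neither", "ambiguous")
    n <- vapply(cats, function(ct) sum(cls$category == ct), integer(1))
    total <- sum(n)
    data.frame(category = cats, n = as.integer(n),
               proportion = if (total > 0) n / total else rep(NA_real_, 5),
               stringsAsFactors = FALSE)
}

#' Remove host-classified reads
#'
#' Only reads whose category is `"host"` are dropped; both/neither/ambiguous
#' reads are retained to maximize graft-derived signal.
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param classifications data frame from [classify_reads()] covering every
#'   read id.
#' @return the retained reads, same container type as the character input.
#' @export
exclude_host <- function(reads, classifications) {
    seqs <- .as_sequences(reads)
    ids <- names(seqs) %||% as.character(seq_along(seqs))
    missing <- setdiff(ids, classifications$read_id)
    if (length(missing) > 0)
        stop("no classification for read(s): ", paste(head(missing, 5), collapse = ", "))
    host_ids <- classifications$read_id[classifications$category == "host"]
    keep <- !(ids %in% host_ids)
    out <- seqs[keep]
    names(out) <- ids[keep]
    out
}
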