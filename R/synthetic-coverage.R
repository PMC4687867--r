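# Synthetic exome-capture coverage with planted copy events and GC bias.

#' Build a capture interval grid
#'
#' Contiguous fixed-width intervals per chromosome (0-based half-open), each
#' carrying a GC fraction and a capture-pool copy count.
#'
#' @param intervals_per_chrom named integer vector.
#' @param width interval width in bp (default 120).
#' @param seed integer seed for the GC and pool-copy draws.
#' @return data frame `chrom`, `start`, `end`, `gc`, `copies_in_pool`.
#' @export
make_intervals <- function(intervals_per_chrom = c(chr1 = 800, chr2 = 600, chr3 = 600),
                           width = 120, seed = 1) {
    set.seed(seed)
    out <- lapply(names(intervals_per_chrom), function(cc) {
        m <- intervals_per_chrom[[cc]]
        data.frame(chrom = cc,
                   start = (seq_len(m) - 1L) * width,
                   end = seq_len(m) * width,
                   stringsAsFactors = FALSE)
    })
    iv <- do.call(rbind, out)
    n <- nrow(iv)
    iv$gc <- pmin(0.8, pmax(0.2, rnorm(n, 0.45, 0.08)))
    iv$copies_in_pool <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.9, 0.1))
    iv
}

# smooth per-sample multiplicative GC bias; coefficients drawn per sample
.gc_bias_fun <- function(amplitude) {
    a1 <- rnorm(1, 0, amplitude)
    a2 <- rnorm(1, 0, amplitude)
    function(gc) exp(a1 * (gc - 0.45) + a2 * ((gc - 0.45)^2 - 0.01))
}

#' Simulate an exome coverage profile
#'
#' Expected reads per interval are proportional to
#' `(purity * c_tumor + (1 - purity) * 2) / 2`, times a smooth per-sample GC
#' bias and the capture-pool copy count; counts are gamma-Poisson
#' (negative-binomial-like) overdispersed. RPKM is computed from the
#' simulated read counts and interval widths.
#'
#' @param intervals interval grid from [make_intervals()]; must be sorted and
#'   non-overlapping, with `gc`.
#' @param copy_events data frame `chrom`, `start`, `end`, `tumor_copies`
#'   (NULL for a diploid sample).
#' @param purity tumor cell fraction.
#' @param depth mean reads per diploid interval.
#' @param dispersion gamma-Poisson overdispersion (0 = Poisson).
#' @param gc_bias_amplitude scale of the random smooth GC bias (0 = flat).
#' @param exact if TRUE, counts are the expected values (no noise).
#' @param seed integer seed.
#' @return list with `profile` (intervals plus `reads` and `rpkm`) and
#'   `truth` (per-interval true tumor copy number).
#' @export
simulate_coverage <- function(intervals, copy_events = NULL, purity = 1,
                              depth = 100, dispersion = 0.02,
                              gc_bias_amplitude = 0.2, exact = FALSE, seed = 1) {
    if (nrow(intervals) == 0) stop("empty interval set")
    stopifnot(all(c("chrom", "start", "end", "gc") %in% names(intervals)))
    set.seed(seed)
    n <- nrow(intervals)
    copies <- rep(2, n)
    if (!is.null(copy_events) && nrow(copy_events) > 0) {
        for (e in seq_len(nrow(copy_events))) {
            ev <- copy_events[e, ]
            hit <- intervals$chrom == ev$chrom &
                intervals$start < ev$end & intervals$end > ev$start
            copies[hit] <- ev$tumor_copies
        }
    }
    cn_factor <- (purity * copies + (1 - purity) * 2) / 2
    bias <- if (gc_bias_amplitude > 0) .gc_bias_fun(gc_bias_amplitude)(intervals$gc)
            else rep(1, n)
    pool <- if ("copies_in_pool" %in% names(intervals)) intervals$copies_in_pool
            else rep(1L, n)
    mu <- depth * cn_factor * bias * pool
    reads <- if (exact) mu
             else if (dispersion > 0)
                 rpois(n, mu * rgamma(n, shape = 1 / dispersion, scale = dispersion))
             else rpois(n, mu)
    widths <- intervals$end - intervals$start
    total <- sum(reads)
    rpkm <- reads / (widths / 1000) / (total / 1e6)
    profile <- cbind(intervals, reads = reads, rpkm = rpkm)
    list(profile = profile,
         truth = data.frame(chrom = intervals$chrom, start = intervals$start,
                            end = intervals$end, true_copies = copies,
                            stringsAsFactors = FALSE))
}
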