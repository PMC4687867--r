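# Joint subclone identification and tumor purity estimation across
# sequential samples.
#
# Somatic variants are modeled as a K-component mixture of binomials: variant
# i in cluster k has alt-read count a_is ~ Binomial(d_is, theta_ks) in sample
# s, with cluster membership shared across samples. theta_ks is the cluster's
# expected VAF in sample s; under a heterozygous diploid model the clonal
# cluster has theta = purity / 2, so purity_s = min(1, 2 * max_k theta_ks).
# Fitting is by expectation-maximization with multiple restarts; the number
# of clusters is chosen by BIC.

#' Fit a K-cluster binomial mixture to variant allele counts
#'
#' @param alt,depth numeric matrices (variants x samples) of alt reads and
#'   total depth; column names are sample ids.
#' @param K number of clusters.
#' @param seed integer seed (restart jitter).
#' @param n_restarts random restarts; the best likelihood wins.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @return object of class `subclone_model`: `K`, `pi` (cluster weights),
#'   `theta` (K x S expected VAFs), `resp` (posterior memberships),
#'   `membership` (hard assignment), `purity` (per sample), `loglik`,
#'   `bic`, `loglik_trace` (of the winning restart), `converged`.
#' @export
fit_subclones <- function(alt, depth, K, seed = 1, n_restarts = 10,
                          max_iter = 500, tol = 1e-8) {
    alt <- as.matrix(alt); depth <- as.matrix(depth)
    stopifnot(all(dim(alt) == dim(depth)), K >= 1,
              all(alt >= 0), all(alt <= depth))
    n <- nrow(alt); S <- ncol(alt)
    if (n < K) stop("fewer variants than clusters")
    set.seed(seed)
    pooled_vaf <- rowSums(alt) / pmax(rowSums(depth), 1)
    centers <- quantile(pooled_vaf, probs = (seq_len(K) - 0.5) / K, names = FALSE)

    best <- NULL
    for (r in seq_len(n_restarts)) {
        theta <- matrix(pmin(pmax(centers + rnorm(K * S, 0, 0.02), 1e-4), 0.999),
                        K, S)
        pi_k <- rep(1 / K, K)
        fit <- .em_binom_mixture(alt, depth, theta, pi_k, max_iter, tol)
        if (is.null(fit)) next   # degenerate cluster; try another restart
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best))
        stop("all EM restarts degenerated; reduce K")
    if (!best$converged)
        warning("EM did not converge within ", max_iter, " iterations")
    # order clusters by pooled theta, largest first (clonal cluster first)
    ord <- order(rowMeans(best$theta), decreasing = TRUE)
    theta <- best$theta[ord, , drop = FALSE]
    colnames(theta) <- colnames(alt)
    resp <- best$resp[, ord, drop = FALSE]
    pi_k <- best$pi[ord]
    p <- (K - 1) + K * S
    structure(list(
        K = K, pi = pi_k, theta = theta, resp = resp,
        membership = max.col(resp),
        purity = pmin(2 * apply(theta, 2, max), 1),
        loglik = best$loglik,
        bic = -2 * best$loglik + p * log(n),
        loglik_trace = best$trace,
        converged = best$converged,
        n_variants = n), class = "subclone_model")
}

.em_binom_mixture <- function(alt, depth, theta, pi_k, max_iter, tol) {
    n <- nrow(alt); K <- nrow(theta)
    lchoose_term <- sum(lchoose(depth, alt))  # constant in the parameters
    trace <- numeric(0)
    loglik <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
        # E-step
        ll_ik <- matrix(0, n, K)
        for (k in seq_len(K)) {
            th <- theta[k, ]
            ll_ik[, k] <- log(pi_k[k]) +
                alt %*% log(th) + (depth - alt) %*% log(1 - th)
        }
        mx <- apply(ll_ik, 1, max)
        w <- exp(ll_ik - mx)
        sw <- rowSums(w)
        new_loglik <- sum(mx + log(sw)) + lchoose_term
        resp <- w / sw
        # M-step
        nk <- colSums(resp)
        if (any(nk < 1)) return(NULL)  # degenerate cluster
        pi_k <- nk / n
        theta <- t(resp) %*% alt / (t(resp) %*% depth)
        theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
        trace <- c(trace, new_loglik)
        if (is.finite(loglik) &&
            abs(new_loglik - loglik) < tol * (abs(loglik) + 1)) {
            loglik <- new_loglik
            converged <- TRUE
            break
        }
        loglik <- new_loglik
    }
    list(theta = theta, pi = pi_k, resp = resp, loglik = loglik,
         trace = trace, converged = converged)
}

#' @export
print.subclone_model <- function(x, ...) {
    cat(sprintf("subclone_model: K = %d, %d variants, logLik = %.2f, BIC = %.2f\n",
                x$K, x$n_variants, x$loglik, x$bic))
    cat("theta (cluster x sample):\n")
    print(round(x$theta, 4))
    cat("purity:", paste(sprintf("%s = %.3f", names(x$purity), x$purity),
                         collapse = ", "), "\n")
    invisible(x)
}

#' Select the number of subclones by BIC
#'
#' Fits K = 1..K_max and keeps the model with the lowest BIC
#' (`-2 logL + p log n`, `p = K - 1 + K * S`). With fewer than 10 variants,
#' K is forced to 1.
#'
#' @inheritParams fit_subclones
#' @param K_max largest number of clusters to try.
#' @return the winning `subclone_model`, with a `score_table` element
#'   (K, loglik, bic).
#' @export
select_k <- function(alt, depth, K_max = 5, seed = 1, n_restarts = 10) {
    alt <- as.matrix(alt)
    if (nrow(alt) < 10) {
        message("fewer than 10 variants; forcing K = 1")
        K_max <- 1
    }
    fits <- list()
    for (K in seq_len(K_max)) {
        fits[[K]] <- tryCatch(
            fit_subclones(alt, depth, K, seed = seed + K, n_restarts = n_restarts),
            error = function(e) NULL)
    }
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("no mixture model could be fitted")
    score <- data.frame(K = which(ok),
                        loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
                        bic = vapply(fits[ok], `[[`, numeric(1), "bic"))
    best <- fits[ok][[which.min(score$bic)]]
    best$score_table <- score
    best
}

#' Per-clone frequency trajectories across samples
#'
#' Cluster-level expected VAF (theta) per sample in declared order, with
#' normal-approximation binomial confidence bands based on the cluster's
#' aggregated depth.
#'
#' @param model a `subclone_model`.
#' @param alt,depth the matrices the model was fitted to.
#' @param sample_order optional ordering of the sample columns.
#' @param conf confidence level of the bands.
#' @return data frame `clone`, `sample`, `theta`, `se`, `lower`, `upper`.
#' @export
clone_frequency_trajectories <- function(model, alt, depth, sample_order = NULL,
                                         conf = 0.95) {
    stopifnot(inherits(model, "subclone_model"))
    alt <- as.matrix(alt); depth <- as.matrix(depth)
    samples <- colnames(model$theta) %||% as.character(seq_len(ncol(model$theta)))
    if (is.null(sample_order)) sample_order <- samples
    zq <- stats::qnorm(1 - (1 - conf) / 2)
    out <- list()
    for (k in seq_len(model$K)) {
        members <- model$membership == k
        d_k <- colSums(depth[members, , drop = FALSE])
        th <- model$theta[k, ]
        se <- sqrt(th * (1 - th) / pmax(d_k, 1))
        out[[k]] <- data.frame(clone = k, sample = samples, theta = th,
                               se = se,
                               lower = pmax(0, th - zq * se),
                               upper = pmin(1, th + zq * se),
                               stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, out)
    tab <- tab[order(tab$clone, match(tab$sample, sample_order)), ]
    rownames(tab) <- NULL
    tab
}

#' Scatter of mutant allele counts versus depth, colored by cluster
#'
#' One panel per sample: each variant's alt reads against its total depth,
#' colored by hard cluster assignment, with per-cluster expected-count lines
#' and binomial 95% bands.
#'
#' @param x a `subclone_model`.
#' @param alt,depth fitted matrices.
#' @param ... passed to `plot`.
#' @return invisibly, NULL. Called for its side effect.
#' @export
plot.subclone_model <- function(x, alt, depth, ...) {
    alt <- as.matrix(alt); depth <- as.matrix(depth)
    S <- ncol(alt)
    cols <- grDevices::hcl.colors(max(x$K, 2), "Dark 3")
    op <- graphics::par(mfrow = c(1, S))
    on.exit(graphics::par(op))
    for (s in seq_len(S)) {
        graphics::plot(depth[, s], alt[, s], col = cols[x$membership],
                       pch = 19, cex = 0.6,
                       xlab = "total reads", ylab = "mutant allele reads",
                       main = colnames(alt)[s] %||% paste("sample", s), ...)
        dd <- seq(0, max(depth[, s]), length.out = 50)
        for (k in seq_len(x$K)) {
            th <- x$theta[k, s]
            graphics::lines(dd, th * dd, col = cols[k])
            graphics::lines(dd, th * dd + 1.96 * sqrt(dd * th * (1 - th)),
                            col = cols[k], lty = 3)
            graphics::lines(dd, pmax(0, th * dd - 1.96 * sqrt(dd * th * (1 - th))),
                            col = cols[k], lty = 3)
        }
    }
    invisible(NULL)
}
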