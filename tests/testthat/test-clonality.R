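# Binomial-mixture subclone model: parameter recovery, model selection,
# EM monotonicity, trajectories.

sim_clones <- function(n = 200, theta = c(0.375, 0.20, 0.08), S = 2,
                       depth = 100, seed = 1) {
    set.seed(seed)
    clone <- sample(seq_along(theta), n, replace = TRUE)
    d <- matrix(rpois(n * S, depth), n, S)
    a <- matrix(rbinom(n * S, d, theta[clone]), n, S)
    colnames(a) <- colnames(d) <- paste0("T", seq_len(S))
    list(alt = a, depth = d, clone = clone)
}

test_that("single-cluster fits recover theta and purity", {
    set.seed(2)
    d <- matrix(rpois(300, 100), 300, 1)
    a <- matrix(rbinom(300, d, 0.375), 300, 1)
    m <- fit_subclones(a, d, K = 1, seed = 3)
    expect_lt(abs(m$theta[1, 1] - 0.375), 0.01)
    expect_lt(abs(m$purity[[1]] - 0.75), 0.02)
    # noiseless clonal pure-tumor limit: a = d/2 exactly
    d2 <- matrix(rep(100L, 50), 50, 1)
    m2 <- fit_subclones(d2 / 2, d2, K = 1, seed = 4)
    expect_equal(unname(m2$theta[1, 1]), 0.5, tolerance = 1e-4)
    expect_equal(unname(m2$purity[[1]]), 1, tolerance = 1e-3)
})

test_that("three planted clones are recovered with shared membership", {
    s <- sim_clones(seed = 8)
    m <- fit_subclones(s$alt, s$depth, K = 3, seed = 9)
    # clusters are ordered by decreasing theta, matching the truth labels
    expect_gt(mean(m$membership == s$clone), 0.9)
    expect_lt(max(abs(m$theta - matrix(c(0.375, 0.20, 0.08), 3, 2))), 0.03)
    expect_lt(abs(m$purity[["T1"]] - 0.75), 0.05)
    # responsibilities are a proper soft assignment
    expect_equal(unname(rowSums(m$resp)), rep(1, nrow(s$alt)))
    expect_equal(sum(m$pi), 1)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
    s <- sim_clones(seed = 10)
    m <- fit_subclones(s$alt, s$depth, K = 3, seed = 11)
    expect_true(all(diff(m$loglik_trace) > -1e-6))
})

test_that("likelihood and purity are invariant under cluster relabeling", {
    s <- sim_clones(n = 120, seed = 12)
    m1 <- fit_subclones(s$alt, s$depth, K = 3, seed = 13, n_restarts = 5)
    m2 <- fit_subclones(s$alt[rev(seq_len(nrow(s$alt))), ],
                        s$depth[rev(seq_len(nrow(s$depth))), ],
                        K = 3, seed = 14, n_restarts = 5)
    expect_equal(m1$loglik, m2$loglik, tolerance = 1e-4)
    expect_equal(m1$purity, m2$purity, tolerance = 0.01)
})

test_that("BIC model selection finds the planted number of clones", {
    # single clone
    set.seed(15)
    d <- matrix(rpois(200, 100), 100, 2)
    a <- matrix(rbinom(200, d, 0.375), 100, 2)
    m1 <- suppressWarnings(select_k(a, d, K_max = 4, seed = 16))
    expect_equal(m1$K, 1)
    # three well-separated clones
    s <- sim_clones(seed = 17)
    m3 <- suppressWarnings(select_k(s$alt, s$depth, K_max = 5, seed = 18))
    expect_equal(m3$K, 3)
    expect_equal(nrow(m3$score_table), 5)
    # guard: too few variants forces K = 1
    expect_message(mf <- select_k(s$alt[1:5, ], s$depth[1:5, ], K_max = 3,
                                  seed = 19), "forcing K = 1")
    expect_equal(mf$K, 1)
})

test_that("clone trajectories are stable when planted stable and track vanishing clones", {
    s <- sim_clones(S = 3, seed = 20)
    m <- fit_subclones(s$alt, s$depth, K = 3, seed = 21)
    traj <- clone_frequency_trajectories(m, s$alt, s$depth)
    expect_equal(nrow(traj), 9)
    for (k in 1:3) {
        th <- traj$theta[traj$clone == k]
        se <- traj$se[traj$clone == k]
        expect_lt(max(abs(th - mean(th))), 3 * max(se))
    }
    # a clone that vanishes at the second timepoint is seen at theta ~ 0
    set.seed(22)
    clone <- sample(1:2, 150, replace = TRUE)
    d <- matrix(rpois(300, 100), 150, 2)
    th_true <- cbind(c(0.375, 0.2)[clone], ifelse(clone == 1, 0.375, 0.001))
    a <- matrix(rbinom(300, d, th_true), 150, 2)
    m2 <- fit_subclones(a, d, K = 2, seed = 23)
    expect_lt(m2$theta[2, 2], 0.02)
    # single sample degenerates to one column without error
    m3 <- fit_subclones(s$alt[, 1, drop = FALSE], s$depth[, 1, drop = FALSE],
                        K = 3, seed = 24)
    traj3 <- clone_frequency_trajectories(m3, s$alt[, 1, drop = FALSE],
                                          s$depth[, 1, drop = FALSE])
    expect_equal(nrow(traj3), 3)
})
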