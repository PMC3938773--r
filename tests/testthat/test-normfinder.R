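# simulate a log-normal Q table with per-gene log2 SDs and optional
# per-gene x group mean shifts (log2 units); groups of equal size n_g
sim_nf_table <- function(sds, n_g, groups = 1L, shifts = NULL) {
  I <- length(sds)
  G <- groups
  if (is.null(shifts)) shifts <- matrix(0, I, G)
  y <- matrix(0, I, n_g * G)
  grp <- rep(paste0("grp", seq_len(G)), each = n_g)
  for (g in seq_len(G)) {
    cols <- which(grp == paste0("grp", g))
    y[, cols] <- shifts[, g] + matrix(rnorm(I * n_g, 0, sds), I, n_g)
  }
  q <- 2^y
  dimnames(q) <- list(paste0("g", seq_len(I)), paste0("o", seq_len(ncol(q))))
  list(q = q, groups = setNames(grp, colnames(q)))
}

test_that("identical genes give all-zero variances, deviations and stabilities", {
  q <- matrix(2^rnorm(8), 4, 8, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("o", 1:8)))
  q <- sweep(q * 0 + 1, 2, 2^rnorm(8), "*")  # every gene identical per obs
  res <- normfinder_stability(q, rep(c("a", "b"), each = 4))
  expect_equal(unname(res$rho), rep(0, 4))
  expect_equal(unname(res$sigma2), matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(res$gamma2, 0)
  expect_equal(unname(res$dtilde), matrix(0, 4, 2), ignore_attr = TRUE)
})

test_that("structural invariants hold on random data", {
  set.seed(53)
  for (i in 1:20) {
    sim <- sim_nf_table(runif(5, 0.1, 0.8), n_g = 6, groups = 3,
                        shifts = matrix(rnorm(15, 0, 0.5), 5, 3))
    res <- normfinder_stability(sim$q, sim$groups)
    expect_true(all(res$rho >= 0))
    expect_true(all(res$sigma2 >= 0))
    expect_gte(res$gamma2, 0)
    # deviations sum to zero within each group
    expect_equal(unname(colSums(res$dhat)), rep(0, 3), tolerance = 1e-10)
    # shrinkage never inflates a deviation
    expect_true(all(abs(res$dtilde) <= abs(res$dhat) + 1e-12))
    # shrink factors decrease with the per-cell error variance sigma2/n_g
    shrink <- res$dtilde / res$dhat
    se2 <- sweep(res$sigma2, 2, res$n_g, "/")
    ord <- order(se2)
    expect_true(all(diff(shrink[ord]) <= 1e-12))
  }
})

test_that("stability is invariant to per-observation scaling and per-gene shifts", {
  set.seed(59)
  sim <- sim_nf_table(runif(6, 0.1, 0.6), n_g = 5, groups = 2,
                      shifts = matrix(rnorm(12, 0, 0.4), 6, 2))
  res <- normfinder_stability(sim$q, sim$groups)
  # scale every observation (sample-loading effect)
  q_obs <- sweep(sim$q, 2, 2^rnorm(ncol(sim$q)), "*")
  res_obs <- normfinder_stability(q_obs, sim$groups)
  expect_equal(res_obs$rho, res$rho, tolerance = 1e-10)
  expect_equal(res_obs$sigma2, res$sigma2, tolerance = 1e-10)
  expect_equal(res_obs$gamma2, res$gamma2, tolerance = 1e-10)
  # multiply one gene by a constant (additive in log2)
  q_gene <- sim$q
  q_gene["g3", ] <- 5.5 * q_gene["g3", ]
  res_gene <- normfinder_stability(q_gene, sim$groups)
  expect_equal(res_gene$rho, res$rho, tolerance = 1e-10)
})

test_that("single-group stability recovers the simulated gene noise ranking", {
  set.seed(61)
  sds <- seq(0.1, 0.8, length.out = 5)
  ok_rank <- 0L
  rho_sum <- numeric(5)
  n_runs <- 30L
  for (i in seq_len(n_runs)) {
    sim <- sim_nf_table(sds, n_g = 200, groups = 1L)
    res <- normfinder_stability(sim$q, sim$groups)
    if (all(order(res$rho) == 1:5)) ok_rank <- ok_rank + 1L
    rho_sum <- rho_sum + unname(res$rho)
  }
  expect_gte(ok_rank, ceiling(0.95 * n_runs))
  rel_err <- abs(rho_sum / n_runs - sds) / sds
  expect_true(all(rel_err < 0.15))
})

test_that("a gene with a group shift is flagged as least stable", {
  set.seed(67)
  shifts <- matrix(0, 5, 2)
  shifts[1, ] <- c(0, 1.0)          # +1 log2 shift in group 2, gene 1 only
  worst <- 0L
  for (i in 1:25) {
    sim <- sim_nf_table(rep(0.3, 5), n_g = 20, groups = 2, shifts = shifts)
    res <- normfinder_stability(sim$q, sim$groups)
    if (which.max(res$rho) == 1L) worst <- worst + 1L
  }
  expect_equal(worst, 25L)
})

test_that("a gene that is both noisy and group-shifted never ranks in the top 2", {
  set.seed(71)
  shifts <- matrix(0, 5, 2)
  shifts[2, ] <- c(0, 1.0)
  sds <- c(0.2, 0.6, 0.2, 0.2, 0.2)   # log2 SD ratio 3 for the bad gene
  for (i in 1:100) {
    sim <- sim_nf_table(sds, n_g = 12, groups = 2, shifts = shifts)
    res <- normfinder_stability(sim$q, sim$groups)
    expect_gte(res$table$rank[2], 3L)
  }
})

test_that("preconditions are enforced", {
  set.seed(73)
  sim <- sim_nf_table(rep(0.3, 5), n_g = 4, groups = 2)
  expect_error(normfinder_stability(sim$q[1:2, ], sim$groups[1:8]),
               "at least 3 genes")
  expect_error(normfinder_stability(sim$q, rep("a", 7)),
               "one group label per observation")
  grp_bad <- sim$groups
  grp_bad[1] <- "lonely"
  expect_error(normfinder_stability(sim$q, grp_bad), "at least 2 observations")
  grp_na <- as.character(sim$groups)
  grp_na[2] <- NA
  expect_error(normfinder_stability(sim$q, grp_na), "without group label")
})

test_that("rank report sorts ascending by stability with stable ties", {
  rho <- c(a = 0.3, b = 0.1, c = 0.2)
  q <- rbind(a = c(1, 1, 1, 1), b = c(1, 1, 1, 1), c = c(1, 1, 1, 1))
  res <- structure(list(table = data.frame(gene = names(rho),
                                           stability_value = unname(rho),
                                           rank = rank(rho, ties.method = "first")),
                        rho = rho, I = 3L),
                   class = "normfinder_result")
  expect_equal(rank_report(res)$gene, c("b", "c", "a"))

  set.seed(79)
  sim15 <- sim_nf_table(runif(15, 0.1, 0.9), n_g = 10, groups = 2)
  tab <- rank_report(normfinder_stability(sim15$q, sim15$groups))
  expect_equal(dim(tab), c(15L, 3L))
  expect_equal(names(tab), c("gene", "stability_value", "rank"))
  expect_false(is.unsorted(tab$stability_value))

  # exact ties keep input order
  q_tie <- sim15$q[1:3, ]
  q_tie[2, ] <- q_tie[1, ]   # genes 1 and 2 identical -> identical rho
  res_tie <- normfinder_stability(q_tie, sim15$groups)
  if (res_tie$rho[1] == res_tie$rho[2]) {
    expect_lt(res_tie$table$rank[1], res_tie$table$rank[2])
  }
})

test_that("observations with missing values are dropped with a warning", {
  set.seed(83)
  sim <- sim_nf_table(rep(0.3, 4), n_g = 10, groups = 2)
  q <- sim$q
  q[1, 3] <- NA
  expect_warning(res <- normfinder_stability(q, sim$groups), "dropping 1")
  expect_equal(unname(res$n_g), c(9L, 10L))
})
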