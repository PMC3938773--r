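test_that("pairwise variation is zero on the diagonal and for proportional genes", {
  set.seed(7)
  q <- random_q(3, 6)
  q["g2", ] <- 0.5 * q["g1", ]     # constant ratio -> V = 0
  v <- pairwise_variation_matrix(q)
  expect_equal(unname(diag(v)), rep(0, 3))
  expect_equal(v["g1", "g2"], 0, tolerance = 1e-12)
  expect_equal(v, t(v))
  expect_true(all(v >= 0))
})

test_that("V matrix and M values match the brute-force oracle", {
  set.seed(11)
  for (i in 1:10) {
    q <- random_q(4, 5)
    expect_equal(pairwise_variation_matrix(q), oracle_v_matrix(q),
                 tolerance = 1e-12)
    expect_equal(stability_m(q), oracle_m(q), tolerance = 1e-12)
  }
  # pairwise-complete behaviour under missing cells
  q <- random_q(3, 6)
  q["g1", 1] <- NA
  expect_equal(pairwise_variation_matrix(q), oracle_v_matrix(q),
               tolerance = 1e-12)
})

test_that("M is the V(j,k) itself for a two-gene subset and errors below that", {
  set.seed(13)
  q <- random_q(4, 6)
  m2 <- stability_m(q, c("g1", "g3"))
  v <- pairwise_variation_matrix(q)
  expect_equal(unname(m2), rep(v["g1", "g3"], 2))
  expect_error(stability_m(q, "g1"), "size >= 2")
  expect_error(pairwise_variation_matrix(q[, 1, drop = FALSE]),
               "fewer than 2 observations")
})

test_that("a markedly noisier gene is excluded first", {
  set.seed(17)
  hits <- 0L
  for (i in 1:200) {
    base <- rnorm(8)
    q <- rbind(g1 = 2^(base + rnorm(8, 0, 0.2)),
               g2 = 2^(base + rnorm(8, 0, 0.2)),
               g3 = 2^(base + rnorm(8, 0, 0.8)))   # 4x the log-scale noise SD
    colnames(q) <- paste0("o", 1:8)
    rk <- rank_genes_stepwise(q)
    if (rk$exclusion_order[1] == "g3") hits <- hits + 1L
  }
  expect_gte(hits, 190L)   # >= 95% of 200 tables
})

test_that("the final pair shares one M value and exact ties break toward later input order", {
  set.seed(19)
  q <- random_q(5, 8)
  rk <- rank_genes_stepwise(q)
  expect_length(rk$exclusion_order, 3L)
  expect_setequal(rk$ranking, rownames(q))
  expect_equal(unname(rk$m_values[rk$best_pair[1]]),
               unname(rk$m_values[rk$best_pair[2]]))
  expect_equal(rk$table$rank[1:2], c(1L, 1L))

  # two exact duplicate pairs -> all four genes tie at the maximal M
  qa <- random_q(2, 8); qb <- random_q(2, 8)
  q4 <- rbind(ga = qa[1, ], gb = qa[1, ], gc = qb[1, ], gd = qb[1, ])
  expect_equal(max(stability_m(q4)), min(stability_m(q4)))
  rk4 <- rank_genes_stepwise(q4)
  expect_equal(rk4$exclusion_order[1], "gd")
  expect_error(rank_genes_stepwise(q4[1:2, ]), "at least 3")
})

test_that("NF series is the geometric mean of the top-ranked genes", {
  q <- rbind(g1 = c(1, 2), g2 = c(4, 8))
  colnames(q) <- c("o1", "o2")
  nf <- normalization_factor_series(q, c("g1", "g2"))
  expect_equal(unname(nf["nf2", ]), c(2, 4))
  # invariant to the internal order of the chosen genes
  set.seed(23)
  q5 <- random_q(5, 8)
  nf_a <- normalization_factor_series(q5, c("g1", "g2", "g3", "g4", "g5"))
  nf_b <- normalization_factor_series(q5, c("g2", "g1", "g3", "g4", "g5"))
  expect_equal(nf_a["nf2", ], nf_b["nf2", ], tolerance = 1e-12)
  expect_equal(nf_a["nf5", ], nf_b["nf5", ], tolerance = 1e-12)
  # matches the product-form oracle
  expect_equal(unname(nf_a), unname(oracle_nf_series(q5, rownames(q5))),
               tolerance = 1e-12)
})

test_that("V series matches the oracle and vanishes for a redundant added gene", {
  set.seed(29)
  q <- random_q(5, 8)
  rk <- rank_genes_stepwise(q)
  nf <- normalization_factor_series(q, rk$ranking)
  vs <- pairwise_variation_series(nf)
  expect_equal(vs$n, 2:4)
  expect_true(all(vs$v >= 0))
  expect_equal(vs$v, oracle_vseries(q, rk$ranking), tolerance = 1e-12)

  # gene n+1 proportional to NF_n -> V(n, n+1) = 0
  q3 <- random_q(2, 8)
  nf2 <- oracle_nf(q3, c("g1", "g2"))
  q3 <- rbind(q3, g3 = 3 * nf2)
  nf_series <- normalization_factor_series(q3, c("g1", "g2", "g3"))
  vs3 <- pairwise_variation_series(nf_series)
  expect_equal(vs3$v[vs3$n == 2], 0, tolerance = 1e-12)
})

test_that("the 0.15 cut-off rule picks the first V below the cut-off", {
  # all-sample survey: V2..V7 above the cut-off, V8/9 = 0.154, V9/10 = 0.134
  vs <- data.frame(n = 2:9, v = c(rep(0.20, 6), 0.154, 0.134))
  opt <- optimal_gene_number(vs)
  expect_equal(opt$n_optimal, 9L)
  expect_true(opt$satisfiable)

  # biotic-stress style series: V2/3 = 0.129 already below
  vs2 <- data.frame(n = 2:5, v = c(0.129, 0.11, 0.1, 0.09))
  expect_equal(optimal_gene_number(vs2)$n_optimal, 2L)

  # nothing below the cut-off
  vs3 <- data.frame(n = 2:6, v = rep(0.3, 5))
  opt3 <- optimal_gene_number(vs3)
  expect_false(opt3$satisfiable)
  expect_equal(opt3$n_optimal, 6L)

  expect_error(optimal_gene_number(data.frame(n = c(3, 4), v = c(0.1, 0.1))),
               "starting at 2")
})

test_that("geNorm statistics are invariant to per-observation and per-gene scaling", {
  set.seed(31)
  q <- random_q(5, 8)
  res <- genorm(q)
  # multiply all Q of single observations by arbitrary positive constants
  q_scaled <- sweep(q, 2, c(10, 1, 0.2, 5, 1, 1, 3, 0.5), "*")
  res_s <- genorm(q_scaled)
  expect_equal(pairwise_variation_matrix(q_scaled),
               pairwise_variation_matrix(q), tolerance = 1e-10)
  expect_equal(res_s$m_values, res$m_values, tolerance = 1e-10)
  expect_equal(res_s$ranking, res$ranking)
  expect_equal(res_s$vseries$v, res$vseries$v, tolerance = 1e-10)
  # multiply all Q of one gene by a positive constant
  q_gene <- q; q_gene["g2", ] <- 7 * q_gene["g2", ]
  expect_equal(stability_m(q_gene), stability_m(q), tolerance = 1e-10)
})

test_that("adding an exact duplicate of a gene can only stabilize it", {
  set.seed(37)
  for (i in 1:10) {
    q <- random_q(4, 8)
    m_before <- stability_m(q)["g1"]
    q_dup <- rbind(q, g1b = q["g1", ])
    m_after <- stability_m(q_dup)["g1"]
    expect_lte(unname(m_after), unname(m_before) + 1e-12)
  }
})

test_that("full geNorm run wires ranking, NF and the decision rule together", {
  set.seed(41)
  q <- random_q(6, 10, sd = 0.3)
  res <- genorm(q, cutoff = 0.15)
  expect_s3_class(res, "genorm_result")
  expect_equal(nrow(res$table), 6L)
  expect_equal(res$vseries$n, 2:5)
  expect_true(res$n_optimal >= 2L)
  expect_output(print(res), "best pair")
})
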