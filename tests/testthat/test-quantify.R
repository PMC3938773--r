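test_that("normalization factor is the geometric mean of reference quantities", {
  q <- rbind(r1 = c(1, 2), r2 = c(4, 8), r3 = c(1, 1))
  colnames(q) <- c("o1", "o2")
  expect_equal(unname(normalization_factor(q, c("r1", "r2"))), c(2, 4))
  q2 <- rbind(r1 = c(1, 1), r2 = c(2, 2), r3 = c(4, 4))
  colnames(q2) <- c("o1", "o2")
  expect_equal(unname(normalization_factor(q2)), c(2, 2))
  # single reference -> NF is that gene's Q
  expect_equal(normalization_factor(q, "r1"), q["r1", ])
  # missing reference quantity is a hard error naming the observation
  q["r2", 2] <- NA
  expect_error(normalization_factor(q, c("r1", "r2")), "o2")
})

test_that("ddCp fold changes follow 2^-(dCp - calibrator mean dCp)", {
  m <- rbind(CAT = c(24, 22), REF = c(20, 20))
  colnames(m) <- c("ctrl", "cold")
  ds <- cp_from_matrix(m)
  meta <- data.frame(sample = c("ctrl", "cold"), subset = "abiotic",
                     group = c("control", "cold"))
  res <- suppressWarnings(
    relative_expression_ddcp(ds, target_genes = "CAT", ref_genes = "REF",
                             meta = meta, calibrator = "control"))
  # dCp: control 4, cold 2 -> ddCp = -2 -> fold 4
  s <- res$summary
  expect_equal(s$mean_fold[s$condition == "cold"], 4)
  expect_equal(s$mean_fold[s$condition == "control"], 1)

  expect_error(relative_expression_ddcp(ds, target_genes = "CAT",
                                        ref_genes = "REF", meta = meta,
                                        calibrator = "heat"),
               "calibrator")
  expect_error(relative_expression_ddcp(ds, target_genes = "CAT2",
                                        ref_genes = "REF", meta = meta,
                                        calibrator = "control"),
               "CAT2")
  expect_error(relative_expression_ddcp(ds, target_genes = "CAT",
                                        ref_genes = "REF2", meta = meta,
                                        calibrator = "control"),
               "REF2")
})

test_that("identical calibrator replicates give fold exactly 1", {
  df <- expand.grid(gene = c("CAT", "REF"), sample = c("t0", "t24"),
                    bio_rep = 1:3, tech_rep = 1L,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$cp <- ifelse(df$gene == "CAT",
                  ifelse(df$sample == "t0", 24, 22), 20)
  ds <- cp_dataset(df)
  meta <- data.frame(sample = c("t0", "t24"), subset = "tc", group = c("t0", "t24"))
  res <- relative_expression_ddcp(ds, target_genes = "CAT", ref_genes = "REF",
                                  meta = meta, calibrator = "t0")
  expect_equal(res$folds$fold[res$folds$condition == "t0"], rep(1, 3))
  expect_equal(res$summary$sd[res$summary$condition == "t0"], 0)
})

test_that("mean-of-reference-Cp route equals the explicit Q/NF oracle", {
  set.seed(91)
  genes <- c("T1", "T2", "R1", "R2", "R3")
  samples <- c("c1", "c2", "x1", "x2")
  m <- matrix(rnorm(20, 22, 2), 5, 4, dimnames = list(genes, samples))
  ds <- cp_from_matrix(m, n_bio = 1L)
  # n_bio = 1 grid built from the same matrix at bio_rep 1
  meta <- data.frame(sample = samples, subset = "s",
                     group = c("ctrl", "ctrl", "trt", "trt"))
  res <- relative_expression_ddcp(ds, target_genes = c("T1", "T2"),
                                  ref_genes = c("R1", "R2", "R3"),
                                  meta = meta, calibrator = "ctrl")
  # oracle: Q per gene, NF as geometric mean, ratio target/NF rescaled to
  # the calibrator's geometric-mean ratio
  q <- 2^(apply(m, 1, min) - m)       # genes x samples
  nf <- apply(q[c("R1", "R2", "R3"), ], 2, function(x) prod(x)^(1 / 3))
  for (tg in c("T1", "T2")) {
    ratio <- q[tg, ] / nf
    cal_gm <- exp(mean(log(ratio[c("c1", "c2")])))
    oracle_fold <- ratio / cal_gm
    got <- res$folds[res$folds$target == tg, ]
    expect_equal(setNames(got$fold, got$sample), oracle_fold,
                 tolerance = 1e-12)
  }
})

test_that("fold changes ignore reference order and per-replicate loading shifts", {
  set.seed(97)
  sim <- simulate_target_timecourse(seed = 97)
  ds <- suppressWarnings(collapse_technical_replicates(sim$dataset))
  meta <- sim$metadata
  r1 <- relative_expression_ddcp(ds, target_genes = "CAT1",
                                 ref_genes = c("EF1a", "ACT", "UBCP"),
                                 meta = meta, calibrator = "t0")
  r2 <- relative_expression_ddcp(ds, target_genes = "CAT1",
                                 ref_genes = c("UBCP", "EF1a", "ACT"),
                                 meta = meta, calibrator = "t0")
  expect_equal(r1$folds$fold, r2$folds$fold, tolerance = 1e-12)

  # add a constant to every Cp of one biological replicate (loading effect)
  ds2 <- ds
  ds2$cp[, "t24", 2, 1] <- ds2$cp[, "t24", 2, 1] + 1.7
  r3 <- relative_expression_ddcp(ds2, target_genes = "CAT1",
                                 ref_genes = c("EF1a", "ACT", "UBCP"),
                                 meta = meta, calibrator = "t0")
  expect_equal(r3$folds$fold, r1$folds$fold, tolerance = 1e-10)
})

test_that("replicate summaries use arithmetic mean and n-1 SD", {
  folds <- data.frame(target = "T", condition = "c",
                      fold = c(2, 4))
  s <- summarize_replicates(folds)
  expect_equal(s$mean_fold, 3)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s$n_bio_reps, 2L)
  expect_warning(s1 <- summarize_replicates(
    data.frame(target = "T", condition = "c", fold = 2)),
    "single biological replicate")
  expect_equal(s1$sd, 0)
})

test_that("time-course estimates are unbiased at the simulated noise level", {
  set.seed(103)
  est <- matrix(NA_real_, 60, 5)
  for (i in seq_len(nrow(est))) {
    sim <- simulate_target_timecourse()
    ds <- suppressWarnings(collapse_technical_replicates(sim$dataset))
    res <- relative_expression_ddcp(ds, target_genes = "CAT1",
                                    ref_genes = sim$truth$ref_genes,
                                    meta = sim$metadata, calibrator = "t0")
    s <- res$summary[match(paste0("t", sim$truth$timepoints), res$summary$condition), ]
    est[i, ] <- s$mean_fold
  }
  truth <- sim$truth$profiles["CAT1", ]
  # Monte-Carlo means on the log scale within ~3 SE of the truth
  mc_mean <- colMeans(log2(est))
  mc_se <- apply(log2(est), 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(mc_mean - log2(truth)) < 3 * mc_se + 0.02))
})
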