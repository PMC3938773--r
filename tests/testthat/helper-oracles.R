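# Brute-force oracles, written independently of the package implementation:
# explicit loops over gene pairs and ratio vectors, geometric means via
# products, least squares via the closed-form normal equations.

oracle_v_matrix <- function(q) {
  genes <- rownames(q)
  n <- length(genes)
  v <- matrix(0, n, n, dimnames = list(genes, genes))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) next
      ratios <- c()
      for (obs in seq_len(ncol(q))) {
        a <- q[j, obs]; b <- q[k, obs]
        if (!is.na(a) && !is.na(b)) ratios <- c(ratios, log(a / b) / log(2))
      }
      m <- sum(ratios) / length(ratios)
      v[j, k] <- sqrt(sum((ratios - m)^2) / (length(ratios) - 1))
    }
  }
  v
}

oracle_m <- function(q, genes = rownames(q)) {
  v <- oracle_v_matrix(q[genes, , drop = FALSE])
  out <- numeric(length(genes))
  names(out) <- genes
  for (j in seq_along(genes)) {
    out[j] <- sum(v[j, -j]) / (length(genes) - 1)
  }
  out
}

oracle_nf <- function(q, genes) {
  apply(q[genes, , drop = FALSE], 2, function(x) prod(x)^(1 / length(x)))
}

oracle_nf_series <- function(q, ranking) {
  t(sapply(2:length(ranking), function(n) oracle_nf(q, ranking[seq_len(n)])))
}

oracle_vseries <- function(q, ranking) {
  sapply(2:(length(ranking) - 1), function(n) {
    r <- log(oracle_nf(q, ranking[seq_len(n)]) /
             oracle_nf(q, ranking[seq_len(n + 1)])) / log(2)
    sqrt(sum((r - mean(r))^2) / (length(r) - 1))
  })
}

# closed-form least squares of y on x (normal equations)
oracle_ls <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# random positive relative-quantity table (log-normal)
random_q <- function(n_gene, n_obs, sd = 1) {
  q <- matrix(2^rnorm(n_gene * n_obs, sd = sd), n_gene, n_obs,
              dimnames = list(paste0("g", seq_len(n_gene)),
                              paste0("o", seq_len(n_obs))))
  q
}
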