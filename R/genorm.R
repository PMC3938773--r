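#' Pairwise-variation matrix of log2 expression ratios
#'
#' The core geNorm quantity: for genes j and k, V(j,k) is the sample standard
#' deviation (n-1 denominator) over observations of log2(Q_j / Q_k). Two
#' ideal reference genes have a constant expression ratio, hence V = 0.
#' Observations missing for either gene are dropped pairwise.
#'
#' @param q relative-quantity matrix, genes x observations
#'   (see [to_relative_quantities()]).
#' @return symmetric genes x genes matrix with zero diagonal.
#' @export
pairwise_variation_matrix <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) < 2L) stop("need at least 2 genes")
  lq <- log2(q)
  n <- nrow(q)
  v <- matrix(0, n, n, dimnames = list(rownames(q), rownames(q)))
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      r <- lq[j, ] - lq[k, ]
      r <- r[!is.na(r)]
      if (length(r) < 2L) {
        stop(sprintf("genes %s and %s share fewer than 2 observations",
                     rownames(q)[j], rownames(q)[k]))
      }
      v[j, k] <- v[k, j] <- stats::sd(r)
    }
  }
  v
}

#' geNorm expression-stability value M
#'
#' M_j is the mean pairwise variation of gene j with all other genes in the
#' subset: the average over k != j of V(j,k). Lower M means more stable
#' expression. For a subset of two genes both carry the same M = V(j,k).
#'
#' @param q relative-quantity matrix.
#' @param genes gene subset to evaluate (default all rows of `q`).
#' @return named numeric vector of M values.
#' @export
stability_m <- function(q, genes = rownames(q)) {
  q <- as.matrix(q)
  if (length(genes) < 2L) stop("stability M needs a gene subset of size >= 2")
  missing_genes <- setdiff(genes, rownames(q))
  if (length(missing_genes) > 0L) {
    stop("gene(s) not in matrix: ", paste(missing_genes, collapse = ", "))
  }
  v <- pairwise_variation_matrix(q[genes, , drop = FALSE])
  m <- rowSums(v) / (length(genes) - 1L)
  m
}

#' Stepwise geNorm ranking by gene exclusion
#'
#' Iteratively computes M on the remaining gene set and removes the gene with
#' the highest M (an exact tie removes the tied gene appearing later in input
#' order), until two genes remain. The two final genes are the best pair and
#' are reported unordered, sharing their two-gene M value; every other gene's
#' reported M is its value at the iteration of its exclusion.
#'
#' @param q relative-quantity matrix with >= 3 genes.
#' @return list with `ranking` (all genes, most stable first; the first two
#'   are the unordered best pair in input order), `best_pair`, `exclusion_order`
#'   (first excluded = least stable), `m_values` (named, at exclusion time),
#'   and `table` (data frame `gene`, `m_value`, `rank`, `excluded_at_iteration`).
#' @export
rank_genes_stepwise <- function(q) {
  q <- as.matrix(q)
  n <- nrow(q)
  if (n < 3L) stop("stepwise ranking needs at least 3 genes")
  remaining <- rownames(q)
  excluded <- character(0)
  m_at_exclusion <- numeric(0)
  iter <- 0L
  while (length(remaining) > 2L) {
    iter <- iter + 1L
    m <- stability_m(q, remaining)
    # ties broken toward the gene later in input order
    worst_i <- max(which(m == max(m)))
    excluded <- c(excluded, remaining[worst_i])
    m_at_exclusion <- c(m_at_exclusion, m[worst_i])
    remaining <- remaining[-worst_i]
  }
  final_m <- stability_m(q, remaining)
  ranking <- c(remaining, rev(excluded))
  m_values <- c(final_m, rev(setNames(m_at_exclusion, excluded)))[ranking]
  table <- data.frame(
    gene = ranking,
    m_value = unname(m_values),
    rank = c(1L, 1L, seq(3L, n)),
    excluded_at_iteration = c(NA_integer_, NA_integer_,
                              rev(seq_len(n - 2L))),
    stringsAsFactors = FALSE)
  list(ranking = ranking, best_pair = remaining,
       exclusion_order = excluded, m_values = m_values, table = table)
}

#' Normalization-factor series over increasing gene numbers
#'
#' NF_n at an observation is the geometric mean of the relative quantities of
#' the n top-ranked genes; the series runs n = 2..N following the stepwise
#' ranking. NF_n does not depend on the internal order of the chosen genes.
#'
#' @param q relative-quantity matrix.
#' @param ranking gene names ordered most stable first (best pair first),
#'   covering all genes to include.
#' @return matrix (N-1) x observations; row `nf2` is the two-gene factor etc.
#' @export
normalization_factor_series <- function(q, ranking) {
  q <- as.matrix(q)
  missing_genes <- setdiff(ranking, rownames(q))
  if (length(missing_genes) > 0L) {
    stop("ranking gene(s) not in matrix: ", paste(missing_genes, collapse = ", "))
  }
  if (length(ranking) < 2L) stop("NF series needs at least 2 ranked genes")
  lq <- log2(q[ranking, , drop = FALSE])
  nf <- t(vapply(2:length(ranking), function(n) {
    2^colMeans(lq[seq_len(n), , drop = FALSE])
  }, numeric(ncol(q))))
  rownames(nf) <- paste0("nf", 2:length(ranking))
  colnames(nf) <- colnames(q)
  nf
}

#' Pairwise variation between sequential normalization factors
#'
#' V(n, n+1) is the standard deviation over observations of
#' log2(NF_n / NF_{n+1}); a large value means the (n+1)-th gene still changes
#' the normalization factor appreciably.
#'
#' @param nf matrix from [normalization_factor_series()].
#' @return data frame with columns `n` and `v` for n = 2..N-1.
#' @export
pairwise_variation_series <- function(nf) {
  n_rows <- nrow(nf)
  if (n_rows < 2L) stop("V series needs NF for at least n and n+1")
  ns <- as.integer(sub("^nf", "", rownames(nf)))
  v <- vapply(seq_len(n_rows - 1L), function(i) {
    r <- log2(nf[i, ] / nf[i + 1L, ])
    stats::sd(r[!is.na(r)])
  }, 0)
  data.frame(n = ns[-n_rows], v = v)
}

#' Optimal number of reference genes from the V series
#'
#' Returns the smallest n whose pairwise variation V(n, n+1) falls below the
#' cut-off (0.15 by default): below it, including an additional reference
#' gene is not required. When no V is below the cut-off the largest available
#' n is returned with `satisfiable = FALSE`; in that case using (at least)
#' the three most stable genes remains a valid normalization strategy, since
#' the cut-off is a guideline rather than a strict threshold.
#'
#' @param vseries data frame with columns `n` (consecutive, starting at 2)
#'   and `v`, as from [pairwise_variation_series()].
#' @param cutoff decision threshold on V. Default 0.15.
#' @return list with `n_optimal`, `satisfiable`, `cutoff`.
#' @export
optimal_gene_number <- function(vseries, cutoff = 0.15) {
  vseries <- as.data.frame(vseries)
  if (nrow(vseries) == 0L) stop("empty V series")
  if (vseries$n[1L] != 2L || any(diff(vseries$n) != 1L)) {
    stop("V series must have consecutive n starting at 2")
  }
  below <- which(vseries$v < cutoff)
  if (length(below) > 0L) {
    list(n_optimal = vseries$n[below[1L]], satisfiable = TRUE, cutoff = cutoff)
  } else {
    list(n_optimal = max(vseries$n), satisfiable = FALSE, cutoff = cutoff)
  }
}

#' Full geNorm analysis
#'
#' Runs the stepwise M ranking, builds the normalization-factor series along
#' the ranking, computes the pairwise-variation series and applies the
#' optimal-gene-number rule.
#'
#' @param q relative-quantity matrix (>= 3 genes).
#' @param cutoff V cut-off for the optimal gene number. Default 0.15.
#' @return object of class `genorm_result`: list with `table` (per-gene M and
#'   rank), `ranking`, `best_pair`, `exclusion_order`, `nf` (NF series
#'   matrix), `vseries`, `n_optimal`, `satisfiable`, `cutoff`.
#' @export
genorm <- function(q, cutoff = 0.15) {
  rk <- rank_genes_stepwise(q)
  nf <- normalization_factor_series(q, rk$ranking)
  vs <- pairwise_variation_series(nf)
  opt <- optimal_gene_number(vs, cutoff)
  structure(c(rk, list(nf = nf, vseries = vs, n_optimal = opt$n_optimal,
                       satisfiable = opt$satisfiable, cutoff = cutoff)),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability analysis\n")
  cat(sprintf("  best pair (unordered): %s (M = %.3f)\n",
              paste(x$best_pair, collapse = " / "),
              x$m_values[x$best_pair[1L]]))
  cat(sprintf("  least stable: %s (M = %.3f)\n",
              x$exclusion_order[1L], x$m_values[x$exclusion_order[1L]]))
  if (x$satisfiable) {
    cat(sprintf("  optimal number of reference genes: %d (first V < %.2f)\n",
                x$n_optimal, x$cutoff))
  } else {
    cat(sprintf("  no V below %.2f; consider using at least the 3 most stable genes\n",
                x$cutoff))
  }
  invisible(x)
}
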