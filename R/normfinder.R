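#' NormFinder model-based stability values
#'
#' Fits the model-based stability estimator to log2 relative quantities:
#' expression of gene i in sample j of group g is decomposed into a sample
#' effect (removed by centering each observation across genes), a
#' gene-by-group effect (the intergroup deviation d) and gene-specific
#' measurement error. The stability value rho combines the gene's shrunken
#' intergroup deviation with its intragroup prediction-error SD; lower rho
#' means more stable expression.
#'
#' The estimator, on y = log2(Q) with I genes and G groups of sizes n_g:
#' \enumerate{
#'   \item center each observation across genes: z_igj = y_igj - mean_i(y_igj);
#'   \item per gene x group sample variance s2_ig of z (denominator n_g - 1),
#'     bias-corrected for the centering:
#'     sigma2_ig = max(0, (s2_ig - (1/I^2) * sum_i' s2_i'g / (1 - 1/I)) / (1 - 2/I));
#'   \item intergroup deviations d_ig = mean_j(z_igj), centered per gene
#'     across groups;
#'   \item intergroup variance
#'     gamma2 = max(0, sum_ig d_ig^2 / ((I-1)(G-1)) - (1/(I G)) * sum_ig sigma2_ig / n_g);
#'   \item shrinkage d~_ig = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g);
#'   \item rho_i = (1/G) * sum_g ( |d~_ig| +
#'     sqrt( (gamma2 * sigma2_ig / n_g) / (gamma2 + sigma2_ig / n_g) ) ).
#' }
#' With a single group rho_i = sqrt(sigma2_i1). When gamma2 = 0 the shrunken
#' deviations and the prediction-error term are identically 0.
#'
#' @param q relative-quantity matrix, genes x observations (>= 3 genes; the
#'   bias correction requires 1 - 2/I > 0). Observations with any missing
#'   gene are dropped with a warning (the per-observation centering needs all
#'   genes).
#' @param groups group (condition) label per observation: either an unnamed
#'   vector aligned with `colnames(q)` or a named vector/list keyed by
#'   observation name. Every group needs at least 2 observations.
#' @return object of class `normfinder_result`: list with `table` (data frame
#'   `gene`, `stability_value`, `rank`), `rho` (named), `sigma2`, `dhat`,
#'   `dtilde` (genes x groups matrices), `gamma2`, `n_g`, `I`, `G`.
#' @export
normfinder_stability <- function(q, groups) {
  q <- as.matrix(q)
  I <- nrow(q)
  if (I < 3L) stop("NormFinder needs at least 3 genes (bias correction requires 1 - 2/I > 0)")
  if (!is.null(names(groups))) {
    if (is.null(colnames(q))) stop("named groups require observation names on q")
    missing_obs <- setdiff(colnames(q), names(groups))
    if (length(missing_obs) > 0L) {
      stop("observation(s) without group label: ",
           paste(missing_obs, collapse = ", "))
    }
    groups <- unlist(groups)[colnames(q)]
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(q)) {
    stop("need one group label per observation")
  }
  if (anyNA(groups) || any(groups == "")) stop("observation(s) without group label")
  keep <- colSums(is.na(q)) == 0L
  if (!all(keep)) {
    warning(sprintf("dropping %d observation(s) with missing values (complete genes required per observation)",
                    sum(!keep)), call. = FALSE)
    q <- q[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  group_levels <- unique(groups)
  G <- length(group_levels)
  n_g <- vapply(group_levels, function(g) sum(groups == g), 0L)
  if (any(n_g < 2L)) {
    stop("every group needs at least 2 observations; too small: ",
         paste(group_levels[n_g < 2L], collapse = ", "))
  }

  y <- log2(q)
  z <- sweep(y, 2L, colMeans(y))                      # per-observation centering

  s2 <- sapply(group_levels, function(g) {
    apply(z[, groups == g, drop = FALSE], 1L, stats::var)
  })
  s2 <- matrix(s2, nrow = I, dimnames = list(rownames(q), group_levels))
  sigma2 <- sapply(group_levels, function(g) {
    common <- (1 / I^2) * sum(s2[, g]) / (1 - 1 / I)
    pmax(0, (s2[, g] - common) / (1 - 2 / I))
  })
  sigma2 <- matrix(sigma2, nrow = I, dimnames = dimnames(s2))

  zbar <- sapply(group_levels, function(g) {
    rowMeans(z[, groups == g, drop = FALSE])
  })
  zbar <- matrix(zbar, nrow = I, dimnames = dimnames(s2))
  dhat <- zbar - rowMeans(zbar)                        # per-gene centering across groups

  if (G >= 2L) {
    gamma2 <- max(0, sum(dhat^2) / ((I - 1) * (G - 1)) -
                    (1 / (I * G)) * sum(sweep(sigma2, 2L, n_g, "/")))
  } else {
    gamma2 <- 0
  }

  se2 <- sweep(sigma2, 2L, n_g, "/")                   # sigma2_ig / n_g
  if (gamma2 > 0) {
    shrink <- gamma2 / (gamma2 + se2)
    dtilde <- dhat * shrink
    pred_err <- sqrt(gamma2 * se2 / (gamma2 + se2))
  } else {
    dtilde <- dhat * 0
    pred_err <- se2 * 0
  }

  if (G == 1L) {
    rho <- sqrt(sigma2[, 1L])
  } else {
    rho <- rowMeans(abs(dtilde) + pred_err)
  }
  names(rho) <- rownames(q)
  rk <- rank(rho, ties.method = "first")
  table <- data.frame(gene = rownames(q), stability_value = unname(rho),
                      rank = rk, stringsAsFactors = FALSE)
  structure(list(table = table, rho = rho, sigma2 = sigma2, dhat = dhat,
                 dtilde = dtilde, gamma2 = gamma2,
                 n_g = setNames(as.integer(n_g), group_levels),
                 I = I, G = G),
            class = "normfinder_result")
}

#' Ranked NormFinder stability table
#'
#' @param res a `normfinder_result` from [normfinder_stability()].
#' @return data frame `gene`, `stability_value`, `rank`, sorted ascending by
#'   stability value (most stable first); exact ties keep input order.
#' @export
rank_report <- function(res) {
  stopifnot(inherits(res, "normfinder_result"))
  out <- res$table[order(res$table$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.normfinder_result <- function(x, ...) {
  tab <- rank_report(x)
  cat(sprintf("NormFinder stability analysis (%d genes, %d group%s)\n",
              x$I, x$G, if (x$G == 1L) "" else "s"))
  cat(sprintf("  most stable: %s (rho = %.3f); least stable: %s (rho = %.3f)\n",
              tab$gene[1L], tab$stability_value[1L],
              tab$gene[nrow(tab)], tab$stability_value[nrow(tab)]))
  cat(sprintf("  intergroup variance gamma2 = %.4g\n", x$gamma2))
  invisible(x)
}
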