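#' Collapse technical replicates to their mean Cp
#'
#' Averages technical replicates on the Cp scale (standard qPCR practice:
#' Cp is already a log2-scale quantity) per (gene, sample, biological
#' replicate). Cells whose technical replicates are all missing stay missing;
#' a cell with only some replicates present is averaged over those, with an
#' informational note.
#'
#' @param ds a [cp_dataset].
#' @param spread_warn warn for any cell whose technical-replicate spread
#'   (max - min) exceeds this many cycles. Default 0.5.
#' @return a [cp_dataset] with a technical-replicate dimension of size 1.
#' @export
collapse_technical_replicates <- function(ds, spread_warn = 0.5) {
  stopifnot(inherits(ds, "cp_dataset"))
  cp <- ds$cp
  collapsed <- apply(cp, c(1, 2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  if (ds$n_tech >= 2L) {
    n_avail <- apply(cp, c(1, 2, 3), function(v) sum(!is.na(v)))
    partial <- sum(n_avail > 0L & n_avail < ds$n_tech)
    if (partial > 0L) {
      message(sprintf("collapse_technical_replicates: %d cell(s) averaged over fewer than %d technical replicates",
                      partial, ds$n_tech))
    }
    spread <- apply(cp, c(1, 2, 3), function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2L) max(v) - min(v) else 0
    })
    if (any(spread > spread_warn)) {
      warning(sprintf("%d cell(s) with technical-replicate spread > %g cycles",
                      sum(spread > spread_warn), spread_warn), call. = FALSE)
    }
  }
  out <- ds
  out$cp <- array(collapsed, dim = c(dim(collapsed), 1L),
                  dimnames = c(dimnames(collapsed)[1:2], list(NULL, NULL)))
  names(dimnames(out$cp)) <- c("gene", "sample", "", "")
  out$n_tech <- 1L
  out
}

#' Fit an amplification-efficiency standard curve
#'
#' Ordinary least squares of mean Cp per dilution point against
#' log10(template amount). The amplification efficiency is
#' E(\%) = (10^(-1/slope) - 1) x 100; a perfect doubling per cycle gives
#' slope -1/log10(2) = -3.3219 and E = 100\%.
#'
#' @param series data frame with columns `amount_ng` (positive template
#'   amounts) and `cp` (one row per replicate measurement), e.g. a fivefold
#'   dilution series 500, 100, 20, 4, 0.8 ng.
#' @return object of class `standard_curve`: list with `slope` (cycles per
#'   log10-ng), `intercept` (cycles), `r2`, `efficiency_pct`, `n_points`.
#' @export
fit_standard_curve <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("amount_ng", "cp") %in% names(series))) {
    stop("dilution series needs columns 'amount_ng' and 'cp'")
  }
  series <- series[!is.na(series$cp), , drop = FALSE]
  if (any(series$amount_ng <= 0)) stop("template amounts must be strictly positive")
  amounts <- sort(unique(series$amount_ng))
  if (length(amounts) < 3L) {
    stop("standard curve needs at least 3 distinct template amounts")
  }
  mean_cp <- vapply(amounts, function(a) mean(series$cp[series$amount_ng == a]), 0)
  x <- log10(amounts)
  if (var(x) == 0) stop("zero variance in log10(amount)")
  fit <- stats::lm(mean_cp ~ x)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mean_cp - mean(mean_cp))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency_pct = efficiency_from_slope(slope),
                 n_points = length(amounts)),
            class = "standard_curve")
}

#' Amplification efficiency from a standard-curve slope
#'
#' @param slope slope of Cp against log10(template amount), cycles per
#'   log10-ng (negative for amplification).
#' @return efficiency in percent: (10^(-1/slope) - 1) x 100.
#' @export
efficiency_from_slope <- function(slope) {
  (10^(-1 / slope) - 1) * 100
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, intercept %.2f, R2 %.4f, E %.1f%% (%d points)\n",
              x$slope, x$intercept, x$r2, x$efficiency_pct, x$n_points))
  invisible(x)
}

#' Transform Cp values to relative quantities Q
#'
#' Computes Q = b^(minCp - Cp) per gene, where minCp is that gene's minimum
#' observed Cp over the included observations and the base b is 2 (assumed
#' 100\% efficiency, the default) or 1 + E/100 per gene in
#' `efficiency_corrected` mode. Each observation is one (sample, biological
#' replicate) after technical-replicate collapse; Q lies in (0, 1] and each
#' gene's maximum Q is exactly 1.
#'
#' @param ds a [cp_dataset] with technical replicates already collapsed
#'   (`n_tech == 1`; see [collapse_technical_replicates()]).
#' @param mode `"base2"` or `"efficiency_corrected"`.
#' @param curves named list or vector mapping every gene to its
#'   [fit_standard_curve()] result (or directly to an efficiency in percent);
#'   required in `efficiency_corrected` mode.
#' @return an `rq_matrix`: numeric matrix genes x observations (columns named
#'   `<sample>.b<bio_rep>`), with attributes `min_cp` (per-gene minimum used)
#'   and `obs_info` (data frame `obs`, `sample`, `bio_rep`).
#' @export
to_relative_quantities <- function(ds, mode = c("base2", "efficiency_corrected"),
                                   curves = NULL) {
  stopifnot(inherits(ds, "cp_dataset"))
  mode <- match.arg(mode)
  if (ds$n_tech != 1L) {
    stop("collapse technical replicates before transforming to relative quantities")
  }
  d <- dim(ds$cp)
  cpm <- matrix(ds$cp, nrow = d[1], ncol = d[2] * d[3])
  rownames(cpm) <- ds$genes
  obs_info <- expand.grid(sample_i = seq_len(d[2]), bio_rep = seq_len(d[3]),
                          KEEP.OUT.ATTRS = FALSE)
  # array layout: columns vary sample fastest, then bio
  obs_info$sample <- ds$samples[obs_info$sample_i]
  obs_info$obs <- paste0(obs_info$sample, ".b", obs_info$bio_rep)
  colnames(cpm) <- obs_info$obs
  base <- rep(2, length(ds$genes))
  if (mode == "efficiency_corrected") {
    if (is.null(curves)) stop("efficiency_corrected mode requires per-gene curves")
    eff <- vapply(ds$genes, function(g) {
      cv <- curves[[g]]
      if (is.null(cv)) stop("no standard curve for gene ", g)
      if (inherits(cv, "standard_curve")) cv$efficiency_pct else as.numeric(cv)
    }, 0)
    base <- 1 + eff / 100
  }
  min_cp <- apply(cpm, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  q <- base^(min_cp - cpm)
  attr(q, "min_cp") <- min_cp
  attr(q, "obs_info") <- data.frame(obs = obs_info$obs, sample = obs_info$sample,
                                    bio_rep = obs_info$bio_rep,
                                    stringsAsFactors = FALSE)
  attr(q, "mode") <- mode
  class(q) <- c("rq_matrix", class(q))
  q
}

#' Drop genes too sparsely measured for stability analysis
#'
#' Genes missing in more than `max_missing` of the observations are excluded
#' with a warning; no imputation is done anywhere in the package.
#'
#' @param q relative-quantity matrix (genes x observations).
#' @param max_missing maximum tolerated fraction of missing observations per
#'   gene. Default 0.2.
#' @return `q` without the offending rows.
#' @export
drop_sparse_genes <- function(q, max_missing = 0.2) {
  frac <- rowMeans(is.na(q))
  drop <- frac > max_missing
  if (any(drop)) {
    warning(sprintf("excluding gene(s) missing in > %d%% of observations: %s",
                    round(100 * max_missing),
                    paste(rownames(q)[drop], collapse = ", ")), call. = FALSE)
    q <- q[!drop, , drop = FALSE]
  }
  q
}

#' Write per-gene standard-curve fits to CSV
#'
#' @param curves named list of `standard_curve` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standard_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(g) {
    cv <- curves[[g]]
    data.frame(gene = g, slope = cv$slope, intercept = cv$intercept,
               r2 = cv$r2, efficiency_pct = cv$efficiency_pct,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
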