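#' Multi-gene normalization factor
#'
#' NF at each observation is the geometric mean of the relative quantities of
#' the chosen reference genes; a single reference gene gives NF = Q.
#'
#' @param q relative-quantity matrix restricted to (or containing) the
#'   reference genes.
#' @param ref_genes character vector of reference genes (default all rows).
#' @return named numeric vector of NF values per observation.
#' @export
normalization_factor <- function(q, ref_genes = rownames(q)) {
  q <- as.matrix(q)
  missing_genes <- setdiff(ref_genes, rownames(q))
  if (length(missing_genes) > 0L) {
    stop("reference gene(s) not in matrix: ", paste(missing_genes, collapse = ", "))
  }
  sub <- q[ref_genes, , drop = FALSE]
  bad_obs <- colnames(sub)[colSums(is.na(sub)) > 0L]
  if (length(bad_obs) > 0L) {
    stop("missing reference quantity at observation(s): ",
         paste(bad_obs, collapse = ", "))
  }
  2^colMeans(log2(sub))
}

#' Relative expression by the 2^-ddCp method
#'
#' For each biological replicate, dCp = Cp_target - mean(Cp of the reference
#' genes); ddCp = dCp - mean dCp of the calibrator condition; fold change =
#' 2^-ddCp. Using the arithmetic mean of reference Cp values is algebraically
#' identical to dividing by the geometric-mean normalization factor, up to a
#' per-gene constant that cancels in ddCp. Fold changes are summarized as
#' mean and SD over biological replicates per condition (100\% amplification
#' efficiency assumed throughout, as in the plain ddCp method).
#'
#' @param targets [cp_dataset] holding the target genes (technical replicates
#'   collapsed).
#' @param refs [cp_dataset] holding the reference genes over the same samples
#'   and biological replicates; defaults to `targets` when both live in one
#'   table.
#' @param target_genes genes to quantify; default all genes of `targets` not
#'   used as references.
#' @param ref_genes character vector of reference genes.
#' @param meta sample metadata with the condition column.
#' @param calibrator condition label used as calibrator (e.g. time 0 or
#'   untreated control).
#' @param condition_col metadata column holding the condition. Default `"group"`.
#' @return object of class `expression_result`: list with `folds`
#'   (per-replicate data frame `target`, `condition`, `sample`, `bio_rep`,
#'   `fold`), `summary` (data frame `target`, `condition`, `mean_fold`, `sd`,
#'   `n_bio_reps`), `ref_genes`, `calibrator`.
#' @export
relative_expression_ddcp <- function(targets, refs = targets,
                                     target_genes = NULL, ref_genes,
                                     meta, calibrator,
                                     condition_col = "group") {
  stopifnot(inherits(targets, "cp_dataset"), inherits(refs, "cp_dataset"))
  if (targets$n_tech != 1L || refs$n_tech != 1L) {
    stop("collapse technical replicates before ddCp quantification")
  }
  meta <- as.data.frame(meta)
  if (!condition_col %in% names(meta)) {
    stop(sprintf("metadata lacks condition column '%s'", condition_col))
  }
  if (is.null(target_genes)) {
    target_genes <- setdiff(targets$genes, ref_genes)
  }
  missing_t <- setdiff(target_genes, targets$genes)
  if (length(missing_t) > 0L) {
    stop("target gene(s) absent: ", paste(missing_t, collapse = ", "))
  }
  missing_r <- setdiff(ref_genes, refs$genes)
  if (length(missing_r) > 0L) {
    stop("reference gene(s) absent: ", paste(missing_r, collapse = ", "))
  }
  samples <- intersect(targets$samples, refs$samples)
  if (length(samples) == 0L) stop("targets and refs share no samples")
  cond <- setNames(as.character(meta[[condition_col]]), meta$sample)[samples]
  if (anyNA(cond)) {
    stop("sample(s) without metadata: ",
         paste(samples[is.na(cond)], collapse = ", "))
  }
  if (!calibrator %in% cond) {
    stop(sprintf("calibrator condition '%s' not present in the data", calibrator))
  }
  n_bio <- min(targets$n_bio, refs$n_bio)

  grid <- expand.grid(sample = samples, bio_rep = seq_len(n_bio),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # mean reference Cp per (sample, bio_rep)
  ref_cp <- vapply(seq_len(nrow(grid)), function(i) {
    v <- refs$cp[ref_genes, grid$sample[i], grid$bio_rep[i], 1L]
    mean(v)
  }, 0)

  folds <- do.call(rbind, lapply(target_genes, function(tg) {
    t_cp <- vapply(seq_len(nrow(grid)), function(i) {
      targets$cp[tg, grid$sample[i], grid$bio_rep[i], 1L]
    }, 0)
    dcp <- t_cp - ref_cp
    cal <- cond[grid$sample] == calibrator
    cal_mean <- mean(dcp[cal], na.rm = TRUE)
    if (is.nan(cal_mean)) {
      stop(sprintf("no usable calibrator replicate for target %s", tg))
    }
    data.frame(target = tg, condition = unname(cond[grid$sample]),
               sample = grid$sample, bio_rep = grid$bio_rep,
               fold = 2^(-(dcp - cal_mean)), stringsAsFactors = FALSE)
  }))
  folds <- folds[!is.na(folds$fold), , drop = FALSE]
  rownames(folds) <- NULL
  structure(list(folds = folds,
                 summary = summarize_replicates(folds),
                 ref_genes = ref_genes, calibrator = calibrator),
            class = "expression_result")
}

#' Summarize per-replicate fold changes per condition
#'
#' @param folds data frame with columns `target`, `condition`, `fold` (one
#'   row per biological replicate).
#' @return data frame `target`, `condition`, `mean_fold`, `sd`, `n_bio_reps`;
#'   mean is arithmetic, SD uses the n-1 denominator, and a condition with a
#'   single replicate reports SD 0 with a warning.
#' @export
summarize_replicates <- function(folds) {
  folds <- as.data.frame(folds)
  stopifnot(all(c("target", "condition", "fold") %in% names(folds)))
  keys <- unique(folds[, c("target", "condition")])
  singletons <- character(0)
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    f <- folds$fold[folds$target == keys$target[i] &
                    folds$condition == keys$condition[i]]
    s <- if (length(f) >= 2L) stats::sd(f) else {
      singletons <<- c(singletons,
                       sprintf("%s/%s", keys$target[i], keys$condition[i]))
      0
    }
    data.frame(target = keys$target[i], condition = keys$condition[i],
               mean_fold = mean(f), sd = s, n_bio_reps = length(f),
               stringsAsFactors = FALSE)
  }))
  if (length(singletons) > 0L) {
    warning("single biological replicate (SD reported as 0) for: ",
            paste(singletons, collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("ddCp relative expression (refs: %s; calibrator: %s)\n",
              paste(x$ref_genes, collapse = ", "), x$calibrator))
  print(x$summary, digits = 3)
  invisible(x)
}
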