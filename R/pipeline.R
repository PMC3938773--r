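#' Samples belonging to a subset
#'
#' Subset membership may be multi-valued (semicolon-separated labels in the
#' metadata `subset` column), because control samples commonly belong to an
#' organ/tissue panel and serve as the control of one or more stress subsets.
#'
#' @param meta sample metadata.
#' @param subset subset label to match.
#' @return character vector of sample names.
#' @export
samples_in_subset <- function(meta, subset) {
  meta <- as.data.frame(meta)
  membership <- strsplit(meta$subset, ";", fixed = TRUE)
  meta$sample[vapply(membership, function(m) subset %in% trimws(m), TRUE)]
}

.subset_q <- function(ds, meta, subset) {
  if (is.null(subset)) return(ds)
  keep <- samples_in_subset(meta, subset)
  keep <- intersect(ds$samples, keep)
  if (length(keep) < 2L) {
    stop(sprintf("subset '%s' selects fewer than 2 samples", subset))
  }
  out <- ds
  out$cp <- ds$cp[, keep, , , drop = FALSE]
  out$samples <- keep
  out
}

#' Run the full stability workflow
#'
#' Validation, technical-replicate collapse, relative-quantity transform and
#' the requested stability methods, optionally restricted to one sample
#' subset. Per-gene minimum Cp values (and hence Q) are recomputed within
#' the analyzed subset; downstream statistics are invariant to that choice.
#' Genes missing in more than 20\% of observations are excluded with a
#' warning. Result tables are written when `out_dir` is given.
#'
#' @param ds a [cp_dataset] (technical replicates collapsed internally if
#'   needed).
#' @param meta sample metadata ([sample_metadata()]).
#' @param methods any of `"genorm"`, `"normfinder"`.
#' @param subset optional subset label; analysis restricted to its samples.
#' @param cutoff geNorm V cut-off. Default 0.15.
#' @param mode transform mode passed to [to_relative_quantities()].
#' @param curves per-gene standard curves for `efficiency_corrected` mode.
#' @param group_col metadata column used as NormFinder group. Default `"group"`.
#' @param out_dir optional output directory; writes `stability.csv`,
#'   `vseries.csv` and `summary.json`.
#' @return list with `validation`, `q`, `genorm`, `normfinder`, `summary`.
#' @export
run_stability <- function(ds, meta, methods = c("genorm", "normfinder"),
                          subset = NULL, cutoff = 0.15,
                          mode = "base2", curves = NULL,
                          group_col = "group", out_dir = NULL) {
  valid_methods <- c("genorm", "normfinder")
  unknown <- setdiff(methods, valid_methods)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown method(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(valid_methods, collapse = ", ")))
  }
  meta <- sample_metadata(as.data.frame(meta))
  report <- validate_dataset(ds, meta)
  if (!report$pass) {
    stop("dataset failed validation: ",
         paste(report$findings$message[report$findings$severity == "error"],
               collapse = "; "))
  }
  if (ds$n_tech > 1L) ds <- collapse_technical_replicates(ds)
  ds <- .subset_q(ds, meta, subset)
  q <- to_relative_quantities(ds, mode = mode, curves = curves)
  q <- drop_sparse_genes(q)

  out <- list(validation = report, q = q, subset = subset, cutoff = cutoff)
  stability_rows <- list()
  if ("genorm" %in% methods) {
    gn <- genorm(q, cutoff = cutoff)
    out$genorm <- gn
    stability_rows$genorm <- data.frame(
      gene = gn$table$gene, method = "genorm",
      stability_value = gn$table$m_value, rank = gn$table$rank,
      excluded_at_iteration = gn$table$excluded_at_iteration,
      stringsAsFactors = FALSE)
  }
  if ("normfinder" %in% methods) {
    obs_info <- attr(q, "obs_info")
    grp <- setNames(meta[[group_col]], meta$sample)[obs_info$sample]
    nf <- normfinder_stability(q, setNames(as.character(grp), obs_info$obs))
    out$normfinder <- nf
    stability_rows$normfinder <- data.frame(
      gene = nf$table$gene, method = "normfinder",
      stability_value = nf$table$stability_value, rank = nf$table$rank,
      excluded_at_iteration = NA_integer_, stringsAsFactors = FALSE)
  }
  out$stability_table <- do.call(rbind, c(stability_rows, make.row.names = FALSE))

  summary <- list(
    subset = if (is.null(subset)) "all" else subset,
    n_genes = nrow(q), n_observations = ncol(q), cutoff = cutoff)
  if (!is.null(out$genorm)) {
    summary$genorm <- list(
      best_pair = out$genorm$best_pair,
      best_pair_m = unname(out$genorm$m_values[out$genorm$best_pair[1L]]),
      least_stable = out$genorm$exclusion_order[1L],
      n_optimal = out$genorm$n_optimal,
      satisfiable = out$genorm$satisfiable)
    if (!out$genorm$satisfiable) {
      summary$genorm$note <- paste(
        "no pairwise variation fell below the cut-off;",
        "using at least the three most stable genes is a valid normalization strategy")
    }
  }
  if (!is.null(out$normfinder)) {
    best <- rank_report(out$normfinder)[1L, ]
    worst <- rank_report(out$normfinder)[out$normfinder$I, ]
    summary$normfinder <- list(
      best_gene = best$gene, best_stability = best$stability_value,
      least_stable = worst$gene, gamma2 = out$normfinder$gamma2)
  }
  out$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$stability_table,
                     file.path(out_dir, "stability.csv"), row.names = FALSE)
    if (!is.null(out$genorm)) {
      vs <- out$genorm$vseries
      vs$below_cutoff <- vs$v < cutoff
      utils::write.csv(vs, file.path(out_dir, "vseries.csv"), row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Run ddCp quantification and write the expression table
#'
#' @param ds [cp_dataset] with targets and references (technical replicates
#'   collapsed internally if needed).
#' @param meta sample metadata with the condition column.
#' @param ref_genes reference genes for the normalization factor.
#' @param calibrator calibrator condition label.
#' @param target_genes targets; default every non-reference gene.
#' @param condition_col metadata condition column. Default `"group"`.
#' @param out_dir optional; writes `expression.csv`.
#' @return an `expression_result` (see [relative_expression_ddcp()]).
#' @export
run_quantify <- function(ds, meta, ref_genes, calibrator,
                         target_genes = NULL, condition_col = "group",
                         out_dir = NULL) {
  if (ds$n_tech > 1L) ds <- collapse_technical_replicates(ds)
  res <- relative_expression_ddcp(ds, target_genes = target_genes,
                                  ref_genes = ref_genes, meta = meta,
                                  calibrator = calibrator,
                                  condition_col = condition_col)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- res$summary
    tab$refs_used <- paste(ref_genes, collapse = ";")
    utils::write.csv(tab, file.path(out_dir, "expression.csv"),
                     row.names = FALSE)
  }
  res
}

#' Simulate a dataset and write it to disk
#'
#' @param cfg a [sim_config] or path to a YAML configuration.
#' @param seed integer seed (overrides nothing else; the generator is driven
#'   entirely by this seed).
#' @param out_dir output directory; writes `cp.csv`, `meta.csv`, `truth.json`.
#' @return the [simulate_cp_dataset()] result, invisibly.
#' @export
run_simulate <- function(cfg = default_sim_config(), seed = 1L, out_dir) {
  if (is.character(cfg)) cfg <- read_sim_config(cfg)
  sim <- simulate_cp_dataset(cfg, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cp_table(sim$dataset, file.path(out_dir, "cp.csv"))
  utils::write.csv(sim$metadata, file.path(out_dir, "meta.csv"),
                   row.names = FALSE)
  truth <- sim$truth
  truth$effects <- as.data.frame(truth$effects)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}
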