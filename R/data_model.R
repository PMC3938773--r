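#' Construct a Cp dataset
#'
#' A `cp_dataset` holds quantification-cycle (Cp/Cq) values indexed by
#' gene x sample x biological replicate x technical replicate. Storage is a
#' rectangular 4-d array; absent measurements are `NA` (the missing mask).
#' Identifiers are case-sensitive opaque strings.
#'
#' @param df long-format data frame with columns `gene`, `sample`, `bio_rep`,
#'   `tech_rep`, `cp`. Replicate indices are positive integers; gaps in the
#'   grid become missing cells.
#' @param n_bio,n_tech declared replicate counts; default the maximum index
#'   present.
#'
#' @return An object of class `cp_dataset`: a list with elements `cp`
#'   (numeric array `[gene, sample, bio, tech]`), `genes`, `samples`,
#'   `n_bio`, `n_tech`.
#'
#' @details Every non-missing Cp must be finite and strictly positive
#'   (Cp is a cycle number); violations are an error, not a warning.
#'   Values that are merely unusual (outside 5--40 cycles) are flagged later
#'   by [validate_dataset()], not here.
#' @export
cp_dataset <- function(df, n_bio = NULL, n_tech = NULL) {
  required <- c("gene", "sample", "bio_rep", "tech_rep", "cp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty Cp table")
  df$gene <- as.character(df$gene)
  df$sample <- as.character(df$sample)
  df$bio_rep <- as.integer(df$bio_rep)
  df$tech_rep <- as.integer(df$tech_rep)
  df$cp <- as.numeric(df$cp)
  if (anyNA(df$bio_rep) || anyNA(df$tech_rep) ||
      any(df$bio_rep < 1L) || any(df$tech_rep < 1L)) {
    stop("bio_rep and tech_rep must be positive integers")
  }
  key <- paste(df$gene, df$sample, df$bio_rep, df$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate Cp entry for (%s, %s, bio %d, tech %d)",
                 dup$gene, dup$sample, dup$bio_rep, dup$tech_rep))
  }
  bad <- !is.na(df$cp) & (!is.finite(df$cp) | df$cp <= 0)
  if (any(bad)) {
    stop("Cp values must be finite and > 0; offending gene(s): ",
         paste(unique(df$gene[bad]), collapse = ", "))
  }
  genes <- unique(df$gene)
  samples <- unique(df$sample)
  if (length(genes) < 2L) stop("a cp_dataset needs at least 2 genes")
  if (length(samples) < 2L) stop("a cp_dataset needs at least 2 samples")
  if (is.null(n_bio)) n_bio <- max(df$bio_rep)
  if (is.null(n_tech)) n_tech <- max(df$tech_rep)
  if (max(df$bio_rep) > n_bio || max(df$tech_rep) > n_tech) {
    stop("replicate index exceeds declared replicate count")
  }
  cp <- array(NA_real_,
              dim = c(length(genes), length(samples), n_bio, n_tech),
              dimnames = list(gene = genes, sample = samples, NULL, NULL))
  idx <- cbind(match(df$gene, genes), match(df$sample, samples),
               df$bio_rep, df$tech_rep)
  cp[idx] <- df$cp
  structure(list(cp = cp, genes = genes, samples = samples,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech)),
            class = "cp_dataset")
}

#' @export
print.cp_dataset <- function(x, ...) {
  cat(sprintf("cp_dataset: %d genes x %d samples x %d bio x %d tech replicates\n",
              length(x$genes), length(x$samples), x$n_bio, x$n_tech))
  n_missing <- sum(is.na(x$cp))
  cat(sprintf("  Cp range: %.2f - %.2f; %d missing cell(s)\n",
              suppressWarnings(min(x$cp, na.rm = TRUE)),
              suppressWarnings(max(x$cp, na.rm = TRUE)), n_missing))
  invisible(x)
}

#' Flatten a Cp dataset to the canonical long data frame
#'
#' @param ds a [cp_dataset].
#' @param drop_missing drop rows whose Cp is missing (default `FALSE`; the
#'   canonical representation keeps the full rectangular grid so the missing
#'   mask survives a write/read round trip).
#' @return data frame with columns `gene`, `sample`, `bio_rep`, `tech_rep`, `cp`.
#' @export
cp_long <- function(ds, drop_missing = FALSE) {
  stopifnot(inherits(ds, "cp_dataset"))
  d <- dim(ds$cp)
  out <- expand.grid(gene_i = seq_len(d[1]), sample_i = seq_len(d[2]),
                     bio_rep = seq_len(d[3]), tech_rep = seq_len(d[4]),
                     KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(gene = ds$genes[out$gene_i],
                    sample = ds$samples[out$sample_i],
                    bio_rep = out$bio_rep, tech_rep = out$tech_rep,
                    cp = ds$cp[cbind(out$gene_i, out$sample_i,
                                     out$bio_rep, out$tech_rep)],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$gene, ds$genes), match(out$sample, ds$samples),
                   out$bio_rep, out$tech_rep), , drop = FALSE]
  rownames(out) <- NULL
  if (drop_missing) out <- out[!is.na(out$cp), , drop = FALSE]
  out
}

# delimiter sniffing: .tsv/.txt -> tab, anything else -> comma
.sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.parse_numeric_cells <- function(x, context) {
  x_chr <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x_chr))
  unparseable <- is.na(out) & !(is.na(x_chr) | x_chr == "" | toupper(x_chr) == "NA")
  if (any(unparseable)) {
    warning(sprintf("%d unparseable numeric cell(s) in %s set to missing (e.g. \"%s\")",
                    sum(unparseable), context, x_chr[unparseable][1L]),
            call. = FALSE)
  }
  out
}

#' Read a Cp table from CSV/TSV
#'
#' @param path file path; delimiter sniffed from the extension (`.tsv`/`.txt`
#'   are tab-separated, everything else comma) unless `sep` is given.
#' @param layout `"long"` (columns `gene,sample,bio_rep,tech_rep,cp`; the
#'   canonical format) or `"wide"` (a `gene` column plus one column per
#'   `<sample>__b<i>_t<j>` combination).
#' @param sep optional delimiter override.
#' @return a [cp_dataset]. Unparseable numeric cells become missing with a
#'   warning; empty cells and `"NA"` are missing without comment.
#' @export
read_cp_table <- function(path, layout = c("long", "wide"), sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniff_sep(path, sep)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty Cp table: ", path)
  if (layout == "long") {
    required <- c("gene", "sample", "bio_rep", "tech_rep", "cp")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("long Cp table lacks column(s): ", paste(missing_cols, collapse = ", "))
    }
    raw$cp <- .parse_numeric_cells(raw$cp, "column 'cp'")
    return(cp_dataset(raw))
  }
  # wide layout
  if (!"gene" %in% names(raw)) stop("wide Cp table lacks a 'gene' column")
  value_cols <- setdiff(names(raw), "gene")
  m <- regmatches(value_cols, regexec("^(.+)__b([0-9]+)_t([0-9]+)$", value_cols))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("wide column name(s) not of form <sample>__b<i>_t<j>: ",
         paste(value_cols[bad], collapse = ", "))
  }
  pieces <- do.call(rbind, lapply(m, `[`, 2:4))
  long <- do.call(rbind, lapply(seq_along(value_cols), function(k) {
    data.frame(gene = raw$gene,
               sample = pieces[k, 1L],
               bio_rep = as.integer(pieces[k, 2L]),
               tech_rep = as.integer(pieces[k, 3L]),
               cp = .parse_numeric_cells(raw[[value_cols[k]]],
                                         sprintf("column '%s'", value_cols[k])),
               stringsAsFactors = FALSE)
  }))
  cp_dataset(long)
}

#' Write a Cp dataset as canonical long-format CSV
#'
#' The full rectangular grid is written, with `NA` for missing cells, so that
#' write-then-read is lossless for values, identifiers and the missing mask.
#'
#' @param ds a [cp_dataset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cp_table <- function(ds, path) {
  df <- cp_long(ds)
  # 17 significant digits represent a double exactly
  df$cp <- ifelse(is.na(df$cp), NA, formatC(df$cp, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a sample-metadata table
#'
#' @param path CSV/TSV with required columns `sample`, `subset`, `group`;
#'   `tissue` and any extra columns are carried through as attributes of the
#'   analysis (e.g. the subset labels `organ_tissue`, `abiotic`, `biotic` of a
#'   tissue/stress survey, and the condition used as NormFinder group).
#' @param sep optional delimiter override.
#' @return data frame, one row per sample, class `c("sample_metadata","data.frame")`.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniff_sep(path, sep)
  meta <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  sample_metadata(meta)
}

#' Construct sample metadata from a data frame
#'
#' @param meta data frame with columns `sample`, `subset`, `group` (required)
#'   and optionally `tissue` plus free-form attribute columns.
#' @return validated metadata data frame.
#' @export
sample_metadata <- function(meta) {
  for (col in c("sample", "subset", "group")) {
    if (!col %in% names(meta)) {
      stop(sprintf("metadata lacks required column '%s'", col))
    }
  }
  meta$sample <- as.character(meta$sample)
  meta$subset <- as.character(meta$subset)
  meta$group <- as.character(meta$group)
  if (anyDuplicated(meta$sample)) {
    stop("duplicate sample row(s): ",
         paste(unique(meta$sample[duplicated(meta$sample)]), collapse = ", "))
  }
  if (any(is.na(meta$subset) | meta$subset == "") ||
      any(is.na(meta$group) | meta$group == "")) {
    stop("subset and group labels must be non-empty for every sample")
  }
  rownames(meta) <- NULL
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

.finding <- function(severity, code, message) {
  data.frame(severity = severity, code = code, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a Cp dataset against its metadata
#'
#' Pure structural QC: cross-checks the sample sets, flags Cp values outside
#' the plausible range, counts missing cells, and reports technical-replicate
#' spread. Findings are reported, never thrown; `pass` is `FALSE` iff at
#' least one error-severity finding exists.
#'
#' @param ds a [cp_dataset].
#' @param meta optional sample metadata ([sample_metadata()]).
#' @param cp_range plausible Cp range in cycles; values outside give a
#'   warning-severity finding. Default `c(5, 40)` (a 40-cycle protocol).
#' @param tech_spread_warn technical-replicate spread (max - min, cycles)
#'   above which a warning finding is emitted. Default 0.5.
#' @return a `validation_report`: list with `counts`, `findings`
#'   (data frame `severity`, `code`, `message`) and logical `pass`.
#' @export
validate_dataset <- function(ds, meta = NULL, cp_range = c(5, 40),
                             tech_spread_warn = 0.5) {
  stopifnot(inherits(ds, "cp_dataset"))
  findings <- list()
  if (!is.null(meta)) {
    meta <- sample_metadata(as.data.frame(meta))
    missing_meta <- setdiff(ds$samples, meta$sample)
    if (length(missing_meta) > 0L) {
      findings[[length(findings) + 1L]] <- .finding(
        "error", "sample_without_metadata",
        paste0("sample(s) in Cp table but absent from metadata: ",
               paste(missing_meta, collapse = ", ")))
    }
    extra_meta <- setdiff(meta$sample, ds$samples)
    if (length(extra_meta) > 0L) {
      findings[[length(findings) + 1L]] <- .finding(
        "warning", "metadata_without_sample",
        paste0("metadata row(s) without Cp data: ",
               paste(extra_meta, collapse = ", ")))
    }
  }
  cp <- ds$cp
  out_of_range <- sum(!is.na(cp) & (cp < cp_range[1] | cp > cp_range[2]))
  if (out_of_range > 0L) {
    findings[[length(findings) + 1L]] <- .finding(
      "warning", "cp_out_of_typical_range",
      sprintf("%d Cp value(s) out of typical range [%g, %g] cycles",
              out_of_range, cp_range[1], cp_range[2]))
  }
  n_missing <- sum(is.na(cp))
  if (n_missing > 0L) {
    findings[[length(findings) + 1L]] <- .finding(
      "warning", "missing_cells",
      sprintf("%d missing Cp cell(s) (%.1f%% of the grid)",
              n_missing, 100 * n_missing / length(cp)))
  }
  if (ds$n_tech >= 2L) {
    spread <- apply(cp, c(1, 2, 3), function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2L) max(v) - min(v) else 0
    })
    n_spread <- sum(spread > tech_spread_warn)
    if (n_spread > 0L) {
      findings[[length(findings) + 1L]] <- .finding(
        "warning", "tech_replicate_spread",
        sprintf("%d cell(s) with technical-replicate spread > %g cycles",
                n_spread, tech_spread_warn))
    }
  }
  findings <- if (length(findings) > 0L) {
    do.call(rbind, findings)
  } else {
    .finding(character(0), character(0), character(0))
  }
  structure(list(
    counts = list(genes = length(ds$genes), samples = length(ds$samples),
                  bio_reps = ds$n_bio, tech_reps = ds$n_tech,
                  missing_cells = n_missing),
    findings = findings,
    pass = !any(findings$severity == "error")
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %s (%d genes, %d samples, %dx%d replicates)\n",
              if (x$pass) "PASS" else "FAIL",
              x$counts$genes, x$counts$samples,
              x$counts$bio_reps, x$counts$tech_reps))
  if (nrow(x$findings) > 0L) {
    for (i in seq_len(nrow(x$findings))) {
      cat(sprintf("  [%s] %s\n", x$findings$severity[i], x$findings$message[i]))
    }
  } else cat("  no findings\n")
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report a `validation_report` from [validate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(
    list(counts = report$counts, pass = report$pass,
         findings = report$findings),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
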