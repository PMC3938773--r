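#' Simulation configuration for synthetic Cp datasets
#'
#' Assembles and validates the parameters of the Cp generative model:
#'
#'   Cp(gene, sample, bio, tech) = base_cp_gene + effect(gene, group(sample))
#'     + loading(sample, bio) + bio_noise(gene, sample, bio) + tech_noise
#'
#' All noise terms are Gaussian on the Cp scale; Cp is a log2-scale quantity,
#' so this corresponds to log-normal expression noise, the standard qPCR
#' error model. Loading shifts are drawn per (sample, biological replicate)
#' — one RNA extraction / cDNA synthesis — and are common to all genes,
#' which is exactly the variation reference-gene normalization removes.
#'
#' @param genes gene names (unique).
#' @param base_cp per-gene baseline Cp in cycles.
#' @param bio_sd per-gene biological log2-noise SD (cycles; Cp cycles are
#'   log2 units).
#' @param design data frame with columns `sample`, `subset`, `group` (and
#'   optionally `tissue`) defining the sample layout.
#' @param effects genes x conditions matrix of condition effects in cycles;
#'   column names must cover every group label in `design`. Default all 0.
#' @param tech_sd technical noise SD in cycles. Default 0.15.
#' @param loading_sd loading-shift SD in cycles. Default 0.5.
#' @param n_bio,n_tech biological / technical replicate counts. Defaults 3, 2.
#' @param stable_genes designated stable genes (ground truth for recovery
#'   experiments).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(genes, base_cp, bio_sd, design, effects = NULL,
                       tech_sd = 0.15, loading_sd = 0.5,
                       n_bio = 3L, n_tech = 2L, stable_genes = character(0)) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (length(base_cp) != length(genes)) stop("base_cp must match genes")
  if (length(bio_sd) != length(genes)) stop("bio_sd must match genes")
  if (any(bio_sd < 0) || tech_sd < 0 || loading_sd < 0) {
    stop("noise SDs must be >= 0")
  }
  if (n_bio < 1L || n_tech < 1L) stop("replicate counts must be >= 1")
  design <- sample_metadata(as.data.frame(design))
  conditions <- unique(design$group)
  if (is.null(effects)) {
    effects <- matrix(0, length(genes), length(conditions),
                      dimnames = list(genes, conditions))
  } else {
    effects <- as.matrix(effects)
    if (!all(genes %in% rownames(effects)) ||
        !all(conditions %in% colnames(effects))) {
      stop("effects matrix must cover every gene and every group label")
    }
    effects <- effects[genes, conditions, drop = FALSE]
  }
  if (!all(stable_genes %in% genes)) stop("stable_genes must be among genes")
  structure(list(genes = genes,
                 base_cp = setNames(as.numeric(base_cp), genes),
                 bio_sd = setNames(as.numeric(bio_sd), genes),
                 design = design, effects = effects,
                 tech_sd = tech_sd, loading_sd = loading_sd,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 stable_genes = as.character(stable_genes)),
            class = "sim_config")
}

#' Default configuration: a 15-gene, 20-sample reference-gene survey
#'
#' Mirrors the design of a multi-condition reference-gene validation study:
#' 15 candidate housekeeping genes assayed over 20 samples in three
#' overlapping subsets — 10 organs/tissues under normal growth, 8
#' abiotic-stress samples (control/drought/salt/cold, root and leaf) and 6
#' biotic-stress samples (control and two pathogen infections, root and
#' leaf); the normal-growth root and leaf samples double as the controls of
#' both stress subsets, so subset membership is encoded as a
#' semicolon-separated list in the `subset` column (see
#' [samples_in_subset()]). Replication is 3 biological x 2 technical.
#' Baseline Cp values span 8.4 (an 18S rRNA-like, highly abundant gene) to
#' 24.8 cycles, most genes between 18 and 24. Two designated stable genes
#' (YLS8, PTB) carry log2 noise SD 0.15 and no condition effects; all other
#' genes have SD >= 0.6 and/or condition shifts >= 1 cycle (the rRNA18S- and
#' GAPDH-like genes get explicit stress-dependent shifts), so most genes
#' span about five to six cycles across samples.
#'
#' @return a [sim_config].
#' @export
default_sim_config <- function() {
  genes <- c("rRNA18S", "ACT", "TUA", "TUB", "EF1a", "GAPDH", "UBC", "UBCP",
             "PP2A", "YLS8", "SAND", "TIP41", "PTB", "IDH", "CAC")
  base_cp <- c(rRNA18S = 8.4, ACT = 19.5, TUA = 20.0, TUB = 20.5, EF1a = 18.5,
               GAPDH = 19.0, UBC = 21.0, UBCP = 21.5, PP2A = 22.0, YLS8 = 22.5,
               SAND = 23.0, TIP41 = 23.5, PTB = 21.8, IDH = 18.2, CAC = 24.8)
  bio_sd <- c(rRNA18S = 1.1, ACT = 0.7, TUA = 0.6, TUB = 0.75, EF1a = 0.7,
              GAPDH = 0.8, UBC = 1.0, UBCP = 0.6, PP2A = 0.6, YLS8 = 0.15,
              SAND = 0.7, TIP41 = 0.65, PTB = 0.15, IDH = 0.9, CAC = 0.7)
  all3 <- "organ_tissue;abiotic;biotic"
  design <- data.frame(
    sample = c("root", "leaf", "stem", "tendril", "pistil", "stamen", "petal",
               "ovary", "fruit_15d", "fruit_31d",
               "drought_root", "drought_leaf", "salt_root", "salt_leaf",
               "cold_root", "cold_leaf",
               "fusarium_root", "fusarium_leaf", "blotch_root", "blotch_leaf"),
    subset = c(all3, all3, rep("organ_tissue", 8),
               rep("abiotic", 6), rep("biotic", 4)),
    group = c("control", "control", rep("normal", 8),
              "drought", "drought", "salt", "salt", "cold", "cold",
              "fusarium", "fusarium", "blotch", "blotch"),
    tissue = c("root", "leaf", "stem", "tendril", "pistil", "stamen", "petal",
               "ovary", "fruit", "fruit",
               rep(c("root", "leaf"), 5)),
    stringsAsFactors = FALSE)
  conditions <- unique(design$group)
  effects <- matrix(0, length(genes), length(conditions),
                    dimnames = list(genes, conditions))
  # abundant rRNA responds to every stress; a glycolytic gene to cold/infection
  effects["rRNA18S", c("drought", "salt", "cold", "fusarium", "blotch")] <-
    c(1.5, 1.2, -1.0, 1.0, -1.2)
  effects["rRNA18S", "normal"] <- 0.5
  effects["GAPDH", c("cold", "fusarium")] <- c(1.2, -1.0)
  effects["IDH", c("drought", "blotch")] <- c(1.0, -1.0)
  sim_config(genes, base_cp, bio_sd, design, effects,
             stable_genes = c("YLS8", "PTB"))
}

#' Simulate a Cp dataset with known ground truth
#'
#' Draws a full gene x sample x biological x technical Cp grid from the
#' generative model described in [sim_config()]. Identical seeds give
#' identical datasets.
#'
#' @param cfg a [sim_config]; default [default_sim_config()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list with `dataset` (a [cp_dataset]), `metadata`
#'   ([sample_metadata()]) and `truth` (stable genes, per-gene noise SDs,
#'   condition effects).
#' @export
simulate_cp_dataset <- function(cfg = default_sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- cfg$genes
  samples <- cfg$design$sample
  n_gene <- length(genes)
  n_samp <- length(samples)
  grp <- setNames(cfg$design$group, samples)

  loading <- matrix(rnorm(n_samp * cfg$n_bio, 0, cfg$loading_sd),
                    n_samp, cfg$n_bio)
  cp <- array(NA_real_, dim = c(n_gene, n_samp, cfg$n_bio, cfg$n_tech),
              dimnames = list(gene = genes, sample = samples, NULL, NULL))
  for (s in seq_len(n_samp)) {
    eff <- cfg$effects[, grp[s]]
    for (b in seq_len(cfg$n_bio)) {
      true_cp <- cfg$base_cp + eff + loading[s, b] +
        rnorm(n_gene, 0, cfg$bio_sd)
      for (t in seq_len(cfg$n_tech)) {
        cp[, s, b, t] <- true_cp + rnorm(n_gene, 0, cfg$tech_sd)
      }
    }
  }
  df <- data.frame(
    gene = rep(genes, times = n_samp * cfg$n_bio * cfg$n_tech),
    sample = rep(rep(samples, each = n_gene), times = cfg$n_bio * cfg$n_tech),
    bio_rep = rep(rep(seq_len(cfg$n_bio), each = n_gene * n_samp),
                  times = cfg$n_tech),
    tech_rep = rep(seq_len(cfg$n_tech), each = n_gene * n_samp * cfg$n_bio),
    cp = as.vector(cp), stringsAsFactors = FALSE)
  list(dataset = cp_dataset(df, n_bio = cfg$n_bio, n_tech = cfg$n_tech),
       metadata = cfg$design,
       truth = list(stable_genes = cfg$stable_genes, bio_sd = cfg$bio_sd,
                    effects = cfg$effects, base_cp = cfg$base_cp,
                    loading_sd = cfg$loading_sd, tech_sd = cfg$tech_sd))
}

#' Simulate a dilution-series for standard-curve fitting
#'
#' Generates Cp measurements for a serial dilution (default the fivefold
#' series 500, 100, 20, 4, 0.8 ng) under a known amplification efficiency:
#' Cp(a) = intercept - log10(a) / log10(1 + E/100) + noise. With zero noise,
#' [fit_standard_curve()] recovers E exactly.
#'
#' @param efficiency_pct true amplification efficiency in percent, in (1, 200].
#' @param intercept Cp at 1 ng. Default 25.
#' @param noise_sd Gaussian Cp noise SD in cycles. Default 0.
#' @param seed optional integer seed.
#' @param amounts template amounts in ng (strictly positive). Default
#'   `c(500, 100, 20, 4, 0.8)`.
#' @param reps technical replicates per point. Default 2.
#' @return data frame `amount_ng`, `cp` with attribute `true_slope`.
#' @export
simulate_dilution_series <- function(efficiency_pct = 100, intercept = 25,
                                     noise_sd = 0, seed = NULL,
                                     amounts = c(500, 100, 20, 4, 0.8),
                                     reps = 2L) {
  if (efficiency_pct <= 1 || efficiency_pct > 200) {
    stop("efficiency must be in (1, 200] percent")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(amounts <= 0)) stop("template amounts must be strictly positive")
  if (!is.null(seed)) set.seed(seed)
  slope <- -1 / log10(1 + efficiency_pct / 100)
  amount <- rep(amounts, each = reps)
  cp <- intercept + slope * log10(amount) + rnorm(length(amount), 0, noise_sd)
  out <- data.frame(amount_ng = amount, cp = cp)
  attr(out, "true_slope") <- slope
  out
}

#' Simulate a target-gene time course for ddCp validation
#'
#' Generates Cp data for target genes whose expression follows known
#' fold-change profiles over a stress time course (default: three
#' catalase-like targets over 0/12/24/36/48 h, up-regulated within the first
#' 24 h and declining afterwards), together with stable reference genes.
#' Target Cp at time t is shifted by -log2(fold(t)) relative to time 0.
#'
#' @param profiles targets x timepoints matrix of true fold changes relative
#'   to the first timepoint. Default three up-then-down profiles peaking at
#'   24 h (`CAT1` reaching fold 4).
#' @param timepoints timepoint labels in hours. Default `c(0, 12, 24, 36, 48)`.
#' @param target_base_cp baseline Cp per target at time 0.
#' @param ref_genes reference gene names. Default `c("EF1a", "ACT", "UBCP")`.
#' @param ref_base_cp baseline Cp per reference gene.
#' @param target_sd biological log2-noise SD of the targets. Default 0.2.
#' @param ref_sd biological log2-noise SD of the references. Default 0.15.
#' @param tech_sd,loading_sd,n_bio,n_tech as in [sim_config()].
#' @param seed optional integer seed.
#' @return list with `dataset` (targets and references in one [cp_dataset]),
#'   `metadata` (one sample per timepoint, `group` = timepoint label) and
#'   `truth` (the profile matrix and noise levels).
#' @export
simulate_target_timecourse <- function(profiles = NULL,
                                       timepoints = c(0, 12, 24, 36, 48),
                                       target_base_cp = NULL,
                                       ref_genes = c("EF1a", "ACT", "UBCP"),
                                       ref_base_cp = NULL,
                                       target_sd = 0.2, ref_sd = 0.15,
                                       tech_sd = 0.15, loading_sd = 0.5,
                                       n_bio = 3L, n_tech = 2L, seed = NULL) {
  if (is.null(profiles)) {
    profiles <- rbind(CAT1 = c(1, 2, 4, 2, 1),
                      CAT2 = c(1, 3, 6, 3, 1.5),
                      CAT3 = c(1, 1.5, 2, 1.5, 1))
  }
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != length(timepoints)) {
    stop("fold profile must be defined at every timepoint")
  }
  if (any(profiles <= 0)) stop("fold changes must be strictly positive")
  targets <- rownames(profiles)
  if (is.null(target_base_cp)) {
    target_base_cp <- setNames(24 + seq_along(targets), targets)
  }
  if (is.null(ref_base_cp)) {
    ref_base_cp <- setNames(c(18.5, 19.5, 21.5)[seq_along(ref_genes)], ref_genes)
  }
  if (!is.null(seed)) set.seed(seed)
  samples <- paste0("t", timepoints)
  genes <- c(targets, ref_genes)
  n_samp <- length(samples)
  cp <- array(NA_real_, dim = c(length(genes), n_samp, n_bio, n_tech),
              dimnames = list(gene = genes, sample = samples, NULL, NULL))
  for (s in seq_len(n_samp)) {
    for (b in seq_len(n_bio)) {
      load <- rnorm(1, 0, loading_sd)
      t_cp <- target_base_cp - log2(profiles[, s]) +
        rnorm(length(targets), 0, target_sd)
      r_cp <- ref_base_cp + rnorm(length(ref_genes), 0, ref_sd)
      true_cp <- c(t_cp, r_cp) + load
      for (t in seq_len(n_tech)) {
        cp[, s, b, t] <- true_cp + rnorm(length(genes), 0, tech_sd)
      }
    }
  }
  df <- data.frame(
    gene = rep(genes, times = n_samp * n_bio * n_tech),
    sample = rep(rep(samples, each = length(genes)), times = n_bio * n_tech),
    bio_rep = rep(rep(seq_len(n_bio), each = length(genes) * n_samp),
                  times = n_tech),
    tech_rep = rep(seq_len(n_tech), each = length(genes) * n_samp * n_bio),
    cp = as.vector(cp), stringsAsFactors = FALSE)
  meta <- sample_metadata(data.frame(
    sample = samples, subset = "timecourse", group = samples,
    hours = timepoints, stringsAsFactors = FALSE))
  list(dataset = cp_dataset(df, n_bio = n_bio, n_tech = n_tech),
       metadata = meta,
       truth = list(profiles = profiles, timepoints = timepoints,
                    targets = targets, ref_genes = ref_genes,
                    target_sd = target_sd, ref_sd = ref_sd))
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors the fields of [sim_config()]: `genes`, `base_cp`,
#' `bio_sd`, `tech_sd`, `loading_sd`, `n_bio`, `n_tech`, `stable_genes`,
#' a `design` list of sample records and an optional `effects` mapping
#' `gene -> {condition: shift}`.
#'
#' @param path YAML file path.
#' @return a [sim_config].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  for (field in c("genes", "base_cp", "bio_sd", "design")) {
    if (is.null(y[[field]])) stop("simulation config lacks field '", field, "'")
  }
  design <- do.call(rbind, lapply(y$design, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  genes <- unlist(y$genes)
  conditions <- unique(design$group)
  effects <- matrix(0, length(genes), length(conditions),
                    dimnames = list(genes, conditions))
  if (!is.null(y$effects)) {
    for (g in names(y$effects)) {
      for (cond in names(y$effects[[g]])) {
        effects[g, cond] <- as.numeric(y$effects[[g]][[cond]])
      }
    }
  }
  sim_config(genes = genes,
             base_cp = unlist(y$base_cp)[genes],
             bio_sd = unlist(y$bio_sd)[genes],
             design = design, effects = effects,
             tech_sd = y$tech_sd %||% 0.15,
             loading_sd = y$loading_sd %||% 0.5,
             n_bio = y$n_bio %||% 3L, n_tech = y$n_tech %||% 2L,
             stable_genes = unlist(y$stable_genes) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
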