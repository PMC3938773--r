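---
title: "Validating qRT-PCR reference genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating qRT-PCR reference genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative real-time PCR expresses a transcript's abundance as a
quantification cycle Cp (also written Cq or Ct): the PCR cycle at which
fluorescence crosses a detection threshold. Cp is a log2-scale quantity —
one cycle is one doubling — and it confounds the biology of interest with
the amount and quality of input material. The standard fix is to normalize
target genes against *reference* (housekeeping) genes assumed stable across
the samples. That assumption fails often enough that reference genes must
themselves be validated per tissue panel and per stress condition; this
package implements the two standard validation statistics (geNorm and
NormFinder), the decision rule for how many reference genes a normalization
factor needs, and the downstream 2^-ddCp quantification, together with a
synthetic Cp generator that provides ground truth for all of them.

## From Cp to relative quantities

Technical replicates are first collapsed by their arithmetic mean on the Cp
scale (Cp is already logarithmic; averaging on the linear scale would
weight replicates unequally). Both stability algorithms expect linear-scale
input, so Cp values are transformed per gene to relative quantities

> Q = 2^(minCp − Cp),

where minCp is the gene's minimum Cp over the analyzed observations; the
most abundant observation of each gene thus gets Q = 1 and all Q lie in
(0, 1]. The base 2 assumes 100% amplification efficiency, matching the
conventional form of both the Q transform and the 2^-ddCp method; an
efficiency-corrected mode, Q = (1 + E/100)^(minCp − Cp) with per-gene E
from standard curves, is available as an explicit opt-in. When an analysis
is restricted to a sample subset, minCp is recomputed within the subset.
Both choices are cosmetic for the statistics below: every per-gene rescaling
of Q cancels in the log-ratios geNorm uses and in NormFinder's centering
(the invariance tests assert exactly this).

Amplification efficiency is estimated from a dilution series by ordinary
least squares of mean Cp per point against log10(template amount):
E(%) = (10^(−1/slope) − 1) × 100, so a perfect doubling per cycle gives
slope −1/log10(2) ≈ −3.3219 and E = 100%.

Missing Cp cells are never imputed. Gene pairs are compared over their
shared observations (pairwise deletion); a gene missing in more than 20% of
observations is dropped from stability analysis with a warning; NormFinder,
whose per-observation centering needs every gene, drops incomplete
observations instead.

## geNorm: stability value M and the V cut-off

Two ideal reference genes have a constant expression ratio across samples,
so the dispersion of their log-ratio measures their joint instability. For
genes j and k, V(j,k) is the sample standard deviation (n−1 denominator,
log base 2) over observations of log2(Q_j/Q_k), and the stability value of
gene j within a candidate set is the average M_j of V(j,k) over all other
candidates. The least stable gene (highest M) is removed and M recomputed,
stepwise, until two genes remain; those form the best pair, reported
unordered with their shared two-gene M. A gene's reported M is its value at
the iteration of its exclusion. An exact M tie is broken by removing the
tied gene that appears later in input order — deterministic and, with
continuous data, essentially only reachable through duplicated genes.

How many genes does a normalization factor need? NF_n is the per-observation
geometric mean of the Q values of the n top-ranked genes. The pairwise
variation V(n, n+1) — the SD over observations of log2(NF_n/NF_{n+1}) —
measures how much the (n+1)-th gene still changes the factor. The smallest
n with V(n, n+1) < 0.15 is reported as the optimal gene number. The 0.15
cut-off is the conventional guideline, exposed as a parameter because it is
explicitly not a strict threshold; when no V falls below it the package
reports the largest n with `satisfiable = FALSE` and notes that using at
least the three most stable genes remains a valid strategy.

## NormFinder: model-based stability

geNorm's pairwise construction can favour coregulated genes. NormFinder
instead fits a two-way model to y = log2(Q): each observation carries a
sample effect (removed by centering each observation across the I genes), and
each gene i in condition group g carries an intergroup deviation d_ig plus
gene-specific error with variance sigma²_ig. The estimator used here, per
group g of size n_g:

1. center each observation across genes: z_igj = y_igj − mean_i y_igj;
2. per-gene sample variances s²_ig of z, bias-corrected for the centering:
   sigma²_ig = max(0, (s²_ig − (1/I²) Σ_i' s²_i'g / (1 − 1/I)) / (1 − 2/I)),
   which is unbiased for the gene's own error variance (hence the
   requirement I ≥ 3, so that 1 − 2/I > 0);
3. d̂_ig = mean_j z_igj, centered per gene across groups;
4. intergroup variance
   γ̂² = max(0, Σ d̂²_ig/((I−1)(G−1)) − (1/(IG)) Σ sigma²_ig/n_g);
5. empirical-Bayes shrinkage d̃_ig = d̂_ig · γ̂²/(γ̂² + sigma²_ig/n_g);
6. stability ρ_i = (1/G) Σ_g [ |d̃_ig| + sqrt(γ̂² (sigma²_ig/n_g) / (γ̂² +
   sigma²_ig/n_g)) ].

Lower ρ means more stable. With a single group, ρ_i = sqrt(sigma²_i1).
Negative variance estimates are truncated at zero, the conventional fix;
when γ̂² = 0 both the shrunken deviations and the prediction-error term are
identically zero, so the limit needs no special division handling. Log base
2 is used throughout for consistency with Q and ddCp; stability values scale
linearly with the log base, so rankings are base-invariant.

Because the stability value is validated against simulations with known
truth rather than against published tables (no raw Cp data accompany
published surveys of this kind), the test suite checks parameter recovery:
with one group and known per-gene log2 SDs between 0.1 and 0.8, the mean
estimated ρ over repeated simulations tracks the true SD within 15% and the
ranking is recovered in ≥95% of runs; a gene given a 1-log2 group shift is
flagged least stable essentially always.

One practical caveat: the grouping variable matters. In a subset with no
real condition structure (e.g. an organ/tissue panel where "control" vs
"normal growth" is a bookkeeping distinction), the intergroup terms reflect
sampling noise, and a nearly noise-free gene can be ranked surprisingly low
because its tiny error variance earns it almost no shrinkage. The grouping
column is therefore explicit (`group_col`), and single-group analysis is
fully supported.

## 2^-ddCp quantification

For each biological replicate, dCp = Cp_target − mean(Cp of the reference
genes); using the arithmetic mean of reference Cp values is algebraically
identical to dividing by the geometric-mean normalization factor, up to a
per-gene constant that cancels in the next step. ddCp subtracts the *mean*
dCp of the calibrator condition (not a single designated replicate — the
textbook ddCp convention leaves this open, and the mean is reproducible and
symmetric), and the fold change is 2^-ddCp. Fold changes are summarized as
arithmetic mean ± SD (n−1) over biological replicates on the linear fold
scale, matching the usual mean ± SD error bars; a single replicate reports
SD 0 with a warning. Efficiency correction is deliberately not applied here,
for parity with the plain ddCp convention.

Two invariances are worth knowing: fold changes are unchanged by any
permutation of the reference set, and by adding a constant to every Cp of
one biological replicate (a loading effect), because both cancel inside dCp.

## The synthetic generator

The generator emulates a 15-candidate-gene survey over 20 samples in three
subsets — 10 organs/tissues under normal growth, 8 abiotic-stress samples
(control/drought/salt/cold × root/leaf) and 6 biotic-stress samples
(control plus two infections × root/leaf) — with 3 biological × 2 technical
replicates. The subsets overlap: the normal root and leaf samples double as
the controls of both stress subsets (10 + 8 + 6 memberships over 20
samples), so the metadata `subset` field holds a semicolon-separated
membership list and `samples_in_subset()` matches membership.

The generative model is

> Cp(g, s, b, t) = base_g + effect(g, group(s)) + loading(s, b)
>   + bioNoise(g, s, b) + techNoise,

with all noise Gaussian on the Cp scale (log-normal expression noise, the
standard qPCR error model). Defaults, chosen once to mirror a realistic
survey: baseline Cp from 8.4 (an 18S-rRNA-like gene) to 24.8, most genes
between 18 and 24; loading SD 0.5 cycles; technical SD 0.15 cycles
(implying a technical duplicate spread above 0.5 cycles in roughly 2% of
cells, which is why the collapse step's QC warning fires occasionally on
healthy simulated data); two designated stable genes (YLS8, PTB) with
biological SD 0.15 and no condition effects; all other genes with SD
0.6–1.3 and/or condition shifts of 1–1.5 cycles (the rRNA- and GAPDH-like
genes get explicit stress responses). Together with the loading shifts this
gives most genes a five-to-six-cycle range across samples. Loading shifts
are drawn per (sample, biological replicate) — each RNA extraction/cDNA
synthesis is one loading unit — and are common to all genes of that
observation, which is precisely the variation that reference-gene
normalization is meant to remove; the stability statistics' invariance to
per-observation scaling therefore holds on simulated data by construction.

What the generator does *not* emulate: inter-gene biological correlation
(genes are conditionally independent given the loading shift, so geNorm's
known blind spot for coregulated pairs is not exercised), missing-data
mechanisms, inhibition or efficiency drift across samples, and
fluorescence-level artefacts. Passing the recovery tests therefore shows
that the statistics do what they claim under their own model assumptions —
not that any particular real dataset satisfies those assumptions.

The dilution-series generator draws Cp = intercept − log10(amount) /
log10(1 + E/100) + noise for the fivefold series 500…0.8 ng, and the
time-course generator shifts target Cp by −log2(fold) along a configurable
profile (default: three targets, up-regulation peaking at 24 h — fold 4 for
the first target — then declining), over 5 timepoints × 3 biological
replicates with reference genes stable up to noise (target log2 SD 0.2).

## Numerical and design choices

* Sample SD (n−1) everywhere a dispersion is reported, matching the
  reference implementations' convention.
* Replicate observations: the unit of analysis is the (sample, biological
  replicate) pair after technical collapse; biological replicates are kept
  as observations rather than pooled, and subset analyses filter
  observations by metadata before any computation.
* Technical-replicate spread warnings at 0.5 cycles and the plausible Cp
  range [5, 40] are QC conventions (a 40-cycle protocol), configurable and
  warning-level only.
* Degenerate inputs are rejected early with named errors: fewer than 3
  distinct dilution amounts, fewer than 3 genes for NormFinder or stepwise
  geNorm, gene pairs sharing fewer than 2 observations, groups smaller
  than 2, a missing calibrator condition.
* Reproducibility: a single integer seed drives each simulation; identical
  seeds give byte-identical datasets.

Problem sizes in the test suite (100 random tables for the oracle
comparisons, 100 simulated surveys for stable-pair recovery, 100 runs for
NormFinder recovery at n = 200, 500 time courses for ddCp coverage) were
chosen so that the binomial/Monte-Carlo margins of the asserted thresholds
are comfortable at desk scale.

## A worked run

```{r, eval = FALSE}
sim <- simulate_cp_dataset(seed = 42)
res <- run_stability(sim$dataset, sim$metadata, out_dir = "results/all")
res$genorm          # best pair, exclusion order, V series, optimal n
rank_report(res$normfinder)

tc <- simulate_target_timecourse(seed = 7)
run_quantify(tc$dataset, tc$metadata,
             ref_genes = c("EF1a", "ACT", "UBCP"), calibrator = "t0")
```

The `analysis/` directory of the source repository chains these steps into
the full survey narrative (simulate → standard curves → all-sample
stability → subset stability → normalization-strategy comparison), writing
its tables under `results/`.

## Known limitations

* geNorm's M rewards coregulation; the simulator's independence assumption
  means this failure mode is documented, not tested.
* NormFinder's ranking depends on the grouping variable; with
  near-degenerate groupings the intergroup terms are noise-driven (see
  above).
* No efficiency-corrected ddCp (Pfaffl-type ratio models) and no
  differential-expression testing; the quantification stops at mean ± SD
  fold changes.
* No instrument-native file parsers; input is plain CSV/TSV.
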