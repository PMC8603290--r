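#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' list. A single `seed` pins all four generators (depth profile, variant
#' calls, expression matrix, cohort); each generator derives its own child
#' seed internally so they can be re-run independently and still reproduce.
#'
#' The depth model is negative binomial: overdispersion is universal in
#' hybrid-capture sequencing, and the `nb_dispersion` size parameter controls
#' it (variance = mean + mean^2/size). GC bias enters multiplicatively
#' through a smooth function of the 100 bp flanking GC fraction (see
#' [simulate_depth_profile()]). Purity defaults to 1 because the simulated
#' tumors emulate established cell lines, which are clonal.
#'
#' @param seed Integer seed pinning all generators.
#' @param mean_depth Mean sequencing depth at an unbiased diploid site
#'   (reads; default 100).
#' @param nb_dispersion Negative-binomial size parameter (default 10; larger
#'   means closer to Poisson).
#' @param gc_bias_amplitude Amplitude of the multiplicative GC bias, in
#'   `[0, 1)` (default 0.3; 0 disables the bias).
#' @param purity Tumor cell fraction in `(0, 1]` (default 1).
#' @param n_snps Number of SNP sites to simulate across the genome.
#' @param segments Copy-number truth segments as returned by
#'   [cn_segments()]; default [default_segments()].
#' @param min_copy_eps Residual copy fraction assigned to homozygously
#'   deleted segments (default 0.1 copies), representing the mismapped and
#'   contaminating reads that keep real deletions from having literally zero
#'   depth. Enters the truth as `expected_lrr = log2(max(c, min_copy_eps)/2)`.
#' @param het_fraction,ambiguous_fraction Fractions of simulated SNP sites
#'   that are heterozygous (normal VAF near 0.5) or of ambiguous zygosity
#'   (VAF in the excluded bands); the remainder is homozygous.
#' @param n_true_somatic Number of true somatic variants to simulate.
#' @param n_artifacts_per_rule Number of artifact variants violating exactly
#'   one discard rule, per rule.
#' @param artifact_rules Which discard rules get artifacts; defaults to the
#'   five read-evidence rules. `"insufficient_caller_support"` may be added.
#' @param nonsyn_fraction Fraction of true somatics annotated non-synonymous.
#' @param n_genes,n_samples_per_group,n_shifted_genes,shift_log2fc Expression
#'   generator: matrix size, group sizes (two groups), number of genes with a
#'   between-group shift, and the shift in log2 units.
#' @param cohort_n Number of patients in the simulated cohort (default 144).
#' @param cd8_cutoff CD8 count defining the high/low strata in the hazard
#'   model (default 82.8 cells per 0.25 mm^2 field).
#' @param hazard_ratios Named positive reals, one per CD8xCD155 stratum,
#'   multiplying the baseline progression hazard. Defaults encode the
#'   inflamed/CD155-low group as the good-prognosis stratum.
#' @param median_pfs_months Baseline median progression-free survival used to
#'   set the baseline exponential hazard (default 6 months).
#' @param censoring_rate Probability that a patient is censored before the
#'   event, in `[0, 1)` (default 0.3; 0 means every event is observed).
#' @param cd155_post_shift Mean ordinal shift applied to the resistance-state
#'   CD155 score of patients with high CD8 infiltration at resistance.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_snps = 500)
#' cfg$mean_depth
sim_config <- function(seed = 1L,
                       mean_depth = 100,
                       nb_dispersion = 10,
                       gc_bias_amplitude = 0.3,
                       purity = 1,
                       n_snps = 10000L,
                       segments = default_segments(),
                       min_copy_eps = 0.1,
                       het_fraction = 0.4,
                       ambiguous_fraction = 0.06,
                       n_true_somatic = 50L,
                       n_artifacts_per_rule = 5L,
                       artifact_rules = c("low_total_reads", "low_vaf",
                                          "germline_support", "single_strand",
                                          "population_db"),
                       nonsyn_fraction = 0.6,
                       n_genes = 2000L,
                       n_samples_per_group = 4L,
                       n_shifted_genes = 200L,
                       shift_log2fc = 2,
                       cohort_n = 144L,
                       cd8_cutoff = 82.8,
                       hazard_ratios = c("CD8lo/CD155lo" = 1,
                                         "CD8lo/CD155hi" = 1.2,
                                         "CD8hi/CD155lo" = 0.35,
                                         "CD8hi/CD155hi" = 1.2),
                       median_pfs_months = 6,
                       censoring_rate = 0.3,
                       cd155_post_shift = 1) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    mean_depth > 0, nb_dispersion > 0,
    gc_bias_amplitude >= 0, gc_bias_amplitude < 1,
    purity > 0, purity <= 1,
    n_snps >= 1,
    min_copy_eps > 0, min_copy_eps < 1,
    het_fraction >= 0, ambiguous_fraction >= 0,
    het_fraction + ambiguous_fraction <= 1,
    n_true_somatic >= 0, n_artifacts_per_rule >= 0,
    nonsyn_fraction >= 0, nonsyn_fraction <= 1,
    n_genes >= 2, n_samples_per_group >= 2,
    n_shifted_genes >= 0, n_shifted_genes <= n_genes,
    cohort_n >= 4,
    all(hazard_ratios > 0), length(hazard_ratios) == 4,
    median_pfs_months > 0,
    censoring_rate >= 0, censoring_rate < 1
  )
  artifact_rules <- match.arg(
    artifact_rules,
    c("low_total_reads", "low_vaf", "germline_support", "single_strand",
      "population_db", "insufficient_caller_support"),
    several.ok = TRUE
  )
  segments <- validate_segments(segments)
  structure(
    list(
      seed = as.integer(seed), mean_depth = mean_depth,
      nb_dispersion = nb_dispersion, gc_bias_amplitude = gc_bias_amplitude,
      purity = purity, n_snps = as.integer(n_snps), segments = segments,
      min_copy_eps = min_copy_eps, het_fraction = het_fraction,
      ambiguous_fraction = ambiguous_fraction,
      n_true_somatic = as.integer(n_true_somatic),
      n_artifacts_per_rule = as.integer(n_artifacts_per_rule),
      artifact_rules = artifact_rules, nonsyn_fraction = nonsyn_fraction,
      n_genes = as.integer(n_genes),
      n_samples_per_group = as.integer(n_samples_per_group),
      n_shifted_genes = as.integer(n_shifted_genes),
      shift_log2fc = shift_log2fc, cohort_n = as.integer(cohort_n),
      cd8_cutoff = cd8_cutoff, hazard_ratios = hazard_ratios,
      median_pfs_months = median_pfs_months, censoring_rate = censoring_rate,
      cd155_post_shift = cd155_post_shift
    ),
    class = "sim_config"
  )
}

#' Copy-number truth segments
#'
#' Builds the ground-truth segment table consumed by
#' [simulate_depth_profile()]. Positions are 1-based inclusive. The expected
#' LRR at purity 1 is `log2(max(copy_number, min_copy_eps) / 2)`, so a
#' diploid segment has expected LRR 0 and a single-copy loss -1.
#'
#' @param chrom Chromosome identifiers.
#' @param start,end Segment bounds in base pairs (1-based, inclusive).
#' @param copy_number Non-negative integer copy number per segment.
#' @param min_copy_eps Residual copy fraction for `copy_number = 0` (see
#'   [sim_config()]).
#' @return A tibble with one row per segment and an `expected_lrr` column.
#' @export
#' @examples
#' cn_segments("chr1", 1, 2e6, 1)$expected_lrr # -1
cn_segments <- function(chrom, start, end, copy_number, min_copy_eps = 0.1) {
  seg <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    copy_number = as.integer(copy_number),
    expected_lrr = log2(pmax(copy_number, min_copy_eps) / 2)
  )
  validate_segments(seg)
}

validate_segments <- function(segments) {
  req <- c("chrom", "start", "end", "copy_number")
  if (!all(req %in% names(segments))) {
    abort(paste("segments must have columns:", paste(req, collapse = ", ")))
  }
  if (any(segments$start > segments$end)) {
    abort("segment start must be <= end")
  }
  if (any(segments$copy_number < 0)) {
    abort("copy_number must be non-negative")
  }
  overlaps <- segments |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(bad = .data$start <= dplyr::lag(.data$end, default = -Inf)) |>
    dplyr::ungroup()
  if (any(overlaps$bad)) {
    abort("segments within a chromosome must not overlap")
  }
  tibble::as_tibble(segments)
}

#' Default copy-number landscape for simulations
#'
#' Three synthetic chromosomes carrying, against a mostly diploid background,
#' one segment each of copy number 1, 3, 4 and 0, all tens of megabases long
#' so that 1 Mb smoothing windows sit well inside segments. Roughly 60% of
#' the genome is diploid, which keeps genome-wide median centering anchored
#' at copy number 2.
#'
#' @param min_copy_eps Residual copy fraction for the homozygous deletion.
#' @return A segment tibble (see [cn_segments()]).
#' @export
default_segments <- function(min_copy_eps = 0.1) {
  cn_segments(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3", "chr3"),
    start = c(1, 30e6 + 1, 1, 25e6 + 1, 1, 20e6 + 1, 32e6 + 1),
    end   = c(30e6, 50e6,  25e6, 45e6,  20e6, 32e6,  50e6),
    copy_number = c(2L, 1L, 2L, 3L, 2L, 0L, 4L),
    min_copy_eps = min_copy_eps
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed,
      "| depth", x$mean_depth,
      "| dispersion", x$nb_dispersion,
      "| gc amplitude", x$gc_bias_amplitude,
      "| purity", x$purity, "\n")
  cat("  snps:", x$n_snps, "over", nrow(x$segments), "segments;",
      "somatics:", x$n_true_somatic,
      "(+", x$n_artifacts_per_rule, "artifacts x",
      length(x$artifact_rules), "rules)\n")
  cat("  expression:", x$n_genes, "genes x 2 x", x$n_samples_per_group,
      "samples; cohort n =", x$cohort_n, "\n")
  invisible(x)
}
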