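#' Simulate a paired tumor/normal SNP depth profile
#'
#' Generates the input of the copy-number pipeline: per-SNP normal and tumor
#' read depths with a shared multiplicative GC bias, plus normal-sample
#' allele counts that define zygosity. Depths are negative binomial,
#'
#' \deqn{n_i \sim NB(\mu = D g(gc_i)), \quad
#'       t_i \sim NB(\mu = D g(gc_i) (p\,c_i^*/2 + (1 - p)))}
#'
#' where `D` is `mean_depth`, `p` the purity, `c_i*` the segment copy number
#' (with homozygous deletions floored at `min_copy_eps` copies to mimic
#' residual mismapped reads), and the smooth unimodal bias
#' `g(gc) = 1 + gc_bias_amplitude * sin(2 * pi * gc)`. GC fractions are drawn
#' from Beta(20, 20), so almost all sites fall in (0.25, 0.75) where `g` is
#' strictly decreasing in GC — a monotone confound the downstream adjustment
#' must remove.
#'
#' Sites are allocated to segments proportionally to segment length and
#' sorted by position. Normal VAFs are drawn so a configurable fraction of
#' sites is heterozygous (Beta tightly around 0.5), a small fraction has
#' ambiguous VAF (uniform over the excluded bands), and the rest is
#' homozygous (near 0 or 1).
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `sites`: tibble of SNP sites (`chrom`, `pos`, `ref`, `alt`,
#'     `n_depth`, `n_alt`, `n_vaf`, `t_depth`, `t_alt`, `gc100`, `in_db`,
#'     plus truth columns `cn_truth`, `segment_id`, `zygosity_truth`);
#'   * `segments`: the truth segment tibble, unchanged;
#'   * `db_positions`: tibble (`chrom`, `pos`) of sites catalogued in the
#'     simulated population SNP database (a stand-in for 1000 Genomes
#'     positions; 90% of sites are catalogued).
#' @export
#' @examples
#' sim <- simulate_depth_profile(sim_config(seed = 7, n_snps = 200))
#' head(sim$sites)
simulate_depth_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seg <- validate_segments(config$segments)
  set.seed(child_seed(config$seed, "depth"))

  # allocate sites to segments proportional to length, at least 1 per segment
  len <- seg$end - seg$start + 1
  n_per <- pmax(1L, as.integer(round(config$n_snps * len / sum(len))))
  # trim/pad to hit n_snps exactly (largest segments absorb the remainder)
  delta <- config$n_snps - sum(n_per)
  ord <- order(len, decreasing = TRUE)
  i <- 1L
  while (delta != 0L) {
    j <- ord[(i - 1L) %% nrow(seg) + 1L]
    step <- sign(delta)
    if (n_per[j] + step >= 1L) {
      n_per[j] <- n_per[j] + step
      delta <- delta - step
    }
    i <- i + 1L
  }

  sites <- purrr::map_dfr(seq_len(nrow(seg)), function(k) {
    pos <- sort(sample(seq(seg$start[k], seg$end[k]), n_per[k],
                       replace = FALSE))
    tibble::tibble(
      chrom = seg$chrom[k], pos = pos,
      cn_truth = seg$copy_number[k], segment_id = k
    )
  }) |>
    dplyr::arrange(.data$chrom, .data$pos)

  n <- nrow(sites)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))

  gc <- rbeta(n, 20, 20)
  g <- 1 + config$gc_bias_amplitude * sin(2 * pi * gc)
  c_eff <- pmax(sites$cn_truth, config$min_copy_eps)
  mu_n <- config$mean_depth * g
  mu_t <- config$mean_depth * g *
    (config$purity * c_eff / 2 + (1 - config$purity))

  n_depth <- rnbinom(n, size = config$nb_dispersion, mu = mu_n)
  t_depth <- rnbinom(n, size = config$nb_dispersion, mu = mu_t)

  zyg <- sample(
    c("het", "ambiguous", "hom"), n, replace = TRUE,
    prob = c(config$het_fraction, config$ambiguous_fraction,
             1 - config$het_fraction - config$ambiguous_fraction)
  )
  vaf_true <- numeric(n)
  vaf_true[zyg == "het"] <- rbeta(sum(zyg == "het"), 300, 300)
  n_amb <- sum(zyg == "ambiguous")
  lo <- runif(n_amb, 0.08, 0.37)
  hi <- runif(n_amb, 0.63, 0.92)
  vaf_true[zyg == "ambiguous"] <- ifelse(runif(n_amb) < 0.5, lo, hi)
  n_hom <- sum(zyg == "hom")
  hom_alt <- runif(n_hom) < 0.5
  vaf_true[zyg == "hom"] <- ifelse(hom_alt,
                                   rbeta(n_hom, 400, 4),
                                   rbeta(n_hom, 4, 400))
  n_alt <- rbinom(n, n_depth, vaf_true)
  n_vaf <- ifelse(n_depth > 0, n_alt / n_depth, NA_real_)

  in_db <- runif(n) < 0.9

  sites <- sites |>
    dplyr::mutate(
      ref = ref, alt = alt,
      n_depth = n_depth, n_alt = n_alt, n_vaf = n_vaf,
      t_depth = t_depth, gc100 = gc, in_db = in_db,
      zygosity_truth = zyg
    ) |>
    dplyr::relocate("chrom", "pos", "ref", "alt", "n_depth", "n_alt",
                    "n_vaf", "t_depth", "gc100", "in_db")

  list(
    sites = sites,
    segments = seg,
    db_positions = sites |>
      dplyr::filter(.data$in_db) |>
      dplyr::select("chrom", "pos")
  )
}
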