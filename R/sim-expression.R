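#' Simulate a gene-by-sample count matrix with group structure
#'
#' Draws negative-binomial counts with lognormal per-gene baseline means and
#' shifts a configurable subset of genes between two sample groups, so that
#' PCA on variable genes separates the groups on PC1 and a signature score
#' over the shifted genes ranks group B above group A.
#'
#' @param config A [sim_config()]; uses `n_genes`, `n_samples_per_group`,
#'   `n_shifted_genes`, `shift_log2fc` and `nb_dispersion`.
#' @return A list with
#'   * `counts`: tibble with a `gene` column and one numeric column per
#'     sample (`A1..An`, `B1..Bn`);
#'   * `groups`: tibble (`sample`, `group`);
#'   * `shifted_genes`: character vector of the genes carrying the shift
#'     (up in group B).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 2, n_genes = 100))
#' dim(sim$counts)
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "expression"))
  ng <- config$n_genes
  ns <- config$n_samples_per_group
  genes <- sprintf("gene%05d", seq_len(ng))
  samples <- c(paste0("A", seq_len(ns)), paste0("B", seq_len(ns)))
  group <- rep(c("A", "B"), each = ns)

  base_mu <- rlnorm(ng, meanlog = log(100), sdlog = 1)
  shifted <- if (config$n_shifted_genes > 0) {
    sample(genes, config$n_shifted_genes)
  } else {
    character()
  }
  lfc <- ifelse(genes %in% shifted, config$shift_log2fc, 0)

  counts <- vapply(seq_along(samples), function(j) {
    mu <- base_mu * 2^(lfc * (group[j] == "B"))
    rnbinom(ng, size = config$nb_dispersion, mu = mu)
  }, numeric(ng))
  colnames(counts) <- samples

  list(
    counts = dplyr::bind_cols(tibble::tibble(gene = genes),
                              tibble::as_tibble(counts)),
    groups = tibble::tibble(sample = samples, group = group),
    shifted_genes = shifted
  )
}
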