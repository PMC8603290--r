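# Expression tables are tibbles with a `gene` identifier column and one
# numeric column per sample; helpers below convert to/from a matrix.

expr_matrix <- function(x) {
  stopifnot("gene" %in% names(x))
  if (anyDuplicated(x$gene)) abort("gene identifiers must be unique")
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort("sample columns must be numeric")
  rownames(m) <- x$gene
  m
}

expr_tibble <- function(m, tag = NULL) {
  out <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                          tibble::as_tibble(m))
  if (!is.null(tag)) attr(out, "transform_tag") <- tag
  out
}

#' Variance-stabilizing-style transform of raw counts
#'
#' A light surrogate for a dispersion-modelled variance-stabilizing
#' transform: per-sample size factors are the median-of-ratios estimate
#' (median over genes of count / geometric-mean-across-samples, computed on
#' genes with no zero count), and the transformed value is
#' `log2(count / size_factor + 1)`. This normalizes sequencing throughput
#' and compresses the count-variance relationship enough for SD-based gene
#' ranking and PCA; it does not reproduce any particular dispersion-fitted
#' transform, and is tagged `vst_like` to say so. Monotone in counts within
#' each sample; a zero count maps to exactly 0.
#'
#' @param counts Count tibble (`gene` column + one numeric column per
#'   sample), at least 2 samples, all counts non-negative.
#' @return The transformed tibble, with attributes `transform_tag =
#'   "vst_like"` and `size_factors` (named per sample).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 50))
#' vst <- vst_like_transform(sim$counts)
#' attr(vst, "size_factors")
vst_like_transform <- function(counts) {
  m <- expr_matrix(counts)
  if (ncol(m) < 2) abort("need at least 2 samples")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(colSums(m) == 0)) abort("a sample has all-zero counts")
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) abort("no gene is nonzero in every sample")
  log_geo <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2,
              function(col) exp(median(log(col) - log_geo)))
  transformed <- log2(sweep(m, 2, sf, "/") + 1)
  out <- expr_tibble(transformed, tag = "vst_like")
  attr(out, "size_factors") <- sf
  out
}

#' Top variable genes by across-sample standard deviation
#'
#' Ranks genes by their SD across samples on the transformed scale and
#' keeps the top `k` (default 10,000), with a deterministic tie-break by
#' gene identifier. If `k` is at least the number of genes, all genes are
#' kept with a warning.
#'
#' @param x Transformed expression tibble.
#' @param k Number of genes to keep (default 10000).
#' @return The subset tibble, in rank order.
#' @export
select_variable_genes <- function(x, k = 10000L) {
  m <- expr_matrix(x)
  stopifnot(k >= 1)
  if (k >= nrow(m)) {
    if (k > nrow(m)) {
      warn(sprintf("k = %d exceeds the %d genes present; keeping all",
                   k, nrow(m)))
    }
    k <- nrow(m)
  }
  gene_sd <- apply(m, 1, sd)
  ord <- order(-gene_sd, rownames(m))
  keep <- rownames(m)[ord[seq_len(k)]]
  out <- x[match(keep, x$gene), , drop = FALSE]
  attr(out, "transform_tag") <- attr(x, "transform_tag")
  out
}

#' Principal component analysis of samples
#'
#' Centers each gene across samples (no unit-variance scaling — the SD
#' ranking upstream already selects for variance) and projects the samples
#' onto the principal axes.
#'
#' @param x Expression tibble (typically the [select_variable_genes()]
#'   output).
#' @param n_components Number of components to report; clipped to
#'   `min(n_samples, n_genes)` with a warning if larger. Default: all.
#' @return An object of class `expr_pca` with elements `scores` (tibble:
#'   `sample`, `PC1`, ...), `explained_variance_fraction`, `sdev`,
#'   `n_genes_used`. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 300))
#' pca <- sim$counts |> vst_like_transform() |> run_pca(n_components = 2)
#' glance(pca)
run_pca <- function(x, n_components = NULL) {
  m <- expr_matrix(x)
  if (ncol(m) < 2) abort("need at least 2 samples")
  max_comp <- min(ncol(m), nrow(m))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    warn(sprintf("n_components clipped from %d to %d",
                 n_components, max_comp))
    n_components <- max_comp
  }
  # samples are observations: transpose so prcomp centers each gene
  fit <- prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  var_all <- fit$sdev^2
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  structure(
    list(
      scores = dplyr::bind_cols(tibble::tibble(sample = colnames(m)),
                                scores),
      explained_variance_fraction = (var_all / sum(var_all))[seq_len(k)],
      sdev = fit$sdev[seq_len(k)],
      total_variance = sum(var_all),
      n_genes_used = nrow(m),
      n_components = k
    ),
    class = "expr_pca"
  )
}

#' @export
print.expr_pca <- function(x, ...) {
  cat("<expr_pca>", nrow(x$scores), "samples,", x$n_genes_used,
      "genes,", x$n_components, "components\n")
  cat("  explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
             collapse = ", "), "\n")
  invisible(x)
}

#' Gene-set signature score
#'
#' For each sample, the mean over the gene set of the genewise z-score
#' (each gene standardized across samples). Genes absent from the matrix
#' are dropped; zero-variance genes contribute 0. A simple summary of
#' coordinate up/down-regulation of a set — not an enrichment test.
#'
#' @param x Transformed expression tibble.
#' @param gene_set Character vector of gene identifiers.
#' @return Tibble with `sample`, `score`, `n_genes_matched`. Errors if no
#'   set gene is present.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 1, n_genes = 200))
#' vst <- vst_like_transform(sim$counts)
#' signature_score(vst, sim$shifted_genes)
signature_score <- function(x, gene_set) {
  m <- expr_matrix(x)
  hit <- intersect(gene_set, rownames(m))
  if (length(hit) == 0) abort("no gene of the set is present in the matrix")
  sub <- m[hit, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  tibble::tibble(
    sample = colnames(m),
    score = colMeans(z),
    n_genes_matched = length(hit)
  )
}
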