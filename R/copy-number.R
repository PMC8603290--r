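#' Select informative SNP sites for copy-number calling
#'
#' Keeps catalogued population SNP positions whose normal-sample VAF marks
#' them as homozygous (VAF <= 0.05 or >= 0.95, boundaries inclusive) or
#' heterozygous (VAF in \[0.4, 0.6\]); sites with VAF in the ambiguous bands
#' (0.05, 0.4) or (0.6, 0.95) are excluded, as are sites absent from the
#' database. Zygosity is annotated on the retained sites.
#'
#' @param sites SNP site tibble with `chrom`, `pos` and `n_vaf` columns.
#' @param db_positions Tibble (`chrom`, `pos`) of catalogued SNP positions
#'   (a 1000 Genomes-style list or a synthetic stand-in).
#' @return The retained sites with a `zygosity` column (`"hom"` / `"het"`).
#'   Warns if nothing is retained.
#' @export
#' @examples
#' sim <- simulate_depth_profile(sim_config(seed = 1, n_snps = 500))
#' snps <- select_informative_snps(sim$sites, sim$db_positions)
#' table(snps$zygosity)
select_informative_snps <- function(sites, db_positions) {
  stopifnot(all(c("chrom", "pos", "n_vaf") %in% names(sites)),
            all(c("chrom", "pos") %in% names(db_positions)))
  out <- sites |>
    dplyr::semi_join(db_positions, by = c("chrom", "pos")) |>
    dplyr::filter(!is.na(.data$n_vaf)) |>
    dplyr::mutate(zygosity = dplyr::case_when(
      .data$n_vaf <= 0.05 | .data$n_vaf >= 0.95 ~ "hom",
      .data$n_vaf >= 0.4 & .data$n_vaf <= 0.6 ~ "het",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$zygosity))
  if (nrow(out) == 0) {
    warn("no informative SNPs retained")
  }
  out
}

#' GC-content depth adjustment by binned median ratios
#'
#' Removes the dependence of read depth on local GC content, independently
#' for the normal and tumor samples. Sites are binned by their 100 bp
#' flanking GC fraction into bins of width `bin_width`; bins holding fewer
#' than `min_bin_sites` sites are merged with the nearest (by GC) populated
#' neighbor until all bins are large enough. Within each sample the
#' adjusted depth is
#'
#' \deqn{d_{adj} = d \times \mathrm{median}(d) / \mathrm{median}_{bin}(d)}
#'
#' so an unbiased profile (all bin medians equal to the global median) is
#' returned unchanged, and adjusted depth stays strictly positive wherever
#' the raw depth is positive.
#'
#' @param sites Informative-site tibble with `n_depth`, `t_depth`, `gc100`.
#' @param bin_width GC bin width (fraction; default 0.01, i.e. 1% GC).
#' @param min_bin_sites Minimum sites per bin before merging (default 20).
#' @return The input tibble with `n_adj` and `t_adj` columns added.
#' @export
gc_adjust_depths <- function(sites, bin_width = 0.01, min_bin_sites = 20L) {
  stopifnot(all(c("n_depth", "t_depth", "gc100") %in% names(sites)),
            bin_width > 0, bin_width <= 1, min_bin_sites >= 1)
  if (nrow(sites) == 0) abort("no sites to adjust")
  if (all(sites$n_depth == 0) || all(sites$t_depth == 0)) {
    abort("all depths are zero; nothing to adjust")
  }
  bin <- gc_bins(sites$gc100, bin_width, min_bin_sites)
  sites |>
    dplyr::mutate(
      n_adj = adjust_one_sample(.data$n_depth, bin),
      t_adj = adjust_one_sample(.data$t_depth, bin)
    )
}

# Assign GC bins of width bin_width, then merge under-populated bins with
# the nearest populated neighbor (by bin center distance) until all
# remaining bins hold >= min_bin_sites sites.
gc_bins <- function(gc, bin_width, min_bin_sites) {
  stopifnot(all(gc >= 0 & gc <= 1))
  bin <- floor(gc / bin_width)
  bin[gc == 1] <- max(bin[gc == 1] - 1, 0) # right edge closed
  # iterative merge of the smallest under-sized bin
  repeat {
    tab <- table(bin)
    ids <- as.numeric(names(tab))
    if (length(ids) <= 1) break
    small <- ids[tab < min_bin_sites]
    if (length(small) == 0) break
    victim <- small[which.min(tab[as.character(small)])]
    others <- ids[ids != victim]
    target <- others[which.min(abs(others - victim))]
    bin[bin == victim] <- target
    if (victim == target) break
  }
  bin
}

adjust_one_sample <- function(depth, bin) {
  global_med <- median(depth)
  bin_med <- tapply(depth, bin, median)
  factor <- global_med / bin_med[as.character(bin)]
  factor[!is.finite(factor)] <- 1
  as.numeric(depth * factor)
}

#' Per-site log-R ratio
#'
#' Computes the raw LRR, `log2(t_adj / n_adj)`, at each site with positive
#' adjusted depths in both samples; sites where either adjusted depth is
#' zero are dropped (with a message reporting the count) so the track never
#' contains infinities. With `center_median = TRUE` (default) a constant is
#' subtracted so the genome-wide median LRR is 0, absorbing tumor/normal
#' throughput differences — with the documented caveat that genome-wide
#' aneuploidy shifts this baseline.
#'
#' @param sites Tibble with `chrom`, `pos`, `n_adj`, `t_adj` (from
#'   [gc_adjust_depths()]).
#' @param center_median Center the genome-wide median LRR at 0?
#' @return An LRR track: the sites sorted by (`chrom`, `pos`) with an
#'   `lrr_raw` column; the number of dropped zero-depth sites is attached
#'   as attribute `n_dropped`.
#' @export
compute_lrr <- function(sites, center_median = TRUE) {
  stopifnot(all(c("chrom", "pos", "n_adj", "t_adj") %in% names(sites)))
  usable <- sites$n_adj > 0 & sites$t_adj > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    inform(sprintf("dropping %d site(s) with zero adjusted depth", n_dropped))
  }
  track <- sites[usable, , drop = FALSE] |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(lrr_raw = log2(.data$t_adj / .data$n_adj))
  if (center_median && nrow(track) > 0) {
    track$lrr_raw <- track$lrr_raw - median(track$lrr_raw)
  }
  attr(track, "n_dropped") <- n_dropped
  track
}

#' Moving-window median smoothing of an LRR track
#'
#' The representative LRR at site i is the median of the raw LRR over all
#' sites on the same chromosome within a window of `window_bp` base pairs
#' centered at position i (|pos - pos_i| <= window_bp / 2). Windows never
#' cross chromosome boundaries and truncate at chromosome ends; the site
#' itself is always in its window, so the representative value is defined
#' everywhere.
#'
#' @param track LRR track from [compute_lrr()].
#' @param window_bp Window width in base pairs (default 1 Mb).
#' @return The track with an `lrr_rep` column added.
#' @export
smooth_lrr <- function(track, window_bp = 1e6) {
  stopifnot(all(c("chrom", "pos", "lrr_raw") %in% names(track)),
            window_bp > 0)
  track <- dplyr::arrange(track, .data$chrom, .data$pos)
  half <- window_bp / 2
  track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(lrr_rep = {
      p <- .data$pos
      x <- .data$lrr_raw
      lo <- findInterval(p - half, p, left.open = TRUE) + 1L
      hi <- findInterval(p + half, p)
      vapply(seq_along(p), function(i) median(x[lo[i]:hi[i]]), numeric(1))
    }) |>
    dplyr::ungroup()
}

#' Call gene-level copy-number status from a smoothed LRR track
#'
#' Averages the representative LRR over the sites falling inside each gene
#' interval and thresholds the mean: `homozygous_loss` at or below -1,
#' `loss` at or below -0.3, `gain` at or above +0.3, `neutral` in between
#' (conventional defaults; the thresholds are exposed). Intervals covered
#' by fewer than `min_sites` sites get a missing status.
#'
#' @param track Smoothed track from [smooth_lrr()].
#' @param genes Gene interval tibble with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; see [read_bed_intervals()] for BED input).
#' @param thresholds Named list with `homozygous_loss`, `loss`, `gain`.
#' @param min_sites Minimum in-interval sites for a non-missing call.
#' @return A tibble with one row per gene: `gene`, `chrom`, `start`, `end`,
#'   `n_sites`, `mean_rep_lrr`, `status`.
#' @export
#' @examples
#' sim <- simulate_depth_profile(sim_config(seed = 1, n_snps = 2000))
#' track <- sim$sites |>
#'   select_informative_snps(sim$db_positions) |>
#'   gc_adjust_depths() |>
#'   compute_lrr() |>
#'   smooth_lrr()
#' genes <- tibble::tibble(gene = "GENE1", chrom = "chr3",
#'                         start = 24e6, end = 26e6)
#' call_gene_status(track, genes)
call_gene_status <- function(track, genes,
                             thresholds = list(homozygous_loss = -1,
                                               loss = -0.3, gain = 0.3),
                             min_sites = 5L) {
  stopifnot(all(c("chrom", "pos", "lrr_rep") %in% names(track)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)),
            thresholds$homozygous_loss <= thresholds$loss,
            thresholds$loss < thresholds$gain)
  out <- genes |>
    tibble::as_tibble() |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_sites = sum(track$chrom == .data$chrom &
                      track$pos >= .data$start & track$pos <= .data$end),
      mean_rep_lrr = ifelse(
        .data$n_sites > 0,
        mean(track$lrr_rep[track$chrom == .data$chrom &
                             track$pos >= .data$start &
                             track$pos <= .data$end]),
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_sites < min_sites ~ NA_character_,
      .data$mean_rep_lrr <= thresholds$homozygous_loss ~ "homozygous_loss",
      .data$mean_rep_lrr <= thresholds$loss ~ "loss",
      .data$mean_rep_lrr >= thresholds$gain ~ "gain",
      TRUE ~ "neutral"
    ))
  if (any(out$n_sites == 0)) {
    warn(sprintf("%d gene interval(s) overlap no track sites",
                 sum(out$n_sites == 0)))
  }
  out
}
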