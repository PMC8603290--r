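toy_sites <- function(n_vaf, in_db = TRUE) {
  n <- length(n_vaf)
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 1000L, n_vaf = n_vaf,
    n_depth = 100L, t_depth = 100L, gc100 = 0.5
  )
}

test_that("informative-SNP selection applies the VAF bands with inclusive boundaries", {
  sites <- toy_sites(c(0.50, 0.20, 0.95, 0.05, 0.40, 0.60, 0.941, 0.051,
                       0.80, 0.00, 1.00))
  db <- sites[, c("chrom", "pos")]
  out <- select_informative_snps(sites, db)
  expect_equal(out$pos / 1000, c(1, 3, 4, 5, 6, 10, 11))
  expect_equal(
    out$zygosity,
    c("het", "hom", "hom", "het", "het", "hom", "hom")
  )
  # a site absent from the database is dropped even with informative VAF
  out2 <- select_informative_snps(sites, db[-1, ])
  expect_false(1000 %in% out2$pos)
  expect_warning(select_informative_snps(sites, db[0, ]), "no informative")
})

test_that("GC adjustment is the identity on an unbiased profile", {
  set.seed(3)
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:2000 * 500L,
    n_depth = rep(c(80L, 100L, 120L), length.out = 2000),
    t_depth = rep(c(90L, 100L, 110L), length.out = 2000),
    gc100 = runif(2000, 0.3, 0.7)
  )
  # depths independent of gc: all bin medians equal the global median
  adj <- gc_adjust_depths(sites, bin_width = 0.2, min_bin_sites = 5)
  expect_equal(adj$n_adj, as.numeric(sites$n_depth))
  expect_equal(adj$t_adj, as.numeric(sites$t_depth))
})

test_that("GC adjustment matches the stated formula on a two-bin toy", {
  # bin A median 100, bin B median 50 -> global median 75:
  # a depth-50 site in bin B maps to 50 * 75 / 50 = 75
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:8 * 1000L,
    n_depth = c(90L, 100L, 100L, 110L, 40L, 50L, 50L, 60L),
    t_depth = c(90L, 100L, 100L, 110L, 40L, 50L, 50L, 60L),
    gc100 = c(rep(0.35, 4), rep(0.65, 4))
  )
  adj <- gc_adjust_depths(sites, bin_width = 0.1, min_bin_sites = 2)
  expect_equal(adj$n_adj[6], 50 * 75 / 50)
  expect_equal(adj$n_adj[2], 100 * 75 / 100)
  # positive depths stay strictly positive
  expect_true(all(adj$n_adj[sites$n_depth > 0] > 0))
})

test_that("under-populated GC bins merge into their nearest neighbor", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:41 * 1000L,
    n_depth = c(rep(100L, 40), 500L), # lone outlier bin
    t_depth = c(rep(100L, 40), 500L),
    gc100 = c(runif(40, 0.40, 0.45), 0.70)
  )
  adj <- gc_adjust_depths(sites, bin_width = 0.01, min_bin_sites = 20)
  # the lone gc=0.70 site cannot form its own bin (a singleton bin would
  # force its depth to the global median); after merging into the pooled
  # bin (median 100) its factor is 100/100 = 1 and the depth is preserved
  expect_equal(adj$n_adj[41], 500)
})

test_that("raw LRR is the centered log2 depth ratio and never infinite", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:4 * 1000L,
    n_adj = c(100, 100, 100, 100), t_adj = c(100, 200, 100, 0)
  )
  expect_message(track <- compute_lrr(sites, center_median = FALSE),
                 "1 site")
  expect_equal(nrow(track), 3)
  expect_equal(track$lrr_raw, c(0, 1, 0))
  expect_equal(attr(track, "n_dropped"), 1)
  centered <- compute_lrr(sites[1:3, ], center_median = TRUE)
  expect_equal(median(centered$lrr_raw), 0)
  expect_true(all(is.finite(centered$lrr_raw)))
})

test_that("window median matches the naive per-site oracle exactly", {
  set.seed(5)
  n <- 1500
  track <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), c(900, 600)),
    pos = c(sort(sample.int(40e6, 900)), sort(sample.int(25e6, 600))),
    lrr_raw = rnorm(n, 0, 0.5)
  )
  sm <- smooth_lrr(track, window_bp = 1e6)
  for (ch in c("chr1", "chr2")) {
    sub <- sm[sm$chrom == ch, ]
    expect_equal(sub$lrr_rep,
                 oracle_window_median(sub$pos, sub$lrr_raw, 1e6))
  }
})

test_that("window median is robust, truncates at ends, and degenerates to identity", {
  # constant input: median of constants
  const <- tibble::tibble(chrom = "chr1", pos = 1:50 * 10000L,
                          lrr_raw = 0.7)
  expect_equal(smooth_lrr(const)$lrr_rep, rep(0.7, 50))
  # one outlier among in-window neighbors at background 0
  out <- tibble::tibble(chrom = "chr1", pos = c(1, 2, 3, 4, 5) * 1e5,
                        lrr_raw = c(0, 0, 3, 0, 0))
  expect_equal(smooth_lrr(out, window_bp = 1e6)$lrr_rep[3], 0)
  # window smaller than inter-site spacing: each site is its own window
  sparse <- tibble::tibble(chrom = "chr1", pos = c(1, 10, 20) * 1e6,
                           lrr_raw = c(0.1, -0.2, 0.3))
  expect_equal(smooth_lrr(sparse, window_bp = 1000)$lrr_rep,
               sparse$lrr_raw)
  # windows never cross chromosome boundaries
  two <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(100L, 200L),
                        lrr_raw = c(1, -1))
  expect_equal(smooth_lrr(two, window_bp = 1e6)$lrr_rep, c(1, -1))
})

test_that("representative LRR is scale invariant in tumor depth when centered", {
  sim <- simulate_depth_profile(sim_config(seed = 21, n_snps = 2000))
  snps <- select_informative_snps(sim$sites, sim$db_positions)
  t1 <- snps |> gc_adjust_depths() |> compute_lrr() |> smooth_lrr()
  t2 <- snps |>
    dplyr::mutate(t_depth = t_depth * 7L) |>
    gc_adjust_depths() |>
    compute_lrr() |>
    smooth_lrr()
  expect_equal(t2$lrr_rep, t1$lrr_rep, tolerance = 1e-12)
})

test_that("smoothing reduces within-segment variance and recovers segment means", {
  sim <- simulate_depth_profile(sim_config(seed = 22, n_snps = 6000))
  track <- sim$sites |>
    select_informative_snps(sim$db_positions) |>
    gc_adjust_depths() |>
    compute_lrr() |>
    smooth_lrr()
  per_seg <- track |>
    dplyr::group_by(segment_id, cn_truth) |>
    dplyr::summarise(mean_rep = mean(lrr_rep), sd_rep = sd(lrr_rep),
                     sd_raw = sd(lrr_raw), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(n >= 500, cn_truth >= 1)
  expect_true(all(abs(per_seg$mean_rep - log2(per_seg$cn_truth / 2)) < 0.1))
  expect_true(all(per_seg$sd_rep < per_seg$sd_raw))
})

test_that("doubling the GC bias amplitude barely moves post-adjustment segment means", {
  seg_means <- function(amp) {
    sim <- simulate_depth_profile(sim_config(seed = 23, n_snps = 10000,
                                             gc_bias_amplitude = amp))
    sim$sites |>
      select_informative_snps(sim$db_positions) |>
      gc_adjust_depths() |>
      compute_lrr() |>
      smooth_lrr() |>
      dplyr::group_by(segment_id) |>
      dplyr::summarise(m = mean(lrr_rep), .groups = "drop") |>
      dplyr::pull(m)
  }
  expect_true(all(abs(seg_means(0.3) - seg_means(0.6)) < 0.05))
})

test_that("gene status calls follow the thresholds and the min-sites guard", {
  flat <- tibble::tibble(chrom = "chr1", pos = 1:20 * 1000L,
                         lrr_raw = 0, lrr_rep = 0)
  genes <- tibble::tibble(gene = "G", chrom = "chr1",
                          start = 1, end = 25000)
  expect_equal(call_gene_status(flat, genes)$status, "neutral")
  lvls <- list(homozygous_loss = -1.2, loss = -0.5, gain = 0.5)
  for (cs in list(c(-1.2, "homozygous_loss"), c(-0.5, "loss"),
                  c(0.5, "gain"), c(0.4, "neutral"))) {
    tr <- dplyr::mutate(flat, lrr_rep = as.numeric(cs[1]))
    expect_equal(call_gene_status(tr, genes, thresholds = lvls)$status,
                 cs[2])
  }
  # fewer than min_sites overlapping sites: status missing
  few <- call_gene_status(flat[1:3, ], genes, min_sites = 5)
  expect_true(is.na(few$status))
  # no overlap at all: warning and missing status
  off <- tibble::tibble(gene = "H", chrom = "chr9", start = 1, end = 10)
  expect_warning(res <- call_gene_status(flat, off), "no track sites")
  expect_true(is.na(res$status))
})

test_that("BED intervals convert 0-based half-open to 1-based inclusive exactly", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tB2M", "chr2\t0\t100"), bed)
  iv <- read_bed_intervals(bed)
  expect_equal(iv$start, c(1000, 1))
  expect_equal(iv$end, c(2000, 100))
  expect_equal(iv$gene[1], "B2M")
  # round trip through the BED writer
  seg <- cn_segments("chr1", 1000, 2000, 1L)
  out <- tempfile(fileext = ".bed")
  write_segments_bed(seg, out)
  expect_equal(strsplit(readLines(out), "\t")[[1]][2:3], c("999", "2000"))
})
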