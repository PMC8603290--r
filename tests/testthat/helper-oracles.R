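# Independent brute-force oracles used across the suite. Each is written
# directly from the definition it checks and shares no code with the
# package implementation.

# all five read-evidence predicates plus consensus, as one boolean
oracle_keep <- function(v, th = filter_thresholds()) {
  nc <- length(unique(strsplit(v$callers, ",")[[1]]))
  !(v$t_depth < th$min_total_reads |
      (v$t_alt / v$t_depth) < th$min_vaf |
      v$n_alt > th$max_germline_alt |
      (v$t_alt > 0 & ((v$t_alt_fwd == 0) != (v$t_alt_rev == 0))) |
      v$in_population_db | v$in_blacklist_db |
      nc < th$min_callers)
}

# naive O(n^2) per-site window median on one chromosome
oracle_window_median <- function(pos, lrr, window_bp) {
  vapply(seq_along(pos), function(i) {
    median(lrr[abs(pos - pos[i]) <= window_bp / 2])
  }, numeric(1))
}

# two-sided Fisher p by full enumeration of tables with the given margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  pobs <- pr[xs == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# exhaustive Youden scan over every observed threshold
oracle_youden <- function(marker, outcome) {
  best_j <- -Inf
  best_t <- NA_real_
  for (th in sort(unique(marker))) {
    pos <- marker >= th
    j <- sum(pos & outcome) / sum(outcome) +
      sum(!pos & !outcome) / sum(!outcome) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- th
    }
  }
  list(cutoff = best_t, j = best_j)
}

expect_same_tibble <- function(x, y) {
  expect_equal(as.data.frame(x), as.data.frame(y))
}
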