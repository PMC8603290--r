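test_that("ROC cut-off: perfect separation reaches J = 1 between the clusters", {
  d <- tibble::tibble(
    marker = c(1, 2, 3, 4, 10, 11, 12, 13),
    ok = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  rc <- roc_cutoff(d, marker, ok)
  expect_equal(rc$youden_j, 1)
  expect_equal(rc$cutoff, 10) # smallest observed value achieving J = 1
  expect_equal(rc$auc, 1)
  expect_error(roc_cutoff(d, marker, rep(TRUE, 8)), "both classes")
})

test_that("ROC cut-off equals an exhaustive Youden scan on random 20-patient toys", {
  set.seed(31)
  for (rep in 1:20) {
    d <- tibble::tibble(
      marker = round(rnorm(20, 50, 15), 1),
      ok = runif(20) < 0.5
    )
    if (length(unique(d$ok)) < 2) next
    rc <- roc_cutoff(d, marker, ok)
    or <- oracle_youden(d$marker, d$ok)
    expect_equal(rc$youden_j, or$j)
    expect_equal(rc$cutoff, or$cutoff)
  }
})

test_that("ROC cut-off maps through strictly monotone marker transforms", {
  set.seed(32)
  d <- tibble::tibble(marker = rgamma(60, 3, 0.1), ok = runif(60) < 0.4)
  rc <- roc_cutoff(d, marker, ok)
  rc_log <- roc_cutoff(dplyr::mutate(d, marker = log(marker)), marker, ok)
  expect_equal(rc_log$cutoff, log(rc$cutoff))
  expect_equal(rc_log$youden_j, rc$youden_j)
})

test_that("ROC optimism under an uninformative marker stays small at n = 500", {
  set.seed(33)
  js <- replicate(20, {
    d <- tibble::tibble(marker = rnorm(500), ok = runif(500) < 0.5)
    roc_cutoff(d, marker, ok)$youden_j
  })
  expect_gt(mean(js), 0)     # maximizing J is optimistically biased...
  expect_lt(mean(js), 0.15)  # ...but only mildly at this sample size
})

test_that("six-month landmark outcome handles censoring per configuration", {
  d <- tibble::tibble(
    pfs_months = c(10, 3, 2, 6),
    pfs_event = c(FALSE, TRUE, FALSE, TRUE)
  )
  expect_equal(pfs_landmark_outcome(d), c(TRUE, FALSE, NA, TRUE))
  expect_equal(
    pfs_landmark_outcome(d, censored_before = "non_progressor"),
    c(TRUE, FALSE, TRUE, TRUE)
  )
})

test_that("stratification uses >= for CD8 and the 0-1 / 2-3 CD155 split", {
  d <- tibble::tibble(
    cd8_count = c(82.8, 82.79, 200, 10, NA),
    cd155_score = c(1L, 2L, 3L, 0L, 1L),
    id = 1:5
  )
  expect_message(s <- stratify(d, cd8_cutoff = 82.8), "1 patient")
  expect_equal(as.character(s$stratum),
               c("CD8hi/CD155lo", "CD8lo/CD155hi", "CD8hi/CD155hi",
                 "CD8lo/CD155lo"))
  expect_equal(sum(attr(s, "group_sizes")), 4)
  # group sizes always sum to the (non-missing) cohort size
  coh <- simulate_cohort(sim_config(seed = 34))
  s2 <- stratify(coh, cd8_cutoff = 82.8)
  expect_equal(sum(attr(s2, "group_sizes")), nrow(coh))
})

test_that("Fisher p matches brute-force hypergeometric enumeration and its symmetries", {
  set.seed(35)
  for (rep in 1:25) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value
    expect_equal(p, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                    tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    # invariance under transposition and row/column swaps
    expect_equal(fisher_exact_2x2(tab[1, 1], tab[2, 1],
                                  tab[1, 2], tab[2, 2])$p_value, p)
    expect_equal(fisher_exact_2x2(tab[2, 1], tab[2, 2],
                                  tab[1, 1], tab[1, 2])$p_value, p)
    expect_equal(fisher_exact_2x2(tab[1, 2], tab[1, 1],
                                  tab[2, 2], tab[2, 1])$p_value, p)
  }
  # identical rows carry no signal
  expect_equal(fisher_exact_2x2(7, 3, 7, 3)$p_value, 1)
  # odds ratio is the sample ad/bc
  expect_equal(fisher_exact_2x2(5, 2, 1, 4)$odds_ratio, 10)
  # zero margin: p = 1 by convention, with a message
  expect_message(z <- fisher_exact_2x2(0, 0, 5, 5), "margin")
  expect_equal(z$p_value, 1)
})

test_that("Kaplan-Meier matches closed forms and hand-computed censoring toys", {
  # four events at distinct times: steps 0.75, 0.5, 0.25, 0
  d4 <- tibble::tibble(t = 1:4, e = TRUE)
  expect_equal(km_estimate(d4, t, e)$survival, c(0.75, 0.5, 0.25, 0))
  # no events: flat at 1
  d0 <- tibble::tibble(t = 1:4, e = FALSE)
  expect_true(all(km_estimate(d0, t, e)$survival == 1))
  # interleaved censoring, hand-computed product-limit values:
  # t=1 (6 at risk, 1 event) 5/6; t=2 (5 at risk, 1 event, 1 censored)
  # 5/6*4/5 = 2/3; t=3 (3 at risk, 1 event) 4/9; t=5 (1 at risk, 1 event) 0
  dc <- tibble::tibble(t = c(1, 2, 2, 3, 4, 5),
                       e = c(1, 0, 1, 1, 0, 1))
  km <- km_estimate(dc, t, e)
  expect_equal(km$survival[km$time %in% c(1, 2, 3, 5)],
               c(5 / 6, 2 / 3, 4 / 9, 0))
  # without censoring KM equals the empirical survival function
  set.seed(36)
  tt <- rexp(40)
  dn <- tibble::tibble(t = tt, e = TRUE)
  km2 <- km_estimate(dn, t, e)
  expect_equal(km2$survival, vapply(km2$time, function(s) mean(tt > s),
                                    numeric(1)))
})

test_that("log-rank: degenerate and internal-consistency checks", {
  set.seed(37)
  d <- tibble::tibble(t = rexp(40), e = TRUE, g = rep(c("a", "b"), 20))
  # a group compared with itself: duplicate the data under two labels
  dup <- tibble::tibble(t = rep(d$t, 2), e = TRUE,
                        g = rep(c("x", "y"), each = 40))
  lt <- logrank_test(dup, t, e, g)
  expect_equal(lt$chi_square, 0, tolerance = 1e-10)
  expect_equal(lt$p_value, 1)
  # two-group statistic equals the squared standardized O - E sum
  lt2 <- logrank_test(d, t, e, g)
  oe <- tidy(lt2)
  expect_equal(lt2$df, 1)
  expect_equal(sum(oe$observed - oe$expected), 0, tolerance = 1e-10)
  expect_error(logrank_test(d[d$g == "a", ], t, e, g), "two non-empty")
  # pairwise follow-up applies Bonferroni over the pairs
  d3 <- tibble::tibble(t = rexp(60), e = TRUE,
                       g = rep(c("a", "b", "c"), 20))
  pw <- pairwise_logrank(d3, t, e, g)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 3))
})

test_that("log-rank detects a hazard ratio of 3 at n = 200 per group", {
  set.seed(38)
  hits <- replicate(30, {
    d <- tibble::tibble(
      t = c(rexp(200, 1), rexp(200, 3)), e = TRUE,
      g = rep(c("a", "b"), each = 200)
    )
    logrank_test(d, t, e, g)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("paired pre/post test matches the textbook t formula and its edge cases", {
  # identical vectors: no change, p = 1
  same <- tibble::tibble(pre = c(1, 2, 3), post = c(1, 2, 3))
  r0 <- paired_pre_post(same, pre, post)
  expect_equal(r0$mean_change, 0)
  expect_equal(r0$p_value, 1)
  # hand-computed 5-pair example
  d5 <- tibble::tibble(pre = c(1, 2, 3, 4, 5), post = c(2, 2, 4, 4, 7))
  r5 <- paired_pre_post(d5, pre, post)
  dd <- d5$post - d5$pre
  t_hand <- mean(dd) / (sd(dd) / sqrt(5))
  expect_equal(r5$t_statistic, t_hand)
  expect_equal(r5$p_value, 2 * stats::pt(-abs(t_hand), 4))
  expect_equal(r5$mean_change, 0.8)
  # constant nonzero shift: limiting p = 0 with a warning
  shift <- tibble::tibble(pre = c(1, 2, 3), post = c(2, 3, 4))
  expect_warning(rs <- paired_pre_post(shift, pre, post), "zero variance")
  expect_equal(rs$p_value, 0)
  # constant +1 shift with jitter rejects in nearly all replicates at n=25
  set.seed(39)
  ps <- replicate(40, {
    pre <- rnorm(25, 10)
    d <- tibble::tibble(pre = pre, post = pre + 1 + rnorm(25, 0, 0.8))
    paired_pre_post(d, pre, post)$p_value
  })
  expect_gte(mean(ps < 0.05), 0.95)
  # subgroup analysis adds rows per stratifier level
  coh <- simulate_cohort(sim_config(seed = 40, cohort_n = 60))
  sub <- paired_pre_post(coh, cd155_score, cd155_post,
                         by = cd8_post >= 82.8)
  expect_equal(sub$subgroup, c("overall", "FALSE", "TRUE"))
  expect_equal(sub$n[1], 60)
})
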