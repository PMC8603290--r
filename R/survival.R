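#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function under right censoring.
#' Survival starts at 1, steps down at event times, and censored subjects
#' leave the risk set without a step. Fitted via [survival::survfit()];
#' returned as a tidy step-function table.
#'
#' @param data Tibble with one row per subject.
#' @param time,event Columns (tidy-eval): follow-up time (>= 0) and event
#'   indicator (`TRUE`/1 = event, `FALSE`/0 = censored).
#' @param group Optional column for stratified curves.
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   (and `group` when stratified), one row per distinct observed time.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 4, cohort_n = 40))
#' km_estimate(coh, pfs_months, pfs_event)
km_estimate <- function(data, time, event, group = NULL) {
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(as.logical(eval_tidy(enquo(event), data)))
  if (any(t < 0)) abort("times must be non-negative")
  g <- eval_tidy(enquo(group), data)
  if (is.null(g)) {
    fit <- survival::survfit(survival::Surv(t, e) ~ 1)
    tibble::tibble(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, survival = fit$surv
    )
  } else {
    fit <- survival::survfit(survival::Surv(t, e) ~ g)
    grp_lev <- sub("^g=", "", names(fit$strata))
    tibble::tibble(
      group = rep(grp_lev, fit$strata),
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, survival = fit$surv
    )
  }
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times, with `df = n_groups - 1`, via [survival::survdiff()].
#' Errors if any group is empty or no event occurred.
#'
#' @param data Tibble with one row per subject.
#' @param time,event,group Columns (tidy-eval).
#' @return An object of class `logrank_test`: `chi_square`, `df`,
#'   `p_value`, `n`, and a per-group observed/expected table. Supports
#'   `tidy()` and `glance()`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 4))
#' s <- stratify(coh, cd8_cutoff = 82.8)
#' logrank_test(s, pfs_months, pfs_event, stratum)
logrank_test <- function(data, time, event, group) {
  t <- eval_tidy(enquo(time), data)
  e <- as.integer(as.logical(eval_tidy(enquo(event), data)))
  g <- eval_tidy(enquo(group), data)
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2) abort("need at least two non-empty groups")
  if (sum(e) == 0) abort("no events observed")
  fit <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- nlevels(g) - 1
  structure(
    list(
      chi_square = unname(fit$chisq),
      df = df,
      p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
      n = length(t),
      groups = tibble::tibble(
        group = sub("^g=", "", names(fit$n)),
        n = as.integer(fit$n),
        observed = fit$obs, expected = fit$exp
      )
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<logrank_test> chi-square = %.3f, df = %d, p = %.4g, n = %d\n",
              x$chi_square, x$df, x$p_value, x$n))
  print(x$groups)
  invisible(x)
}

#' Pairwise log-rank tests with Bonferroni correction
#'
#' Follow-up to a >2-group [logrank_test()]: every pair of groups is
#' compared and p-values are Bonferroni-adjusted over the number of pairs.
#'
#' @inheritParams logrank_test
#' @return Tibble with `group1`, `group2`, `chi_square`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_logrank <- function(data, time, event, group) {
  t <- eval_tidy(enquo(time), data)
  e <- as.logical(eval_tidy(enquo(event), data))
  g <- droplevels(as.factor(eval_tidy(enquo(group), data)))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    sel <- g %in% pr
    sub <- tibble::tibble(t = t[sel], e = e[sel],
                          g = droplevels(g[sel]))
    lt <- logrank_test(sub, t, e, g)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   chi_square = lt$chi_square, p_value = lt$p_value)
  })
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

#' Paired pre/post comparison by paired t-test
#'
#' Paired t-test on post - pre differences (e.g. CD155 membrane scores at
#' baseline vs at the resistance state), optionally within subgroups
#' defined by a stratifier evaluated per patient (e.g. CD8-high at
#' resistance). When the differences have zero variance but a nonzero mean
#' the t statistic is unbounded; the p-value is then reported as the
#' limiting 0 with a warning. Identical pre and post vectors give a mean
#' change of 0 with p = 1.
#'
#' @param data Tibble with one row per patient.
#' @param pre,post Columns (tidy-eval) of paired marker values.
#' @param by Optional column (tidy-eval) splitting patients into subgroups
#'   analyzed separately (an `overall` row is always included).
#' @return Tibble with `subgroup`, `n`, `mean_change`, `t_statistic`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 6))
#' paired_pre_post(coh, cd155_score, cd155_post,
#'                 by = cd8_post >= 82.8)
paired_pre_post <- function(data, pre, post, by = NULL) {
  x <- eval_tidy(enquo(pre), data)
  y <- eval_tidy(enquo(post), data)
  stopifnot(length(x) == length(y))
  b <- eval_tidy(enquo(by), data)

  one <- function(label, xi, yi) {
    ok <- !is.na(xi) & !is.na(yi)
    xi <- xi[ok]; yi <- yi[ok]
    if (length(xi) < 2) {
      return(tibble::tibble(subgroup = label, n = length(xi),
                            mean_change = mean(yi - xi),
                            t_statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_))
    }
    d <- yi - xi
    if (sd(d) == 0) {
      if (mean(d) == 0) {
        return(tibble::tibble(subgroup = label, n = length(xi),
                              mean_change = 0, t_statistic = 0,
                              df = length(xi) - 1, p_value = 1))
      }
      warn("zero variance of differences with nonzero mean; p -> 0")
      return(tibble::tibble(subgroup = label, n = length(xi),
                            mean_change = mean(d), t_statistic = Inf,
                            df = length(xi) - 1, p_value = 0))
    }
    tt <- t.test(yi, xi, paired = TRUE)
    tibble::tibble(subgroup = label, n = length(xi),
                   mean_change = unname(tt$estimate),
                   t_statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  }

  res <- one("overall", x, y)
  if (!is.null(b)) {
    for (lv in sort(unique(b[!is.na(b)]))) {
      sel <- !is.na(b) & b == lv
      res <- dplyr::bind_rows(res, one(as.character(lv), x[sel], y[sel]))
    }
  }
  res
}
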