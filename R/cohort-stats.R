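#' Progression-free-at-6-months outcome for ROC cut-off selection
#'
#' Dichotomizes progression-free survival at a landmark (default 6 months):
#' `TRUE` for patients progression-free at the landmark, `FALSE` for
#' patients who progressed before it. Patients censored before the landmark
#' without progression are ambiguous; by default they are excluded (`NA`),
#' or counted as progression-free with
#' `censored_before = "non_progressor"`.
#'
#' @param data Cohort tibble.
#' @param time,event Columns (tidy-eval) holding the PFS time in months and
#'   the progression indicator.
#' @param landmark_months Landmark time (default 6).
#' @param censored_before `"exclude"` (default) or `"non_progressor"`.
#' @return Logical vector aligned with the rows of `data`.
#' @export
pfs_landmark_outcome <- function(data, time = pfs_months, event = pfs_event,
                                 landmark_months = 6,
                                 censored_before = c("exclude",
                                                     "non_progressor")) {
  censored_before <- match.arg(censored_before)
  t <- eval_tidy(enquo(time), data)
  e <- as.logical(eval_tidy(enquo(event), data))
  out <- ifelse(t >= landmark_months, TRUE,
                ifelse(e, FALSE, NA))
  if (censored_before == "non_progressor") out[is.na(out)] <- TRUE
  out
}

#' ROC-based cut-off by Youden's J
#'
#' Scans every observed marker value as a candidate cut-off, classifying a
#' patient as test-positive when `marker >= cutoff` (or `<=` with
#' `direction = "<="`), and returns the cut-off maximizing Youden's
#' J = sensitivity + specificity - 1 against the binary outcome. Ties are
#' broken toward the smaller cut-off. Rows with a missing marker or outcome
#' are dropped.
#'
#' @param data Cohort tibble.
#' @param marker,outcome Columns (tidy-eval): a numeric marker and a
#'   logical outcome (`TRUE` = positive class, e.g. progression-free at 6
#'   months).
#' @param direction `">="` (higher marker predicts the positive class,
#'   default) or `"<="`.
#' @return An object of class `roc_cutoff`: `cutoff`, `youden_j`, `auc`
#'   (trapezoidal), `n`, `direction`, and `curve` — a tibble of all ROC
#'   points (`threshold`, `sensitivity`, `specificity`, `youden_j`).
#'   Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 2))
#' coh$pf6 <- pfs_landmark_outcome(coh)
#' roc_cutoff(coh, cd8_count, pf6)
roc_cutoff <- function(data, marker, outcome, direction = c(">=", "<=")) {
  direction <- match.arg(direction)
  m <- eval_tidy(enquo(marker), data)
  y <- as.logical(eval_tidy(enquo(outcome), data))
  ok <- !is.na(m) & !is.na(y)
  m <- m[ok]; y <- y[ok]
  if (length(unique(y)) < 2) {
    abort("outcome must contain both classes")
  }
  thr <- sort(unique(m))
  curve <- purrr::map_dfr(thr, function(th) {
    pos <- if (direction == ">=") m >= th else m <= th
    tibble::tibble(
      threshold = th,
      sensitivity = sum(pos & y) / sum(y),
      specificity = sum(!pos & !y) / sum(!y)
    )
  }) |>
    dplyr::mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  best <- which(curve$youden_j == max(curve$youden_j))[1] # smallest cutoff
  # trapezoidal AUC over the full curve (add the corner points)
  fpr <- c(1, 1 - curve$specificity, 0)
  tpr <- c(1, curve$sensitivity, 0)
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
  structure(
    list(cutoff = curve$threshold[best],
         youden_j = curve$youden_j[best],
         auc = auc, n = length(m), direction = direction, curve = curve),
    class = "roc_cutoff"
  )
}

#' @export
print.roc_cutoff <- function(x, ...) {
  cat(sprintf(
    "<roc_cutoff> cutoff = %g (marker %s cutoff positive), J = %.3f, AUC = %.3f, n = %d\n",
    x$cutoff, x$direction, x$youden_j, x$auc, x$n
  ))
  invisible(x)
}

#' Four-group CD8 x CD155 stratification
#'
#' Assigns each patient to one of `CD8lo/CD155lo`, `CD8lo/CD155hi`,
#' `CD8hi/CD155lo`, `CD8hi/CD155hi`. CD8-high means `cd8_count >= cutoff`
#' (a count equal to the cut-off is high); CD155-high means the ordinal
#' score falls in `cd155_high_levels` (default \{2, 3\}, i.e. 0-1 vs 2-3).
#' Patients with a missing marker are dropped with a message.
#'
#' @param data Cohort tibble with `cd8_count` and `cd155_score` columns.
#' @param cd8_cutoff CD8 count cut-off (e.g. from [roc_cutoff()]).
#' @param cd155_high_levels Scores counted as CD155-high.
#' @return The retained rows with a `stratum` factor added (levels in the
#'   order above); group sizes are attached as attribute `group_sizes`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 2))
#' s <- stratify(coh, cd8_cutoff = 82.8)
#' attr(s, "group_sizes")
stratify <- function(data, cd8_cutoff, cd155_high_levels = c(2L, 3L)) {
  stopifnot(all(c("cd8_count", "cd155_score") %in% names(data)),
            is.numeric(cd8_cutoff), length(cd8_cutoff) == 1)
  miss <- is.na(data$cd8_count) | is.na(data$cd155_score)
  if (any(miss)) {
    inform(sprintf("excluding %d patient(s) with missing markers",
                   sum(miss)))
  }
  lev <- c("CD8lo/CD155lo", "CD8lo/CD155hi", "CD8hi/CD155lo",
           "CD8hi/CD155hi")
  out <- data[!miss, , drop = FALSE] |>
    dplyr::mutate(stratum = factor(paste0(
      ifelse(.data$cd8_count >= cd8_cutoff, "CD8hi", "CD8lo"), "/",
      ifelse(.data$cd155_score %in% cd155_high_levels, "CD155hi", "CD155lo")
    ), levels = lev))
  attr(out, "group_sizes") <- table(out$stratum)
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood convention (sum of
#' hypergeometric probabilities of all tables, with the observed margins,
#' no more probable than the observed one — the usual statistical-package
#' behaviour) and the sample odds ratio `a*d / (b*c)`. A zero margin makes
#' the table uninformative: p is 1 by convention, with a message.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   \[\[a, b\], \[c, d\]\].
#' @return One-row tibble: `odds_ratio`, `p_value`, `n`.
#' @export
#' @examples
#' fisher_exact_2x2(19, 44, 22, 59)
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4, all(counts >= 0),
            all(counts == round(counts)))
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    inform("a table margin is zero; p = 1 by convention")
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  tibble::tibble(
    odds_ratio = (a * d) / (b * c),
    p_value = p,
    n = sum(counts)
  )
}
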