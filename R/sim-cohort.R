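#' Simulate an immunotherapy cohort with stratum-dependent hazards
#'
#' Generates one row per patient: a continuous CD8 count (mean over five
#' 0.25 mm^2 fields), an ordinal CD155 membrane score in 0-3, treatment
#' metadata, progression-free and overall survival under an exponential
#' hazard that depends on the CD8xCD155 stratum, independent censoring, and
#' an optional paired resistance-state CD155 score.
#'
#' The baseline hazard is `log(2) / median_pfs_months`; each stratum's
#' hazard is the baseline times its entry in `hazard_ratios`. Censoring is
#' exponential with the rate chosen so that each patient is censored before
#' the event with probability `censoring_rate` exactly (competing
#' exponentials); `censoring_rate = 0` therefore observes every event.
#' Overall survival adds an independent exponential post-progression time.
#' Resistance-state CD155 scores shift upward by `cd155_post_shift` (plus
#' rounding noise) for patients with a high resistance-state CD8 count, and
#' stay at baseline on average for the rest.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `id`, `cd8_count`, `cd155_score`,
#'   `treatment_line`, `melanoma_type`, `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`, `cd8_post`, `cd155_post`, and the truth
#'   column `stratum_truth`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 5, cohort_n = 50))
#' dplyr::count(coh, stratum_truth)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "cohort"))
  n <- config$cohort_n

  # CD8 counts: right-skewed around the clinical cut-off scale
  cd8 <- rgamma(n, shape = 2.2, scale = 55)
  cd155 <- sample(0:3, n, replace = TRUE, prob = c(0.25, 0.25, 0.3, 0.2))
  stratum <- paste0(
    ifelse(cd8 >= config$cd8_cutoff, "CD8hi", "CD8lo"), "/",
    ifelse(cd155 >= 2, "CD155hi", "CD155lo")
  )
  hr <- config$hazard_ratios[stratum]
  if (anyNA(hr)) {
    abort("hazard_ratios must be named by the four CD8xCD155 strata")
  }

  base_rate <- log(2) / config$median_pfs_months
  rate <- base_rate * unname(hr)
  event_t <- rexp(n, rate)
  if (config$censoring_rate > 0) {
    cens_rate <- rate * config$censoring_rate / (1 - config$censoring_rate)
    cens_t <- rexp(n, cens_rate)
  } else {
    cens_t <- rep(Inf, n)
  }
  pfs <- pmin(event_t, cens_t)
  pfs_event <- event_t <= cens_t

  post_prog <- rexp(n, base_rate / 2)
  os_uncens <- event_t + post_prog
  os <- pmin(os_uncens, cens_t)
  os_event <- os_uncens <= cens_t

  cd8_post <- cd8 * rlnorm(n, 0, 0.3)
  shift <- ifelse(cd8_post >= config$cd8_cutoff, config$cd155_post_shift, 0)
  cd155_post <- pmin(3L, pmax(0L, as.integer(round(
    cd155 + shift + rnorm(n, 0, 0.4)
  ))))

  tibble::tibble(
    id = sprintf("PT%03d", seq_len(n)),
    cd8_count = cd8,
    cd155_score = as.integer(cd155),
    treatment_line = sample(c("first", "second"), n, replace = TRUE,
                            prob = c(0.91, 0.09)),
    melanoma_type = sample(c("cutaneous_or_unknown", "acral_or_mucosal"),
                           n, replace = TRUE, prob = c(63, 81)),
    pfs_months = pfs, pfs_event = pfs_event,
    os_months = os, os_event = os_event,
    cd8_post = cd8_post, cd155_post = cd155_post,
    stratum_truth = stratum
  )
}
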