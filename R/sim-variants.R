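#' Simulate a multi-caller somatic variant call set with known truth
#'
#' Emits a variant table of true somatic mutations plus, for each configured
#' discard rule, artifacts violating exactly that one rule — so a filtering
#' run can be scored against truth variant by variant. True somatics satisfy
#' every keep-condition (tumor depth >= 20, VAF >= 0.05, at most 2 mutant
#' reads in the germline control, alt reads on both strands, absent from the
#' population database and blacklist) and are reported by at least 2 of the
#' 3 simulated callers.
#'
#' @param config A [sim_config()]; uses `n_true_somatic`,
#'   `n_artifacts_per_rule`, `artifact_rules` and `nonsyn_fraction`.
#' @return A tibble of variant calls with evidence columns (`chrom`, `pos`,
#'   `ref`, `alt`, `callers` — comma-separated caller ids — `t_depth`,
#'   `t_alt`, `t_alt_fwd`, `t_alt_rev`, `n_alt`, `in_population_db`,
#'   `in_blacklist_db`, `consequence`) and truth columns `truth_class`
#'   (`"somatic"` or `"artifact"`) and `truth_rule` (the one rule an
#'   artifact violates; `NA` for somatics).
#' @export
#' @examples
#' vc <- simulate_variant_calls(sim_config(seed = 3, n_artifacts_per_rule = 1))
#' table(vc$truth_class)
simulate_variant_calls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "variants"))
  callers <- c("caller_A", "caller_B", "caller_C")

  n_art <- config$n_artifacts_per_rule * length(config$artifact_rules)
  n_tot <- config$n_true_somatic + n_art
  if (n_tot == 0) {
    return(empty_variant_table())
  }

  # a clean template variant that passes every rule
  passing <- function(n) {
    t_depth <- as.integer(round(runif(n, 60, 200)))
    vaf <- runif(n, 0.15, 0.6)
    t_alt <- pmax(2L, as.integer(round(vaf * t_depth)))
    t_alt_fwd <- vapply(t_alt, function(k) {
      f <- rbinom(1, k, 0.5)
      min(max(f, 1L), k - 1L) # both strands covered
    }, integer(1))
    tibble::tibble(
      t_depth = t_depth, t_alt = t_alt,
      t_alt_fwd = as.integer(t_alt_fwd),
      t_alt_rev = t_alt - as.integer(t_alt_fwd),
      n_alt = sample(0:2, n, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
      in_population_db = FALSE, in_blacklist_db = FALSE,
      n_callers = sample(2:3, n, replace = TRUE)
    )
  }

  som <- passing(config$n_true_somatic)
  if (config$n_true_somatic > 0) {
    som$truth_class <- "somatic"
    som$truth_rule <- NA_character_
  }

  art <- purrr::map_dfr(config$artifact_rules, function(rule) {
    k <- config$n_artifacts_per_rule
    if (k == 0) return(NULL)
    x <- passing(k)
    if (rule == "low_total_reads") {
      # depth in [10, 19] with VAF kept >= 0.05 and both strands covered
      x$t_depth <- as.integer(round(runif(k, 10, 19)))
      x$t_alt <- pmax(2L, as.integer(round(runif(k, 0.2, 0.5) * x$t_depth)))
      x$t_alt_fwd <- pmin(pmax(rbinom(k, x$t_alt, 0.5), 1L), x$t_alt - 1L)
      x$t_alt_rev <- x$t_alt - x$t_alt_fwd
    } else if (rule == "low_vaf") {
      x$t_depth <- as.integer(round(runif(k, 150, 300)))
      x$t_alt <- sample(2:4, k, replace = TRUE) # VAF <= 4/150 < 0.05
      x$t_alt_fwd <- pmin(pmax(rbinom(k, x$t_alt, 0.5), 1L), x$t_alt - 1L)
      x$t_alt_rev <- x$t_alt - x$t_alt_fwd
    } else if (rule == "germline_support") {
      x$n_alt <- sample(3:10, k, replace = TRUE)
    } else if (rule == "single_strand") {
      one_fwd <- runif(k) < 0.5
      x$t_alt_fwd <- ifelse(one_fwd, x$t_alt, 0L)
      x$t_alt_rev <- x$t_alt - x$t_alt_fwd
    } else if (rule == "population_db") {
      in_pop <- runif(k) < 0.5
      x$in_population_db <- in_pop
      x$in_blacklist_db <- !in_pop
    } else if (rule == "insufficient_caller_support") {
      x$n_callers <- 1L
    }
    x$truth_class <- "artifact"
    x$truth_rule <- rule
    x
  })

  vc <- dplyr::bind_rows(som, art)
  n <- nrow(vc)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  vc <- vc |>
    dplyr::mutate(
      chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
      pos = sample.int(5e7, n),
      ref = ref,
      alt = vapply(ref, function(b) sample(setdiff(bases, b), 1),
                   character(1)),
      callers = vapply(.data$n_callers, function(m) {
        paste(sort(sample(callers, m)), collapse = ",")
      }, character(1)),
      consequence = sample(
        c("non_synonymous", "synonymous", "other"), n, replace = TRUE,
        prob = c(config$nonsyn_fraction,
                 (1 - config$nonsyn_fraction) * 0.9,
                 (1 - config$nonsyn_fraction) * 0.1)
      )
    ) |>
    dplyr::select(-"n_callers") |>
    dplyr::relocate("chrom", "pos", "ref", "alt", "callers", "t_depth",
                    "t_alt", "t_alt_fwd", "t_alt_rev", "n_alt",
                    "in_population_db", "in_blacklist_db", "consequence") |>
    dplyr::arrange(.data$chrom, .data$pos)
  vc
}

empty_variant_table <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), callers = character(), t_depth = integer(),
    t_alt = integer(), t_alt_fwd = integer(), t_alt_rev = integer(),
    n_alt = integer(), in_population_db = logical(),
    in_blacklist_db = logical(), consequence = character(),
    truth_class = character(), truth_rule = character()
  )
}

#' Split a merged variant table into per-caller tables
#'
#' The inverse of [consensus_merge()]: reconstructs the three per-caller
#' call sets implied by the `callers` column, dropping consensus-only
#' columns. Useful for exercising the merge on simulated data.
#'
#' @param variants A variant tibble with a comma-separated `callers` column.
#' @return A named list of tibbles, one per caller id appearing in the data.
#' @export
split_by_caller <- function(variants) {
  ids <- sort(unique(unlist(strsplit(variants$callers, ","))))
  setNames(lapply(ids, function(id) {
    variants |>
      dplyr::filter(purrr::map_lgl(
        strsplit(.data$callers, ","), ~ id %in% .x
      )) |>
      dplyr::select(-"callers")
  }), ids)
}
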