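#' Filtering thresholds for somatic variant discard rules
#'
#' Threshold boundary semantics follow the rules as stated, with strict
#' inequalities: tumor depth < `min_total_reads` discards (19 fails, 20
#' passes); VAF < `min_vaf` discards (VAF = 0.05 passes); germline mutant
#' reads > `max_germline_alt` discard (2 passes, 3 fails). `min_callers`
#' sets the consensus rule: 1 is the union of callers, 3 the intersection,
#' and the default 2 majority voting.
#'
#' @param min_total_reads Minimum tumor total read number (default 20).
#' @param min_vaf Minimum tumor variant allele frequency (default 0.05).
#' @param max_germline_alt Maximum mutant reads tolerated in the germline
#'   control (default 2).
#' @param min_callers Minimum number of supporting callers (default 2).
#' @return A validated list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_total_reads = 20L, min_vaf = 0.05,
                              max_germline_alt = 2L, min_callers = 2L) {
  stopifnot(min_total_reads > 0, min_vaf > 0, max_germline_alt >= 0,
            min_callers >= 1, min_callers <= 3)
  structure(
    list(min_total_reads = min_total_reads, min_vaf = min_vaf,
         max_germline_alt = max_germline_alt,
         min_callers = as.integer(min_callers)),
    class = "filter_thresholds"
  )
}

#' Variant allele frequency
#'
#' @param t_alt Variant-supporting read count(s).
#' @param t_depth Total read count(s) at the position; must be positive.
#' @return `t_alt / t_depth`, in `[0, 1]`. Vectorized.
#' @export
#' @examples
#' compute_vaf(5, 100) # 0.05 — not below the 0.05 discard threshold
compute_vaf <- function(t_alt, t_depth) {
  if (any(t_depth <= 0)) {
    abort("VAF undefined at zero depth; pre-filter zero-depth records")
  }
  if (any(t_alt < 0 | t_alt > t_depth)) {
    abort("t_alt must satisfy 0 <= t_alt <= t_depth")
  }
  t_alt / t_depth
}

#' Merge per-caller variant tables into a consensus table
#'
#' One output row per distinct variant keyed by (`chrom`, `pos`, `ref`,
#' `alt`); the `callers` column records which callers reported it. Numeric
#' evidence (depths, strand counts, germline support) is taken from the
#' first caller in `precedence` that reported the variant, and the chosen
#' source is recorded in `evidence_source`.
#'
#' @param per_caller_tables Named list of variant tibbles, one per caller,
#'   each with key columns plus evidence columns.
#' @param precedence Character vector giving the caller priority for
#'   evidence on disagreement; defaults to the list order.
#' @return A tibble with `callers` (comma-separated, sorted), `n_callers`
#'   and `evidence_source` columns added.
#' @export
consensus_merge <- function(per_caller_tables,
                            precedence = names(per_caller_tables)) {
  stopifnot(is.list(per_caller_tables), length(per_caller_tables) >= 1)
  if (is.null(names(per_caller_tables)) ||
      any(names(per_caller_tables) == "")) {
    abort("per_caller_tables must be a named list (one name per caller)")
  }
  stopifnot(setequal(precedence, names(per_caller_tables)))

  pooled <- purrr::imap_dfr(per_caller_tables, function(tbl, id) {
    if (nrow(tbl) == 0) return(NULL)
    dplyr::mutate(tibble::as_tibble(tbl), .caller = id)
  })
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- empty_variant_table()
    out$n_callers <- integer()
    out$evidence_source <- character()
    return(dplyr::select(out, -dplyr::any_of(c("truth_class", "truth_rule"))))
  }

  conflicts <- pooled |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref) |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf(
      "conflicting ref alleles at %d position(s), e.g. %s:%s",
      nrow(conflicts), conflicts$chrom[1], conflicts$pos[1]
    ))
  }

  pooled |>
    dplyr::mutate(.rank = match(.data$.caller, precedence)) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::arrange(.data$.rank, .by_group = TRUE) |>
    dplyr::mutate(
      callers = paste(sort(unique(.data$.caller)), collapse = ","),
      n_callers = dplyr::n_distinct(.data$.caller),
      evidence_source = dplyr::first(.data$.caller)
    ) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".caller", -".rank") |>
    dplyr::relocate("chrom", "pos", "ref", "alt", "callers", "n_callers") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Apply the somatic-variant discard rules
#'
#' Evaluates every discard rule on each variant and returns a per-variant
#' decision. A variant is discarded when any of the following holds:
#' * `low_total_reads` — tumor total read number < `min_total_reads`;
#' * `low_vaf` — tumor VAF < `min_vaf`;
#' * `germline_support` — mutant reads in the germline control >
#'   `max_germline_alt`;
#' * `single_strand` — all variant reads on one strand (zero on exactly one
#'   strand, with at least one variant read);
#' * `population_db` — present in the population SNP database or the
#'   user-supplied blacklist;
#' * `insufficient_caller_support` — reported by fewer than `min_callers`
#'   callers.
#' A variant is kept if and only if its reason list is empty.
#'
#' @param variants Variant tibble (as from [consensus_merge()] or
#'   [simulate_variant_calls()]) with columns `t_depth`, `t_alt`,
#'   `t_alt_fwd`, `t_alt_rev`, `n_alt`, `in_population_db`,
#'   `in_blacklist_db` and `callers` (comma-separated) or `n_callers`.
#' @param thresholds A [filter_thresholds()].
#' @return The input tibble with `vaf`, `kept` (logical), `reasons`
#'   (list-column of reason codes) and `reason_str` (comma-separated)
#'   appended.
#' @export
#' @examples
#' vc <- simulate_variant_calls(sim_config(seed = 1))
#' dec <- apply_discard_rules(vc)
#' table(dec$kept, dec$truth_class)
apply_discard_rules <- function(variants, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  v <- tibble::as_tibble(variants)
  if (nrow(v) == 0) {
    return(dplyr::mutate(v, vaf = numeric(), kept = logical(),
                         reasons = list(), reason_str = character()))
  }
  if (any(v$t_alt > v$t_depth) || any(v$t_alt < 0)) {
    abort("invalid read counts: need 0 <= t_alt <= t_depth")
  }
  if (any(v$t_alt_fwd + v$t_alt_rev != v$t_alt)) {
    abort("strand counts must sum to t_alt")
  }
  n_callers <- if ("n_callers" %in% names(v)) {
    v$n_callers
  } else {
    vapply(strsplit(v$callers, ","), function(x) length(unique(x)),
           integer(1))
  }

  vaf <- ifelse(v$t_depth > 0, v$t_alt / v$t_depth, 0)
  low_total <- v$t_depth < thresholds$min_total_reads
  low_vaf <- vaf < thresholds$min_vaf
  germ <- v$n_alt > thresholds$max_germline_alt
  single <- v$t_alt > 0 & xor(v$t_alt_fwd == 0, v$t_alt_rev == 0)
  popdb <- v$in_population_db | v$in_blacklist_db
  few_callers <- n_callers < thresholds$min_callers

  reason_mat <- cbind(
    low_total_reads = low_total, low_vaf = low_vaf,
    germline_support = germ, single_strand = single,
    population_db = popdb, insufficient_caller_support = few_callers
  )
  reasons <- apply(reason_mat, 1, function(r) colnames(reason_mat)[r],
                   simplify = FALSE)
  v |>
    dplyr::mutate(
      vaf = vaf,
      kept = !(low_total | low_vaf | germ | single | popdb | few_callers),
      reasons = reasons,
      reason_str = vapply(reasons, paste, character(1), collapse = ",")
    )
}

#' Tumor mutation burden
#'
#' Counts the kept non-synonymous mutations. Kept synonymous mutations are
#' excluded from the count but remain in the decision table — both classes
#' are called, only non-synonymous ones enter the burden.
#'
#' @param decisions Output of [apply_discard_rules()].
#' @return Integer count of kept non-synonymous mutations.
#' @export
#' @examples
#' vc <- simulate_variant_calls(sim_config(seed = 1))
#' compute_tmb(apply_discard_rules(vc))
compute_tmb <- function(decisions) {
  stopifnot(all(c("kept", "consequence") %in% names(decisions)))
  sum(decisions$kept & decisions$consequence == "non_synonymous")
}

#' One-row TMB summary
#'
#' @param decisions Output of [apply_discard_rules()].
#' @param sample_id Sample identifier carried into the summary.
#' @return A one-row tibble: `sample_id`, `n_input`, `n_kept`,
#'   `n_non_synonymous`.
#' @export
tmb_summary <- function(decisions, sample_id = "sample") {
  tibble::tibble(
    sample_id = sample_id,
    n_input = nrow(decisions),
    n_kept = sum(decisions$kept),
    n_non_synonymous = compute_tmb(decisions)
  )
}
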