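# Readers and writers for the plain-text interchange formats the pipeline
# consumes and emits. All tables are TSV; gene intervals may arrive as BED.

#' Read gene intervals from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted exactly to the
#' 1-based inclusive convention used internally (`start = bed_start + 1`,
#' `end = bed_end`).
#'
#' @param path Path to a 3+ column BED file (chrom, start, end\[, name\]).
#' @return Tibble with `chrom`, `start`, `end`, `gene`.
#' @export
read_bed_intervals <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", fill = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) abort("BED needs at least 3 columns")
  raw <- raw[!is.na(raw[[2]]) & !is.na(raw[[3]]), , drop = FALSE]
  tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]) + 1,
    end = as.numeric(raw[[3]]),
    gene = if (ncol(raw) >= 4) as.character(raw[[4]]) else
      paste0("interval", seq_len(nrow(raw)))
  )
}

#' Write truth segments as BED with a copy-number column
#'
#' @param segments Segment tibble (see [cn_segments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  readr::write_tsv(
    tibble::tibble(
      chrom = segments$chrom,
      start = as.integer(segments$start - 1), # back to 0-based half-open
      end = as.integer(segments$end),
      copy_number = segments$copy_number
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a SNP-site table
#'
#' @param path TSV with at least `chrom`, `pos`, `n_depth`, `t_depth`,
#'   `gc100` (and usually `n_vaf` or `n_alt`).
#' @return A tibble; `n_vaf` is derived from `n_alt`/`n_depth` when absent.
#' @export
read_snp_sites <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("chrom", "pos", "n_depth", "t_depth", "gc100")
  if (!all(req %in% names(x))) {
    abort(paste("missing columns:", paste(setdiff(req, names(x)),
                                          collapse = ", ")))
  }
  if (!"n_vaf" %in% names(x) && "n_alt" %in% names(x)) {
    x$n_vaf <- ifelse(x$n_depth > 0, x$n_alt / x$n_depth, NA_real_)
  }
  x
}

#' Read a cohort table
#'
#' @param path TSV with one row per patient (columns as produced by
#'   [simulate_cohort()]).
#' @return A tibble; times are validated as non-negative.
#' @export
read_cohort <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in intersect(c("pfs_months", "os_months"), names(x))) {
    if (any(x[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("%s contains negative times", col))
    }
  }
  x
}

#' Write a TMB summary as JSON
#'
#' @param summary One-row tibble from [tmb_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tmb_json <- function(summary, path) {
  jsonlite::write_json(as.list(summary[1, ]), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
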