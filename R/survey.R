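#' Round half-up to a fixed number of decimals
#'
#' Unlike [round()] (banker's rounding), ties go away from zero, matching the
#' convention of the published survey percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a homolog hit table from TSV
#'
#' Tool-agnostic layout: `species`, `group`, `evalue`, `length_aa`.
#'
#' @param path Path to a TSV file.
#' @return Data frame of hit records.
#' @export
read_hits_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "group", "evalue", "length_aa")
  if (!all(need %in% names(df)))
    stop("hit TSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$evalue)) || any(df$evalue < 0))
    stop("evalue must be finite and >= 0")
  if (any(df$length_aa < 1)) stop("length_aa must be >= 1")
  df
}

#' Keep hits below a significance threshold
#'
#' Strict inequality: a hit at exactly the threshold is removed.
#'
#' @param records Data frame with an `evalue` column.
#' @param evalue_max Threshold (default `1e-3`).
#' @return Filtered records.
#' @export
filter_hits <- function(records, evalue_max = 1e-3) {
  records[records$evalue < evalue_max, , drop = FALSE]
}

#' Remove fragment sequences
#'
#' Keeps records with `length_aa >= min_len`; sequences shorter than the
#' threshold are treated as fragments and dropped.
#'
#' @param records Data frame with a `length_aa` column.
#' @param min_len Minimum length in amino acids (default 450).
#' @return Filtered records.
#' @export
drop_fragments <- function(records, min_len = 450L) {
  records[records$length_aa >= min_len, , drop = FALSE]
}

#' Taxonomic survey table
#'
#' Counts unique species with a surviving hit per group and expresses them as
#' a percentage of the group's total species count, rounded half-up.
#'
#' @param records Data frame with `species` and `group` columns (already
#'   filtered).
#' @param totals Named numeric vector (group -> total species count) or a
#'   data frame with `group` and `n_total_species` (and optionally `digits`
#'   for per-row output precision).
#' @param digits Default decimal places for the percentage (default 2).
#' @return Data frame: `group`, `n_hit_species`, `n_total_species`, `pct`.
#' @export
survey_table <- function(records, totals, digits = 2) {
  if (is.data.frame(totals)) {
    tot <- stats::setNames(totals$n_total_species, totals$group)
    dig <- if ("digits" %in% names(totals))
      stats::setNames(totals$digits, totals$group) else NULL
  } else {
    tot <- totals
    dig <- NULL
  }
  groups <- names(tot)
  missing <- setdiff(unique(records$group), groups)
  if (length(missing))
    stop("groups missing from totals: ", paste(missing, collapse = ", "))
  n_hit <- vapply(groups, function(g)
    length(unique(records$species[records$group == g])), 0L)
  d <- if (is.null(dig)) rep(digits, length(groups)) else unname(dig[groups])
  pct <- vapply(seq_along(groups), function(i)
    round_half_up(100 * n_hit[i] / tot[[i]], d[i]), 0)
  data.frame(group = groups, n_hit_species = unname(n_hit),
             n_total_species = unname(tot), pct = pct,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Published homolog-survey count pairs
#'
#' The shipped fixture of per-group hit/total species counts (with the
#' published percentage and its printed precision) for the PADI taxonomic
#' survey, so the percentage computation can be checked end to end.
#'
#' @return Data frame: `group`, `taxid`, `n_hit_species`, `n_total_species`,
#'   `printed_pct`, `digits`.
#' @export
table1_reference <- function() {
  read.delim(system.file("extdata", "table1_counts.tsv", package = "hgtrace"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
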