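#' Accumulated genetic divergence (AGD) for a homolog triple
#'
#' For a protein with homologs in a reference taxon (e.g. human), a bridge
#' taxon (e.g. *Branchiostoma*) and a distal taxon (e.g. a cyanobacterium),
#' the AGD contrasts two bit-score densities that share the reference as
#' query and self-normalizer:
#' `agd = density(reference, bridge) - density(reference, distal)`.
#'
#' Under vertical descent the distal homolog has accumulated far more
#' divergence than the bridge homolog and AGD is large; a gene recently
#' transferred from the distal lineage into the reference/bridge clade shows
#' similar densities on both comparisons and AGD near zero.
#'
#' @param triple List or one-row data frame with `label`, `reference_id`,
#'   `bridge_id`, `distal_id`.
#' @param seqs Named character vector of protein sequences containing all
#'   three ids.
#' @param scheme A [scoring_scheme()].
#' @return One-row data frame: `label`, `d_distal_ref`, `d_bridge_ref`, `agd`.
#' @export
compute_agd <- function(triple, seqs, scheme = scoring_scheme()) {
  ids <- c(triple$reference_id, triple$bridge_id, triple$distal_id)
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    stop("sequences not loaded: ", paste(missing, collapse = ", "))
  ref <- seqs[[triple$reference_id]]
  d_distal <- bitscore_density(ref, seqs[[triple$distal_id]], scheme,
                               triple$reference_id, triple$distal_id)$density
  d_bridge <- bitscore_density(ref, seqs[[triple$bridge_id]], scheme,
                               triple$reference_id, triple$bridge_id)$density
  data.frame(label = triple$label, d_distal_ref = d_distal,
             d_bridge_ref = d_bridge, agd = d_bridge - d_distal,
             stringsAsFactors = FALSE)
}

#' AGD for a table of homolog triples
#'
#' @param triples Data frame with columns `label`, `reference_id`,
#'   `bridge_id`, `distal_id` (the TSV layout used throughout).
#' @inheritParams compute_agd
#' @return Data frame of AGD records, one row per triple.
#' @export
compute_agd_table <- function(triples, seqs, scheme = scoring_scheme()) {
  do.call(rbind, lapply(seq_len(nrow(triples)), function(i)
    compute_agd(triples[i, ], seqs, scheme)))
}

#' AGD from externally supplied bit scores
#'
#' Bypasses the built-in aligner: takes a table of precomputed bit scores
#' (e.g. from a profile search tool) with columns `query_id`, `target_id`,
#' `bits`, which must include the reference self-comparison rows.
#'
#' @param triples Data frame of homolog triples (see [compute_agd_table()]).
#' @param scores Data frame with `query_id`, `target_id`, `bits`.
#' @return Data frame of AGD records.
#' @export
agd_from_scores <- function(triples, scores) {
  get_bits <- function(q, t) {
    hit <- scores$bits[scores$query_id == q & scores$target_id == t]
    if (length(hit) != 1L)
      stop("need exactly one bit score for ", q, " vs ", t)
    hit
  }
  do.call(rbind, lapply(seq_len(nrow(triples)), function(i) {
    tr <- triples[i, ]
    self <- get_bits(tr$reference_id, tr$reference_id)
    if (self <= 0) stop("reference self bit score must be positive")
    d_distal <- get_bits(tr$reference_id, tr$distal_id) / self
    d_bridge <- get_bits(tr$reference_id, tr$bridge_id) / self
    data.frame(label = tr$label, d_distal_ref = d_distal,
               d_bridge_ref = d_bridge, agd = d_bridge - d_distal,
               stringsAsFactors = FALSE)
  }))
}

#' Summarize a panel of AGD records
#'
#' Computes the panel mean, sample standard deviation (n - 1) and a
#' Shapiro-Wilk normality test (Royston approximation, via
#' [stats::shapiro.test()]). Normality is retained when p > 0.05; a panel
#' with zero spread is flagged unusable for z-testing.
#'
#' @param records Data frame of AGD records (needs an `agd` column), or a
#'   numeric vector of AGD values.
#' @param category Panel label, e.g. `"vertical_ribosomal"`, `"egt_candidate"`,
#'   `"mito_encoded"` or `"custom"`.
#' @return An object of class `agd_panel`.
#' @export
panel_summary <- function(records, category = "custom") {
  values <- if (is.data.frame(records)) records$agd else as.numeric(records)
  if (length(values) < 3L) stop("panel needs at least 3 records")
  s <- sd(values)
  sw <- tryCatch(shapiro.test(values),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  structure(list(category = category,
                 records = if (is.data.frame(records)) records else NULL,
                 values = values, n = length(values),
                 mean = mean(values), sd = s,
                 shapiro_W = unname(sw$statistic), shapiro_p = sw$p.value,
                 normal = isTRUE(sw$p.value > 0.05),
                 usable_z = s > 0),
            class = "agd_panel")
}

#' @export
print.agd_panel <- function(x, ...) {
  cat("AGD panel (", x$category, "): n = ", x$n,
      ", mean = ", signif(x$mean, 4), ", sd = ", signif(x$sd, 4), "\n",
      sep = "")
  if (is.na(x$shapiro_p)) {
    cat("Shapiro-Wilk: not computable (degenerate values)\n")
  } else {
    cat("Shapiro-Wilk: W = ", signif(x$shapiro_W, 4), ", p = ",
        signif(x$shapiro_p, 4),
        if (x$normal) " (normality retained)" else " (normality rejected)",
        "\n", sep = "")
  }
  invisible(x)
}

#' One-tailed z-score outlier test against a panel
#'
#' Tests whether a value is an outlier relative to a normal panel:
#' `z = (value - mean) / sd`, with `p = pnorm(z)` for the lower tail or
#' `1 - pnorm(z)` for the upper tail.
#'
#' @param value Test value (e.g. the AGD of a candidate HGT protein).
#' @param panel An `agd_panel` from [panel_summary()].
#' @param tail `"lower"` (default; is the value suspiciously small?) or
#'   `"upper"`.
#' @param alpha Rejection level.
#' @return List of class `outlier_test`: `test_value`, `z`, `p_one_tailed`,
#'   `alpha`, `reject`.
#' @export
z_outlier_test <- function(value, panel, tail = c("lower", "upper"),
                           alpha = 0.05) {
  tail <- match.arg(tail)
  if (!inherits(panel, "agd_panel")) stop("panel must be an agd_panel")
  if (!isTRUE(panel$usable_z)) stop("panel sd is zero; z test undefined")
  z <- (value - panel$mean) / panel$sd
  p <- if (tail == "lower") pnorm(z) else 1 - pnorm(z)
  structure(list(test_value = value, z = z, p_one_tailed = p,
                 tail = tail, alpha = alpha, reject = p < alpha),
            class = "outlier_test")
}

#' @export
print.outlier_test <- function(x, ...) {
  cat("z outlier test (", x$tail, " tail): z = ", signif(x$z, 4),
      ", p = ", signif(x$p_one_tailed, 4),
      if (x$reject) paste0(" -> reject at alpha = ", x$alpha)
      else paste0(" -> retain at alpha = ", x$alpha), "\n", sep = "")
  invisible(x)
}

#' Control-panel protein names
#'
#' The protein names of the three control panels used by the AGD analysis:
#' 26 vertically inherited ribosomal proteins, 19 mitochondrially located
#' endosymbiotic-gene-transfer (EGT) candidates, and the 10 proteins still
#' encoded in the mitochondrial genome. Shipped as a fixture so users can
#' attach their own sequences to the panel structure.
#'
#' @return Data frame with columns `category`, `label`.
#' @export
panel_members <- function() {
  read.delim(system.file("extdata", "panel_members.tsv", package = "hgtrace"),
             stringsAsFactors = FALSE)
}

#' Read homolog triples from TSV
#'
#' @param path TSV with columns `label`, `reference_id`, `bridge_id`,
#'   `distal_id` and optionally `category`.
#' @return Data frame of triples.
#' @export
read_triples_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "reference_id", "bridge_id", "distal_id")
  if (!all(need %in% names(df)))
    stop("triples TSV must have columns: ", paste(need, collapse = ", "))
  df
}
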