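#' Construct a protein alignment object
#'
#' @param ids Character vector of row identifiers.
#' @param seqs Gapped sequences (amino acids plus `-`), all the same length.
#' @param groups Optional group labels (e.g. `metazoa`, `cyanobacteria`,
#'   `actinobacteria`, `fungi`); defaults to `"other"`.
#' @return Object of class `aa_alignment` (data frame `id`, `group`, `seq`).
#' @export
aa_alignment <- function(ids, seqs, groups = NULL) {
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (length(ids) < 2L) stop("alignment needs at least 2 rows")
  if (length(unique(nchar(seqs))) != 1L)
    stop("all alignment rows must have equal length")
  if (anyDuplicated(ids)) stop("duplicate row ids")
  groups <- groups %||% rep("other", length(ids))
  structure(data.frame(id = ids, group = groups, seq = toupper(seqs),
                       stringsAsFactors = FALSE),
            class = c("aa_alignment", "data.frame"))
}

#' Read an aligned FASTA file
#'
#' Group labels may be encoded in FASTA headers as `id|group`.
#'
#' @param path Path to an aligned (equal-length, gapped) FASTA file.
#' @return An `aa_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- sub("\\s.*$", "", names(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  groups <- vapply(parts, function(p) if (length(p) > 1) p[2] else "other", "")
  aa_alignment(ids, as.character(set), groups)
}

aln_row <- function(aln, id) {
  i <- match(id, aln$id)
  if (is.na(i)) stop("sequence '", id, "' not in alignment")
  strsplit(aln$seq[i], "")[[1]]
}

#' Map ungapped reference positions to alignment columns
#'
#' Builds the bijection between 1-based ungapped positions of a reference row
#' (the convention used for human PADI2 residue numbering) and 0-based
#' alignment columns.
#'
#' @param aln An `aa_alignment`.
#' @param reference_id Row id of the reference sequence.
#' @return Object of class `column_map`: `reference_id`, `mapping` (integer
#'   vector; `mapping[p]` is the 0-based column of reference position `p`),
#'   `reference_residues`.
#' @export
build_column_map <- function(aln, reference_id) {
  chars <- aln_row(aln, reference_id)
  nongap <- which(chars != "-")
  structure(list(reference_id = reference_id,
                 mapping = nongap - 1L,
                 reference_residues = chars[nongap]),
            class = "column_map")
}

#' Diagnostic residue rules for PADI typing
#'
#' Reads the shipped rule table mapping human-PADI2-numbered positions to the
#' residue states expected in the three-domain cyanobacterial/metazoan type
#' ("Ai") versus the two-domain actinobacterial/fungal type ("Bi"):
#' the calcium switch D389 (glycine in Bi sequences, incompetent for metal
#' coordination), the calcium-site-6 conservative substitutions D125->N and
#' E131->D, the triple-histidine motif at 300-302 marking the Bi connector
#' beta-sheet, advisory region rules (155-180, 292-302, calcium sites 2/4),
#' and catalytic/substrate residues expected to be conserved in all PADIs.
#'
#' @param path Optional path to a custom rules TSV (columns `name`,
#'   `positions`, `kind`, `ai_states`, `bi_states`, `severity`).
#' @return Data frame of rules; `positions` are comma-separated reference
#'   positions, states are comma-separated per-position residue alternatives.
#' @export
residue_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "padi_residue_rules.tsv",
                                package = "hgtrace")
  rules <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "positions", "kind", "ai_states", "bi_states", "severity")
  if (!all(need %in% names(rules)))
    stop("rules TSV must have columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(rules))) {
    if (rules$kind[i] == "diagnostic") {
      ai <- setdiff(strsplit(rules$ai_states[i], ",")[[1]], c("*", "!"))
      bi <- setdiff(strsplit(rules$bi_states[i], ",")[[1]], c("*", "!"))
      if (length(intersect(ai, bi)))
        stop("rule '", rules$name[i], "': ai and bi states must be disjoint")
    }
  }
  rules
}

rule_positions <- function(rule) {
  tokens <- strsplit(rule$positions, ",")[[1]]
  unlist(lapply(tokens, function(t) {
    if (grepl("-", t, fixed = TRUE)) {
      ends <- as.integer(strsplit(t, "-", fixed = TRUE)[[1]])
      seq.int(ends[1], ends[2])
    } else as.integer(t)
  }))
}

# Observed states of a row at reference positions; NA where gapped or
# positions exceed the map.
observed_states <- function(row_chars, map, positions) {
  cols <- rep(NA_integer_, length(positions))
  ok <- positions >= 1L & positions <= length(map$mapping)
  cols[ok] <- map$mapping[positions[ok]] + 1L
  out <- rep(NA_character_, length(positions))
  out[ok] <- row_chars[cols[ok]]
  out[out == "-"] <- NA_character_
  out
}

#' Classify a sequence as Ai-like or Bi-like from diagnostic residues
#'
#' Evaluates every rule at its mapped alignment columns and calls the
#' sequence `Ai_like` if all severity-critical diagnostic rules match the Ai
#' states and none matches a Bi state, `Bi_like` in the mirror case, and
#' `ambiguous` otherwise (including when rule positions are gapped and thus
#' unevaluable). Conserved-in-all rules (catalytic/substrate residues) are
#' reported but do not drive the call.
#'
#' @param aln An `aa_alignment`.
#' @param map A `column_map` from [build_column_map()].
#' @param rules Rules data frame (default [residue_rules()]).
#' @param id Row id to classify.
#' @return Object of class `type_call`: `id`, `call`, `per_rule` data frame.
#' @export
classify_sequence <- function(aln, map, rules = residue_rules(), id) {
  chars <- aln_row(aln, id)
  per <- lapply(seq_len(nrow(rules)), function(i) {
    rule <- rules[i, ]
    pos <- rule_positions(rule)
    obs <- observed_states(chars, map, pos)
    split_states <- function(s) strsplit(s, ",")[[1]]
    ai <- if (nzchar(rule$ai_states)) split_states(rule$ai_states) else
      character(0)
    bi <- if (nzchar(rule$bi_states)) split_states(rule$bi_states) else
      character(0)
    evaluable <- !anyNA(obs)
    # Per-position state tokens: a residue letter, "*" (any), or "!"
    # (anything other than the opposite side's state at that position).
    match_side <- function(side, other) {
      if (!evaluable || length(side) != length(obs)) return(FALSE)
      all(vapply(seq_along(obs), function(j) {
        if (side[j] == "*") TRUE
        else if (side[j] == "!") length(other) == length(obs) &&
          obs[j] != other[j]
        else obs[j] == side[j]
      }, TRUE))
    }
    match_ai <- rule$kind != "region" && match_side(ai, bi)
    match_bi <- rule$kind != "region" && match_side(bi, ai)
    data.frame(name = rule$name, kind = rule$kind, severity = rule$severity,
               observed = paste(ifelse(is.na(obs), "-", obs), collapse = ""),
               evaluable = evaluable, match_ai = match_ai,
               match_bi = match_bi, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  crit <- per$kind == "diagnostic" & per$severity == "critical"
  ai_ok <- all(per$evaluable[crit]) && all(per$match_ai[crit]) &&
    !any(per$match_bi[crit])
  bi_ok <- all(per$evaluable[crit]) && all(per$match_bi[crit]) &&
    !any(per$match_ai[crit])
  call <- if (ai_ok) "Ai_like" else if (bi_ok) "Bi_like" else "ambiguous"
  structure(list(id = id, call = call, per_rule = per), class = "type_call")
}

#' @export
print.type_call <- function(x, ...) {
  cat(x$id, "->", x$call, "\n")
  print(x$per_rule[, c("name", "severity", "observed", "match_ai",
                       "match_bi")], row.names = FALSE)
  invisible(x)
}

#' Classify every row of an alignment
#'
#' @inheritParams classify_sequence
#' @return Data frame with columns `id`, `call`.
#' @export
classify_all <- function(aln, map, rules = residue_rules()) {
  calls <- vapply(aln$id, function(id)
    classify_sequence(aln, map, rules, id)$call, "")
  data.frame(id = aln$id, call = unname(calls), stringsAsFactors = FALSE)
}

#' Per-group consensus at reference positions
#'
#' For each requested position and group, reports the single-letter consensus
#' if all (non-gapped) members share one residue, a two-state consensus
#' `"X/Y"` if members take exactly two residues, and `"nc"` (not conserved)
#' otherwise. A gap at the position renders that member unevaluable; if no
#' member is evaluable the entry is `"-"`.
#'
#' @param aln An `aa_alignment`.
#' @param map A `column_map`.
#' @param positions Integer vector of reference positions.
#' @param groups Character vector of group labels to report (default: all
#'   groups in the alignment).
#' @return Data frame: `position`, one column per group.
#' @export
conservation_report <- function(aln, map, positions,
                                groups = unique(aln$group)) {
  for (g in groups) if (!any(aln$group == g))
    stop("group '", g, "' has no sequences")
  rows <- lapply(aln$id, function(id) aln_row(aln, id))
  names(rows) <- aln$id
  out <- data.frame(position = positions)
  for (g in groups) {
    ids <- aln$id[aln$group == g]
    cons <- vapply(positions, function(p) {
      obs <- vapply(ids, function(id)
        observed_states(rows[[id]], map, p), "")
      obs <- obs[!is.na(obs)]
      states <- sort(unique(obs))
      if (length(states) == 0L) "-"
      else if (length(states) == 1L) states
      else if (length(states) == 2L) {
        tab <- sort(table(obs), decreasing = TRUE)
        paste(names(tab), collapse = "/")
      } else "nc"
    }, "")
    out[[g]] <- cons
  }
  out
}

#' Synthetic PADI-like demonstration alignment
#'
#' Generates a small gapless alignment emulating the diagnostic residue
#' layout of the PADI family on human-PADI2 numbering: metazoan and
#' cyanobacterial rows carry the Ai states (D125, E131, calcium switch D389,
#' a non-histidine connector at 300-302) and actinobacterial/fungal rows the
#' Bi states (N125, D131, G389, the HHH motif at 300-302), with the
#' catalytic/substrate residues conserved everywhere and seeded random
#' background divergence. This is a synthetic stand-in, not real PADI
#' sequence data.
#'
#' @param seed Random seed.
#' @param n_per_group Rows per group (default 3).
#' @param length Reference length (default 700; must cover position 647).
#' @return An `aa_alignment` whose first row, `ref_metazoa_1`, is the
#'   numbering reference.
#' @export
make_padi_demo_alignment <- function(seed = 1L, n_per_group = 3L,
                                     length = 700L) {
  stopifnot(length >= 650L)
  set.seed(seed)
  ref <- sample(AA20, length, replace = TRUE)
  ai_states <- list(`125` = "D", `131` = "E", `389` = "D",
                    `300` = "W", `301` = "K", `302` = "D")
  bi_states <- list(`125` = "N", `131` = "D", `389` = "G",
                    `300` = "H", `301` = "H", `302` = "H")
  catalytic <- list(`351` = "D", `471` = "H", `473` = "D", `647` = "C")
  apply_states <- function(x, states) {
    for (p in names(states)) x[as.integer(p)] <- states[[p]]
    x
  }
  ref <- apply_states(ref, ai_states)
  ref <- apply_states(ref, catalytic)
  fixed <- c(as.integer(names(ai_states)), as.integer(names(catalytic)))
  mutate_bg <- function(x, n_mut) {
    free <- setdiff(seq_along(x), fixed)
    sites <- sample(free, n_mut)
    x[sites] <- sample(AA20, n_mut, replace = TRUE)
    x
  }
  ids <- character(0); seqs <- character(0); grps <- character(0)
  for (g in c("metazoa", "cyanobacteria", "actinobacteria", "fungi")) {
    type_bi <- g %in% c("actinobacteria", "fungi")
    for (i in seq_len(n_per_group)) {
      x <- mutate_bg(ref, if (g == "metazoa") 15L * (i - 1L) else 60L)
      if (type_bi) x <- apply_states(x, bi_states)
      ids <- c(ids, paste0(if (i == 1 && g == "metazoa") "ref_" else "",
                           g, "_", i))
      seqs <- c(seqs, paste(x, collapse = ""))
      grps <- c(grps, g)
    }
  }
  aa_alignment(ids, seqs, grps)
}
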