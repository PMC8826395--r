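#' Read protein sequences from FASTA
#'
#' Reads a FASTA file (wrapped or single-line records) into a named character
#' vector of uppercase amino-acid sequences. The 20 standard residues plus
#' `X` (unknown) are accepted; any other character is an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) validate_protein(seqs[[i]], names(seqs)[i])
  seqs
}

#' Read nucleotide sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences over A/C/G/T/N.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` writes each sequence on one line.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else {
      writeLines(s, con)
    }
  }
  invisible(path)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

validate_protein <- function(seq, id = "<seq>") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("protein sequence '", id, "' must be a non-empty string")
  if (seq != toupper(seq))
    stop("protein sequence '", id, "' must be uppercase")
  bad <- setdiff(strsplit(seq, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop("protein sequence '", id, "' contains invalid characters: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

validate_dna <- function(seq, id = "<seq>") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("nucleotide sequence '", id, "' must be a non-empty string")
  bad <- setdiff(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("nucleotide sequence '", id, "' contains invalid characters: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}
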