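# Text input/output: FASTA records with optional per-record constraint
# lines, and the block output format (sequence, dot-bracket, energy).
#
# The input dialect extends FASTA: after a record's sequence line(s), a line
# consisting of constraint characters (. x ( )) supplies hard constraints
# for that record.  Because such mixed records are not valid FASTA, they are
# parsed here rather than delegated to a FASTA reader.

#' Read RNA sequences (FASTA dialect with optional constraint lines)
#'
#' Reads plain FASTA, headerless sequence lines, or the extended dialect in
#' which a record's sequence line is followed by a hard-constraint line
#' over \code{. x ( )}.
#'
#' @param path File path, or a character vector of lines via \code{text}.
#' @param text Character vector of input lines (used when \code{path} is
#'   missing).
#' @return A data.frame with columns \code{name}, \code{seq},
#'   \code{constraint} (NA when absent).
#' @export
read_fasta_rna <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- list()
  name <- NULL
  seqb <- character(0)
  consb <- character(0)
  flush <- function() {
    if (!length(seqb)) return()
    recs[[length(recs) + 1L]] <<- list(
      name = if (is.null(name)) paste0("seq", length(recs) + 1L) else name,
      seq = paste(seqb, collapse = ""),
      constraint = if (length(consb)) paste(consb, collapse = "") else
        NA_character_)
    seqb <<- character(0)
    consb <<- character(0)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- sub("^>\\s*", "", ln)
    } else if (grepl("^[.x()<>{}|]+$", ln)) {
      consb <- c(consb, ln)
    } else {
      if (length(consb)) flush()  # headerless record boundary
      seqb <- c(seqb, ln)
    }
  }
  flush()
  if (!length(recs)) stop("no sequence records found")
  data.frame(
    name = vapply(recs, `[[`, "", "name"),
    seq = vapply(recs, `[[`, "", "seq"),
    constraint = vapply(recs, `[[`, "", "constraint"),
    stringsAsFactors = FALSE)
}

# one output block per record: sequence, then structure with "(energy)"
format_fold <- function(fold, name = NULL) {
  c(if (!is.null(name)) paste0(">", name),
    fold$seq,
    paste0(fold$structure, sprintf(" (%.2f)", fold$mfe)))
}
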