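#' Read a reference FASTA into a reference set
#'
#' Loads nucleotide reference sequences (typically tRNA-scale, tens to a few
#' hundred bases each) into a named character vector, the reference-set
#' representation used throughout the package. Sequences are upper-cased and
#' validated to the alphabet `A,C,G,T,N`. Reference names routinely contain
#' `|` separators (e.g. tRNA database identifiers); the full header line is
#' kept by default.
#'
#' @param path Path to a FASTA file.
#' @param full_names Keep the complete header line (minus the leading `>`)
#'   as the reference name (default). If `FALSE`, the name is truncated at
#'   the first whitespace.
#' @return A named character vector of uppercase sequences, one element per
#'   FASTA record, with class `"reference_set"`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, full_names = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path)
  }
  nm <- names(set)
  if (!full_names) {
    nm <- sub("\\s.*$", "", nm)
  }
  nm <- trimws(nm)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0L) {
    stop("duplicate reference name(s) in FASTA: ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters (outside A,C,G,T,N) in record(s): ",
         paste(nm[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record(s): ", paste(nm[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- nm
  structure(seqs, class = "reference_set")
}

#' Write a reference set to FASTA
#'
#' @param ref Named character vector of sequences (a `reference_set`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  stopifnot(!is.null(names(ref)), all(nzchar(names(ref))))
  lines <- as.vector(rbind(paste0(">", names(ref)), unname(unclass(ref))))
  writeLines(lines, path)
  invisible(path)
}

# Single reference base at 1-based positions; "" outside the sequence.
ref_base_at <- function(ref, ref_name, pos) {
  if (!ref_name %in% names(ref)) {
    stop("reference '", ref_name, "' absent from the reference set")
  }
  s <- ref[[ref_name]]
  out <- rep("", length(pos))
  ok <- pos >= 1L & pos <= nchar(s)
  out[ok] <- substring(s, pos[ok], pos[ok])
  out
}
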