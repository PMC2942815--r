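## Loading and validating in-frame coding sequences.

#' Validate a set of in-frame coding sequences
#'
#' Sequences must have length divisible by 3, contain only A/C/G/T (gaps "-"
#' are allowed when \code{aligned = TRUE}), and contain no internal stop
#' codons. A single terminal stop codon is removed silently (RefSeq-style
#' CDS records include it).
#'
#' @param seqs named character vector of nucleotide sequences, or a
#'   \code{Biostrings::DNAStringSet}.
#' @param aligned logical; allow gap characters.
#' @return named character vector (uppercase), validated.
#' @export
validate_codon_sequences <- function(seqs, aligned = FALSE) {
  if (inherits(seqs, c("DNAStringSet", "BStringSet"))) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs)) || anyNA(seqs))
    stop("expected a named character vector of sequences")
  if (anyDuplicated(names(seqs)))
    stop("duplicated sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  allowed <- if (aligned) "ACGT-" else "ACGT"
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (nchar(s) == 0L) stop("empty sequence: ", id)
    if (nchar(s) %% 3L != 0L)
      stop("sequence '", id, "' length ", nchar(s), " is not a multiple of 3")
    if (grepl(paste0("[^", allowed, "]"), s))
      stop("sequence '", id, "' contains characters outside {", allowed, "}")
    cods <- split_codons(s)
    stops <- which(is_stop_codon(cods) %in% TRUE)
    if (length(stops)) {
      if (length(stops) == 1L && stops == length(cods)) {
        seqs[[id]] <- substr(s, 1L, nchar(s) - 3L)
        if (nchar(seqs[[id]]) == 0L) stop("sequence '", id, "' is only a stop codon")
      } else {
        stop("sequence '", id, "' has internal stop codon(s) at codon ",
             paste(stops[stops < length(cods)], collapse = ", "))
      }
    }
  }
  seqs
}

#' Read in-frame coding sequences from a multi-FASTA file
#'
#' @param path FASTA file (gaps "-" permitted when \code{aligned = TRUE}).
#' @inheritParams validate_codon_sequences
#' @return named character vector of validated sequences.
#' @export
read_codon_fasta <- function(path, aligned = FALSE) {
  x <- Biostrings::readBStringSet(path)
  validate_codon_sequences(stats::setNames(as.character(x), names(x)),
                           aligned = aligned)
}

#' Write sequences as multi-FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_codon_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# translate an in-frame (possibly gapped) nucleotide sequence to one-letter
# amino acids; gapped codons become "-", partially gapped/ambiguous "X"
translate_cds <- function(seq) {
  cods <- split_codons(seq)
  aa <- translate_codons(cods)
  gap <- cods == "---"
  aa[gap] <- "-"
  aa[is.na(aa) & !gap] <- "X"
  paste(aa, collapse = "")
}
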