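## Codon tables for NG86-style counting and for the simulator.
## Standard genetic code (NCBI table 1) only.

NUCS <- c("A", "C", "G", "T")

# package-level cache for derived tables (built lazily on first use)
.parasym_cache <- new.env(parent = emptyenv())

#' All 64 codons in fixed (A,C,G,T) lexicographic order
#' @keywords internal
#' @noRd
all_codons <- function() {
  g <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Build the codon lookup tables used throughout the package
#'
#' For every codon: its amino acid, stop status, NG86 synonymous site count,
#' and the classification of its nine single-nucleotide neighbours
#' (synonymous / non-synonymous / stop). Change index e in 1..9 encodes
#' position \code{(e - 1) \%/\% 3 + 1} mutated to the \code{(e - 1) \%\% 3 + 1}-th
#' alternative nucleotide (alternatives in A,C,G,T order, skipping the
#' current one).
#'
#' @return list of tables; cached after first call.
#' @keywords internal
#' @noRd
codon_tables <- function() {
  if (!is.null(.parasym_cache$tables)) return(.parasym_cache$tables)

  codons <- all_codons()
  gc_map <- Biostrings::GENETIC_CODE  # standard code, names are codons
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"

  n <- length(codons)
  idx <- stats::setNames(seq_len(n), codons)

  ## neighbour tables: 64 x 9
  nb_target <- matrix(NA_integer_, n, 9)
  nb_class <- matrix(NA_integer_, n, 9)  # 0 syn, 1 nonsyn, 2 stop
  for (i in seq_len(n)) {
    cod <- strsplit(codons[i], "")[[1]]
    e <- 0L
    for (pos in 1:3) {
      alts <- NUCS[NUCS != cod[pos]]
      for (a in alts) {
        e <- e + 1L
        mut <- cod
        mut[pos] <- a
        j <- idx[[paste(mut, collapse = "")]]
        nb_target[i, e] <- j
        nb_class[i, e] <- if (is_stop[j]) 2L else if (aa[j] == aa[i]) 0L else 1L
      }
    }
  }

  ## NG86 synonymous sites with stop-reduced per-position denominators:
  ## position contributes (#syn changes) / (3 - #stop changes); a position
  ## whose three changes are all stops contributes 0.
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (pos in 1:3) {
      e <- (pos - 1L) * 3L + 1:3
      cls <- nb_class[i, e]
      denom <- 3L - sum(cls == 2L)
      if (denom > 0L) s <- s + sum(cls == 0L) / denom
    }
    syn_sites[i] <- s
  }

  ## per-codon change-class counts (for the simulator)
  n_syn_ch <- rowSums(nb_class == 0L)
  n_nonsyn_ch <- rowSums(nb_class == 1L)

  .parasym_cache$tables <- list(
    codons = codons, index = idx, aa = aa, is_stop = is_stop,
    nb_target = nb_target, nb_class = nb_class,
    syn_sites = syn_sites, nonsyn_sites = 3 - syn_sites,
    n_syn_ch = n_syn_ch, n_nonsyn_ch = n_nonsyn_ch,
    sense = which(!is_stop))
  .parasym_cache$tables
}

#' NG86 synonymous and non-synonymous site counts of a codon
#'
#' Each of the three codon positions contributes the fraction of its
#' single-nucleotide changes that are synonymous, counted among changes not
#' producing a stop codon (the per-position denominator is reduced by
#' stop-producing changes). Non-synonymous sites are \code{3 - syn_sites}.
#'
#' @param codon character scalar, a sense codon (A/C/G/T).
#' @return named numeric vector \code{c(syn_sites=, nonsyn_sites=)}.
#' @examples
#' count_sites("TTT")  # 1/3 synonymous site
#' count_sites("TGG")  # tryptophan: 0 synonymous sites
#' @export
count_sites <- function(codon) {
  tb <- codon_tables()
  i <- codon_index(codon, tb)
  if (tb$is_stop[i]) stop("count_sites(): '", codon, "' is a stop codon")
  c(syn_sites = tb$syn_sites[i], nonsyn_sites = tb$nonsyn_sites[i])
}

# map codon string -> table row, with validation
codon_index <- function(codon, tb = codon_tables()) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("expected a single 3-letter codon, got: ", deparse(codon))
  codon <- toupper(codon)
  i <- tb$index[codon]
  if (is.na(i)) stop("not an unambiguous A/C/G/T codon: '", codon, "'")
  unname(i)
}

#' Translate a vector of codons to one-letter amino acids
#' @param codons character vector of 3-mers (may include gapped/ambiguous
#'   codons, returned as NA).
#' @return character vector of amino acids ("*" for stop, NA for
#'   gap/ambiguity).
#' @keywords internal
#' @noRd
translate_codons <- function(codons) {
  tb <- codon_tables()
  i <- tb$index[toupper(codons)]
  out <- rep(NA_character_, length(codons))
  ok <- !is.na(i)
  out[ok] <- tb$aa[i[ok]]
  out
}

#' Is a codon a stop codon under the standard genetic code?
#' @param codon character vector of 3-mers.
#' @return logical vector; NA for ambiguous/gapped codons.
#' @export
is_stop_codon <- function(codon) {
  tb <- codon_tables()
  i <- tb$index[toupper(codon)]
  out <- rep(NA, length(codon))
  ok <- !is.na(i)
  out[ok] <- tb$is_stop[i[ok]]
  out
}

# split an in-frame nucleotide string into codons
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
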