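## Building paralogous gene families: global-alignment identity links,
## single-linkage clustering, codon-aware multiple alignment, and the
## identity/divergence family filters. Genome-scale repeat masking and
## BLAST discovery are out of scope; identity is computed from global
## amino-acid alignments of the provided coding sequences, back-projected
## to nucleotides.

#' Similarity link between two coding sequences
#'
#' Globally aligns the amino-acid translations (Needleman-Wunsch,
#' BLOSUM62), back-projects the alignment to nucleotides, and reports the
#' nucleotide identity over aligned codon columns together with the
#' coverage (aligned span as a fraction of the average sequence length).
#'
#' @param a,b in-frame nucleotide sequences (unaligned, gap-free).
#' @param id_a,id_b identifiers.
#' @return data.frame row: id_a, id_b, identity_fraction, coverage_fraction.
#' @export
pairwise_similarity <- function(a, b, id_a = "a", id_b = "b") {
  pa <- translate_cds(toupper(unname(a)))
  pb <- translate_cds(toupper(unname(b)))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ## back-project: aligned (non-gap in both) AA columns correspond to codons
  ia <- cumsum(pat != "-")
  ib <- cumsum(sub != "-")
  both <- pat != "-" & sub != "-"
  ca <- split_codons(toupper(unname(a)))[ia[both]]
  cb <- split_codons(toupper(unname(b)))[ib[both]]
  nt_matches <- sum(3L - nt_hamming(ca, cb))
  n_aligned_nt <- 3L * length(ca)
  identity <- if (n_aligned_nt) nt_matches / n_aligned_nt else 0
  coverage <- n_aligned_nt / mean(c(nchar(a), nchar(b)))
  data.frame(id_a = id_a, id_b = id_b,
             identity_fraction = identity,
             coverage_fraction = min(1, coverage),
             stringsAsFactors = FALSE)
}

#' All-pairs similarity links for a sequence set
#' @param seqs named character vector of in-frame sequences.
#' @return data.frame of \code{\link{pairwise_similarity}} rows.
#' @export
similarity_links <- function(seqs) {
  ids <- names(seqs)
  n <- length(ids)
  if (n < 2L) return(data.frame(id_a = character(), id_b = character(),
                                identity_fraction = numeric(),
                                coverage_fraction = numeric()))
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    rows[[length(rows) + 1L]] <-
      pairwise_similarity(seqs[[i]], seqs[[j]], ids[i], ids[j])
  do.call(rbind, rows)
}

#' Single-linkage clustering of genes from thresholded similarity links
#'
#' Genes joined by any link with identity >= \code{min_identity} over
#' coverage >= \code{min_coverage} fall in the same preliminary group
#' (connected components of the link graph). Singletons are returned too;
#' downstream family filtering drops groups below the minimum size.
#'
#' @param links data.frame with columns id_a, id_b, identity_fraction,
#'   coverage_fraction (as from \code{\link{similarity_links}}).
#' @param ids all gene ids (so unlinked genes appear as singletons);
#'   defaults to the ids present in \code{links}.
#' @param min_identity,min_coverage link thresholds (defaults 0.75 / 0.20).
#' @return named integer vector: component membership per gene id, with
#'   components numbered by their lexicographically smallest member.
#' @export
single_linkage_cluster <- function(links, ids = NULL,
                                   min_identity = 0.75, min_coverage = 0.20) {
  if (is.null(ids)) ids <- sort(unique(c(links$id_a, links$id_b)))
  keep <- links$identity_fraction >= min_identity &
    links$coverage_fraction >= min_coverage
  g <- igraph::graph_from_data_frame(
    links[keep, c("id_a", "id_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  ## renumber components deterministically by smallest member id
  comp <- comp[ids]
  reps <- vapply(split(names(comp), comp), min, character(1))
  stats::setNames(match(reps[as.character(comp)], sort(unname(reps))), ids)
}

#' Codon-aware multiple alignment of a gene group
#'
#' Aligns amino-acid translations (mafft) and back-projects the alignment
#' to codons; sequences that already share one length are taken as aligned
#' (the simulator emits gap-free alignments).
#'
#' @param seqs named character vector of in-frame sequences.
#' @param method "auto" (align only when lengths differ), "mafft", or
#'   "none" (require equal lengths).
#' @return named character vector: codon alignment with "-" gaps.
#' @export
align_family <- function(seqs, method = c("auto", "mafft", "none")) {
  method <- match.arg(method)
  same_len <- length(unique(nchar(seqs))) == 1L
  if (method == "none" ||
      (method == "auto" && same_len)) {
    if (!same_len) stop("sequences differ in length; alignment required")
    return(toupper(seqs))
  }
  if (Sys.which("mafft") == "")
    stop("mafft not found on PATH; supply pre-aligned sequences")
  aa <- vapply(seqs, translate_cds, character(1))
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aa), fin)
  status <- system2("mafft", c("--auto", "--amino", "--quiet", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aal <- as.character(Biostrings::readAAStringSet(fout))
  ## restore input order (mafft preserves it, but be safe) and back-project
  aal <- aal[names(seqs)]
  out <- vapply(names(seqs), function(id) {
    cods <- split_codons(toupper(seqs[[id]]))
    cols <- strsplit(aal[[id]], "")[[1]]
    res <- character(length(cols))
    k <- 0L
    for (i in seq_along(cols)) {
      if (cols[i] == "-") res[i] <- "---"
      else { k <- k + 1L; res[i] <- cods[k] }
    }
    if (k != length(cods)) stop("back-projection failed for ", id)
    paste(res, collapse = "")
  }, character(1))
  out
}

# fraction of unanimous nucleotide columns after removing columns with any
# gap; also per-gene mean pairwise divergence over those columns
alignment_identity_stats <- function(aln) {
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  keep <- colSums(mat == "-") == 0L
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat); L <- ncol(mat)
  if (L == 0L)
    return(list(identity = NA_real_,
                divergence = stats::setNames(rep(NA_real_, n), names(aln)),
                n_columns = 0L))
  unanimous <- vapply(seq_len(L),
                      function(j) length(unique(mat[, j])) == 1L, logical(1))
  div <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- mean(mat[i, ] != mat[j, ])
    div[i, j] <- div[j, i] <- d
  }
  list(identity = mean(unanimous),
       divergence = stats::setNames(rowSums(div) / (n - 1L), names(aln)),
       n_columns = L)
}

#' Filter an aligned gene group into an accepted family (or reject it)
#'
#' After removing alignment columns containing any gap: genes whose mean
#' pairwise nucleotide divergence from the other members exceeds
#' \code{max_divergence} are removed one at a time (most divergent first,
#' statistics recomputed after each removal); the remaining family must
#' have at least \code{min_size} members and a unanimous-column identity
#' fraction within [\code{min_identity}, \code{max_identity}].
#'
#' @param aln named character vector: codon alignment of the group.
#' @param min_identity,max_identity family-level identity window
#'   (defaults 0.25 / 0.98).
#' @param max_divergence per-gene removal threshold (default 0.80).
#' @param min_size minimum family size (default 3).
#' @param family_id label.
#' @return list of class \code{"gene_family"} (\code{family_id},
#'   \code{members}, \code{alignment}, \code{qc}) when accepted, otherwise
#'   a list of class \code{"family_rejection"} with a \code{reason}.
#' @export
filter_family <- function(aln, min_identity = 0.25, max_identity = 0.98,
                          max_divergence = 0.80, min_size = 3,
                          family_id = "family") {
  if (is.null(names(aln)) || length(unique(nchar(aln))) != 1L)
    stop("aln must be a named, equal-length alignment")
  removed <- character(0)
  repeat {
    if (length(aln) < min_size)
      return(reject(family_id, sprintf("fewer than %d members remain", min_size),
                    removed))
    st <- alignment_identity_stats(aln)
    worst <- which.max(st$divergence)
    if (length(aln) > min_size - 1L && !is.na(st$divergence[worst]) &&
        st$divergence[worst] > max_divergence) {
      removed <- c(removed, names(aln)[worst])
      aln <- aln[-worst]
      next
    }
    break
  }
  st <- alignment_identity_stats(aln)
  if (is.na(st$identity))
    return(reject(family_id, "no gap-free alignment columns", removed))
  if (st$identity < min_identity)
    return(reject(family_id, sprintf(
      "family identity %.3f below %.2f", st$identity, min_identity), removed))
  if (st$identity > max_identity)
    return(reject(family_id, sprintf(
      "family identity %.3f above %.2f", st$identity, max_identity), removed))
  structure(list(family_id = family_id, members = names(aln),
                 alignment = aln,
                 qc = list(identity = st$identity,
                           divergence = st$divergence,
                           n_columns = st$n_columns,
                           removed = removed)),
            class = "gene_family")
}

reject <- function(family_id, reason, removed = character(0)) {
  structure(list(family_id = family_id, reason = reason, removed = removed),
            class = "family_rejection")
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene_family '", x$family_id, "': ", length(x$members),
      " members, identity ", sprintf("%.3f", x$qc$identity), "\n", sep = "")
  invisible(x)
}

#' @export
print.family_rejection <- function(x, ...) {
  cat("rejected family '", x$family_id, "': ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Build gene families from a sequence set
#'
#' Runs all-pairs similarity linking, single-linkage clustering at the
#' 75\%-identity / 20\%-coverage thresholds, per-group codon-aware
#' alignment, and the family identity/divergence filters.
#'
#' @param seqs named character vector of in-frame sequences.
#' @param min_identity,min_coverage link thresholds.
#' @param min_size minimum family size.
#' @param family_min_identity,family_max_identity,max_divergence filter
#'   thresholds, see \code{\link{filter_family}}.
#' @param align_method see \code{\link{align_family}}.
#' @return list: \code{families} (accepted \code{gene_family} objects),
#'   \code{rejections}, and \code{qc} (data.frame of per-group outcomes).
#' @export
build_families <- function(seqs, min_identity = 0.75, min_coverage = 0.20,
                           min_size = 3, family_min_identity = 0.25,
                           family_max_identity = 0.98, max_divergence = 0.80,
                           align_method = "auto") {
  seqs <- validate_codon_sequences(seqs)
  links <- similarity_links(seqs)
  memb <- single_linkage_cluster(links, ids = names(seqs),
                                 min_identity = min_identity,
                                 min_coverage = min_coverage)
  fams <- list(); rejs <- list(); qc <- list()
  for (g in sort(unique(memb))) {
    ids <- names(memb)[memb == g]
    fid <- sprintf("fam%03d", g)
    if (length(ids) < min_size) {
      rejs[[fid]] <- reject(fid, sprintf("group size %d below %d",
                                         length(ids), min_size))
      qc[[fid]] <- data.frame(family_id = fid, n_in = length(ids), n_out = 0L,
                              accepted = FALSE, reason = rejs[[fid]]$reason)
      next
    }
    aln <- align_family(seqs[ids], method = align_method)
    res <- filter_family(aln, min_identity = family_min_identity,
                         max_identity = family_max_identity,
                         max_divergence = max_divergence,
                         min_size = min_size, family_id = fid)
    if (inherits(res, "gene_family")) {
      fams[[fid]] <- res
      qc[[fid]] <- data.frame(family_id = fid, n_in = length(ids),
                              n_out = length(res$members), accepted = TRUE,
                              reason = "")
    } else {
      rejs[[fid]] <- res
      qc[[fid]] <- data.frame(family_id = fid, n_in = length(ids), n_out = 0L,
                              accepted = FALSE, reason = res$reason)
    }
  }
  list(families = fams, rejections = rejs,
       qc = if (length(qc)) do.call(rbind, c(qc, list(make.row.names = FALSE)))
            else data.frame())
}
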