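# Independent oracles used across tests. These deliberately avoid the
# package's internal tables and code paths: the genetic code comes straight
# from Biostrings::GENETIC_CODE and paths are enumerated by recursive DFS.

oracle_aa <- function(codon) unname(Biostrings::GENETIC_CODE[[codon]])

# brute-force path enumeration for NG86 differences: explore every ordering
# of single-nucleotide steps from a to b by depth-first search, discard
# paths through stop codons, average step classifications
oracle_count_diffs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  acc <- list(syn = 0, paths = 0L)
  walk <- function(cur, syn_so_far) {
    pos <- which(cur != cb)
    if (!length(pos)) {
      acc$syn <<- acc$syn + syn_so_far
      acc$paths <<- acc$paths + 1L
      return(invisible())
    }
    for (p in pos) {
      nxt <- cur
      nxt[p] <- cb[p]
      codon_next <- paste(nxt, collapse = "")
      if (oracle_aa(codon_next) == "*") next
      step_syn <- oracle_aa(codon_next) == oracle_aa(paste(cur, collapse = ""))
      walk(nxt, syn_so_far + as.integer(step_syn))
    }
  }
  walk(ca, 0)
  d <- sum(ca != cb)
  if (acc$paths == 0L) return(c(syn = 0, nonsyn = d))
  s <- acc$syn / acc$paths
  c(syn = s, nonsyn = d - s)
}

# exhaustive single-linkage components: merge groups until fixpoint
oracle_components <- function(ids, edges) {
  comp <- as.list(ids)
  names(comp) <- ids
  grp <- stats::setNames(ids, ids)   # representative per id
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      ga <- grp[[edges$id_a[r]]]; gb <- grp[[edges$id_b[r]]]
      if (ga != gb) {
        grp[grp == gb] <- ga
        changed <- TRUE
      }
    }
  }
  ## normalize: membership indexed by smallest member of each group
  reps <- vapply(split(names(grp), unname(grp)), min, character(1))
  stats::setNames(match(reps[as.character(grp)], sort(unname(reps))), ids)
}

# deterministic toy rate matrix from a dS (and optional dN) matrix
toy_matrix <- function(dS, dN = dS * 0.2, family_id = "toy") {
  ids <- rownames(dS)
  sat <- !is.finite(dS)
  diag(sat) <- FALSE
  structure(list(family_id = family_id, ids = ids, dS = dS, dN = dN,
                 aa_identity = matrix(NA_real_, nrow(dS), ncol(dS),
                                      dimnames = dimnames(dS)),
                 nt_diffs = matrix(NA_integer_, nrow(dS), ncol(dS),
                                   dimnames = dimnames(dS)),
                 saturated = sat, provenance = "toy"),
            class = "rate_matrix")
}

# build a symmetric dS matrix; pair names either two single-character ids
# ("ij") or dot-separated ("g1.g2")
sym_ds <- function(ids, ...) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- list(...)
  for (nm in names(vals)) {
    ij <- if (grepl(".", nm, fixed = TRUE)) strsplit(nm, ".", fixed = TRUE)[[1]]
          else strsplit(nm, "")[[1]]
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- vals[[nm]]
  }
  m
}

# nucleotide sequence encoding a given amino-acid string (first codon found)
codons_for <- function(aa_string) {
  gc <- Biostrings::GENETIC_CODE
  vapply(strsplit(aa_string, "")[[1]], function(a) {
    names(gc)[gc == a][1]
  }, character(1))
}
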