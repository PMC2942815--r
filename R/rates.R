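## Pairwise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
## correction. Replaces codeml pairwise runs; an import adapter
## (import_rates) lets externally computed tables be used instead.

# permutations of 1..d, rows = orderings (d <= 3 here)
.perms <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' Synonymous and non-synonymous differences between two codons
#'
#' NG86 pathway averaging: when the codons differ at d positions, the d!
#' orderings of single-nucleotide steps are enumerated; each step is
#' classified synonymous (amino acid preserved) or non-synonymous, and the
#' classification is averaged over orderings whose intermediate codons are
#' all sense codons. Orderings passing through a stop codon are discarded
#' and the average renormalized over the remainder. If every ordering passes
#' through a stop, the d differences are counted as non-synonymous by
#' convention and a warning is emitted.
#'
#' @param codon_a,codon_b sense codons (3-letter strings).
#' @return named numeric vector \code{c(syn_diffs=, nonsyn_diffs=)}; the two
#'   components sum to the nucleotide Hamming distance of the codons.
#' @examples
#' count_diffs("TTT", "TTC")  # Phe->Phe: one synonymous difference
#' count_diffs("TTT", "GTT")  # Phe->Val: one non-synonymous difference
#' @export
count_diffs <- function(codon_a, codon_b) {
  tb <- codon_tables()
  ia <- codon_index(codon_a, tb)
  ib <- codon_index(codon_b, tb)
  if (tb$is_stop[ia] || tb$is_stop[ib])
    stop("count_diffs(): stop codon input")
  d <- codon_pair_diffs(ia, ib, tb, warn = TRUE)
  c(syn_diffs = d[[1]], nonsyn_diffs = d[[2]])
}

# core path-averaged counting on table rows; returns c(syn, nonsyn)
codon_pair_diffs <- function(ia, ib, tb, warn = FALSE) {
  a <- strsplit(tb$codons[ia], "")[[1]]
  b <- strsplit(tb$codons[ib], "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) return(c(0, 0))
  perms <- .perms[[d]]
  syn_tot <- 0
  n_valid <- 0L
  for (r in seq_len(nrow(perms))) {
    cur <- a
    ci <- ia
    syn <- 0
    ok <- TRUE
    for (p in pos[perms[r, ]]) {
      cur[p] <- b[p]
      cj <- tb$index[[paste(cur, collapse = "")]]
      if (tb$is_stop[cj]) { ok <- FALSE; break }
      if (tb$aa[cj] == tb$aa[ci]) syn <- syn + 1
      ci <- cj
    }
    if (ok) { syn_tot <- syn_tot + syn; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) {
    if (warn) warning("all substitution paths between ", tb$codons[ia], " and ",
                      tb$codons[ib], " pass through stop codons; ",
                      "counting all ", d, " difference(s) as non-synonymous")
    return(c(0, d))
  }
  s <- syn_tot / n_valid
  c(s, d - s)
}

# lazily built 64x64 path-averaged difference tables (syn / nonsyn);
# entries involving stop codons are NA
diff_tables <- function() {
  if (!is.null(.parasym_cache$difftab)) return(.parasym_cache$difftab)
  tb <- codon_tables()
  n <- length(tb$codons)
  syn <- matrix(NA_real_, n, n)
  nsy <- matrix(NA_real_, n, n)
  for (ia in tb$sense) for (ib in tb$sense) {
    d <- codon_pair_diffs(ia, ib, tb)
    syn[ia, ib] <- d[[1]]
    nsy[ia, ib] <- d[[2]]
  }
  .parasym_cache$difftab <- list(syn = syn, nonsyn = nsy)
  .parasym_cache$difftab
}

#' Jukes-Cantor distance from a proportion of differences
#' @param p proportion of sites differing (0 <= p < 3/4).
#' @return corrected distance; NA when p >= 3/4 (saturated).
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN and dS for two aligned coding sequences
#'
#' NG86 counting with Jukes-Cantor correction. Codon columns where either
#' sequence has a gap or an ambiguous base, or where either codon is a stop,
#' are skipped pairwise and excluded from \code{n_codons_compared}. Site
#' counts are averaged over the two sequences; differences are
#' path-averaged. When pS or pN reaches 3/4 the Jukes-Cantor distance is
#' undefined and the result is flagged \code{saturated} (distance
#' \code{Inf}); downstream selection must skip such pairs.
#'
#' @param a,b equal-length aligned in-frame nucleotide strings (gaps "-").
#' @param id_a,id_b identifiers (default from names).
#' @return a list of class \code{"pairwise_rates"} with elements
#'   \code{id_a, id_b, syn_sites, nonsyn_sites, syn_diffs, nonsyn_diffs,
#'   pS, pN, dS, dN, n_codons_compared, aa_identity, nt_diffs, saturated}.
#' @export
pairwise_rates <- function(a, b, id_a = NULL, id_b = NULL) {
  if (is.null(id_a)) id_a <- if (!is.null(names(a))) names(a)[1] else "a"
  if (is.null(id_b)) id_b <- if (!is.null(names(b))) names(b)[1] else "b"
  a <- toupper(unname(a)); b <- toupper(unname(b))
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned to equal length (",
         nchar(a), " vs ", nchar(b), ")")
  tb <- codon_tables()
  ca <- split_codons(a); cb <- split_codons(b)
  ia <- tb$index[ca]; ib <- tb$index[cb]
  keep <- !is.na(ia) & !is.na(ib) & !tb$is_stop[ia] & !tb$is_stop[ib]
  ia <- ia[keep]; ib <- ib[keep]
  ncod <- length(ia)

  dt <- diff_tables()
  sd_pairs <- if (ncod) dt$syn[cbind(ia, ib)] else numeric()
  nd_pairs <- if (ncod) dt$nonsyn[cbind(ia, ib)] else numeric()
  syn_sites <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  nonsyn_sites <- 3 * ncod - syn_sites
  syn_diffs <- sum(sd_pairs)
  nonsyn_diffs <- sum(nd_pairs)

  pS <- if (syn_sites > 0) syn_diffs / syn_sites else 0
  pN <- if (nonsyn_sites > 0) nonsyn_diffs / nonsyn_sites else 0
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  saturated <- is.na(dS) || is.na(dN)

  aa_a <- tb$aa[ia]; aa_b <- tb$aa[ib]
  aa_identity <- if (ncod) mean(aa_a == aa_b) else NA_real_
  nt_diffs <- sum(nt_hamming(tb$codons[ia], tb$codons[ib]))

  structure(list(
    id_a = id_a, id_b = id_b,
    syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
    syn_diffs = syn_diffs, nonsyn_diffs = nonsyn_diffs,
    pS = pS, pN = pN,
    dS = if (saturated) Inf else dS, dN = if (saturated) Inf else dN,
    n_codons_compared = ncod, aa_identity = aa_identity,
    nt_diffs = nt_diffs, saturated = saturated),
    class = "pairwise_rates")
}

# per-codon nucleotide Hamming distances between codon string vectors
nt_hamming <- function(ca, cb) {
  m <- matrix(0L, length(ca), 1)
  for (p in 1:3)
    m <- m + (substr(ca, p, p) != substr(cb, p, p))
  as.integer(m)
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf("pairwise rates %s vs %s: dN = %.4g, dS = %.4g (%d codons%s)\n",
              x$id_a, x$id_b, x$dN, x$dS, x$n_codons_compared,
              if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

#' All-pairs rate matrix for a gene family
#'
#' @param seqs named character vector of aligned in-frame sequences
#'   (one shared alignment; gaps "-").
#' @param family_id label for the family.
#' @return list of class \code{"rate_matrix"}: \code{ids}, symmetric
#'   matrices \code{dS}, \code{dN}, \code{aa_identity}, \code{nt_diffs},
#'   logical \code{saturated}, \code{family_id}, and \code{provenance}.
#' @export
rate_matrix <- function(seqs, family_id = "family") {
  if (length(seqs) < 2L) stop("rate_matrix() needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must share one alignment (equal lengths)")
  ids <- names(seqs)
  n <- length(ids)
  dS <- dN <- aai <- matrix(0, n, n, dimnames = list(ids, ids))
  ntd <- matrix(0L, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(aai) <- 1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pr <- pairwise_rates(seqs[[i]], seqs[[j]], ids[i], ids[j])
    dS[i, j] <- dS[j, i] <- pr$dS
    dN[i, j] <- dN[j, i] <- pr$dN
    aai[i, j] <- aai[j, i] <- pr$aa_identity
    ntd[i, j] <- ntd[j, i] <- pr$nt_diffs
    sat[i, j] <- sat[j, i] <- pr$saturated
  }
  structure(list(family_id = family_id, ids = ids, dS = dS, dN = dN,
                 aa_identity = aai, nt_diffs = ntd, saturated = sat,
                 provenance = "internal NG86/JC"),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix '", x$family_id, "': ", length(x$ids), " genes, ",
      sum(x$saturated[upper.tri(x$saturated)]), " saturated pair(s) [",
      x$provenance, "]\n", sep = "")
  invisible(x)
}

#' Export a rate matrix as a long-format pairwise table
#' @param m a \code{rate_matrix}.
#' @return data.frame with one row per unordered pair.
#' @export
rates_table <- function(m) {
  n <- length(m$ids)
  ut <- which(upper.tri(m$dS), arr.ind = TRUE)
  data.frame(family = m$family_id,
             id_a = m$ids[ut[, 1]], id_b = m$ids[ut[, 2]],
             dS = m$dS[ut], dN = m$dN[ut],
             aa_identity = m$aa_identity[ut],
             nt_diffs = m$nt_diffs[ut],
             saturated = m$saturated[ut],
             stringsAsFactors = FALSE)
}

#' Import an externally computed pairwise-rates table
#'
#' Accepts tables of codeml-style pairwise estimates (columns \code{id_a},
#' \code{id_b}, \code{dN}, \code{dS}), so the original maximum-likelihood
#' estimator can stand in for the internal counting one. Every unordered
#' pair of \code{ids} must be present; duplicate (reversed) entries must
#' agree within \code{tol}. Pairs with dS above the downstream comparison
#' cap of 3 (or non-finite values) are flagged saturated.
#'
#' @param table data.frame or path to a TSV.
#' @param ids gene identifiers the matrix must cover; defaults to all ids in
#'   the table.
#' @param family_id label.
#' @param tol tolerance for disagreeing duplicate entries.
#' @return a \code{rate_matrix} (without alignment-derived columns:
#'   \code{aa_identity} and \code{nt_diffs} are NA).
#' @export
import_rates <- function(table, ids = NULL, family_id = "family", tol = 1e-8) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  req <- c("id_a", "id_b", "dN", "dS")
  if (!all(req %in% names(table)))
    stop("rates table must have columns: ", paste(req, collapse = ", "))
  if (is.null(ids)) ids <- sort(unique(c(table$id_a, table$id_b)))
  n <- length(ids)
  dS <- dN <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(dS) <- diag(dN) <- 0
  for (r in seq_len(nrow(table))) {
    a <- table$id_a[r]; b <- table$id_b[r]
    if (!(a %in% ids) || !(b %in% ids) || a == b) next
    differs <- function(x, y) !isTRUE(x == y) && !isTRUE(abs(x - y) <= tol)
    if (!is.na(dS[a, b]) &&
        (differs(dS[a, b], table$dS[r]) || differs(dN[a, b], table$dN[r])))
      stop("asymmetric duplicate entries for pair (", a, ", ", b,
           ") disagree beyond tolerance")
    dS[a, b] <- dS[b, a] <- table$dS[r]
    dN[a, b] <- dN[b, a] <- table$dN[r]
  }
  miss <- which(upper.tri(dS) & is.na(dS), arr.ind = TRUE)
  if (nrow(miss))
    stop("rates table is missing pair(s): ",
         paste(sprintf("(%s, %s)", ids[miss[, 1]], ids[miss[, 2]]),
               collapse = ", "))
  sat <- !is.finite(dS) | !is.finite(dN) | dS > 3
  diag(sat) <- FALSE
  aai <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ntd <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  structure(list(family_id = family_id, ids = ids, dS = dS, dN = dN,
                 aa_identity = aai, nt_diffs = ntd, saturated = sat,
                 provenance = "imported"),
            class = "rate_matrix")
}
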