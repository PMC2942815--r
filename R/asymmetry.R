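## Asymmetry screen: bidirectional best paralog pairs, outgroup-parsimony
## assignment of substitutions to the two post-duplication lineages, exact
## binomial symmetry tests per pair, and the genome-scale binomial
## meta-test.

#' Bidirectional best paralog pairs with their closest cousin
#'
#' Genes A and B form a pair when each is the other's sister (by dS, within
#' the 0.01-3 comparison window). The pair's cousin C must satisfy
#' dS[A,C] > dS[A,B] and dS[B,C] > dS[A,B] (distances capped at
#' \code{ds_max}, saturated pairs excluded) and minimizes
#' dS[A,C] + dS[B,C]; ties break to the lexicographically smaller id.
#' Pairs without a valid cousin are dropped.
#'
#' @param m a \code{rate_matrix}.
#' @param ds_min,ds_max sister comparison window.
#' @return data.frame: family, gene_a, gene_b, cousin, dS_ab, dS_ac, dS_bc.
#' @export
bidirectional_best_pairs <- function(m, ds_min = 0.01, ds_max = 3) {
  sisters <- vapply(m$ids, find_sister, character(1),
                    m = m, ds_min = ds_min, ds_max = ds_max)
  rows <- list()
  for (a in m$ids) {
    b <- sisters[[a]]
    if (is.na(b) || b <= a) next            # each unordered pair once
    if (is.na(sisters[[b]]) || sisters[[b]] != a) next
    cc <- pair_cousin(a, b, m, ds_max)
    if (is.na(cc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      family = m$family_id, gene_a = a, gene_b = b, cousin = cc,
      dS_ab = m$dS[a, b], dS_ac = m$dS[a, cc], dS_bc = m$dS[b, cc],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(family = character(), gene_a = character(),
                      gene_b = character(), cousin = character(),
                      dS_ab = numeric(), dS_ac = numeric(), dS_bc = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# closest cousin of a pair: min dS sum subject to the outgroup inequalities
pair_cousin <- function(a, b, m, ds_max = 3) {
  others <- setdiff(m$ids, c(a, b))
  if (!length(others)) return(NA_character_)
  d_ab <- m$dS[a, b]
  d_ac <- m$dS[a, others]
  d_bc <- m$dS[b, others]
  ok <- !m$saturated[a, others] & !m$saturated[b, others] &
    d_ac > d_ab & d_bc > d_ab & d_ac <= ds_max & d_bc <= ds_max
  if (!any(ok)) return(NA_character_)
  cand <- others[ok]
  tot <- d_ac[ok] + d_bc[ok]
  cand[order(tot, cand)][1]
}

#' Assign substitutions to the two genes of a pair by outgroup parsimony
#'
#' At each divergent position where genes a and b differ, the outgroup c
#' identifies the lineage that changed: if b agrees with c the substitution
#' is assigned to a (x1), if a agrees with c it is assigned to b (x2);
#' positions where all three differ are excluded, and positions with a gap
#' in any of the three are excluded separately.
#'
#' Channels: \code{"aa"} compares translated amino-acid columns.
#' \code{"syn"} considers only nucleotide columns inside codons whose
#' translations are identical across all three genes, so every assigned
#' change is synonymous by construction; codons not amino-acid-conserved
#' across the triplet are excluded from the synonymous channel (counted in
#' \code{excluded_nonconserved}).
#'
#' @param a,b,c aligned in-frame nucleotide strings (a, b the pair, c the
#'   cousin).
#' @param channel "aa" or "syn".
#' @return list of class \code{"substitution_assignment"}: x1, x2, y,
#'   excluded_all_differ, excluded_gap, excluded_nonconserved, channel.
#' @export
assign_substitutions <- function(a, b, c, channel = c("aa", "syn")) {
  channel <- match.arg(channel)
  a <- toupper(unname(a)); b <- toupper(unname(b)); c <- toupper(unname(c))
  if (length(unique(nchar(c(a, b, c)))) != 1L)
    stop("a, b and c must be aligned to equal length")
  ca <- split_codons(a); cb <- split_codons(b); cci <- split_codons(c)
  gap <- grepl("-", ca) | grepl("-", cb) | grepl("-", cci)
  x1 <- 0L; x2 <- 0L; excl_ad <- 0L; excl_nc <- 0L
  excl_gap <- sum(gap)
  aa_a <- translate_codons(ca); aa_b <- translate_codons(cb)
  aa_c <- translate_codons(cci)
  if (channel == "aa") {
    for (i in which(!gap)) {
      if (is.na(aa_a[i]) || is.na(aa_b[i]) || is.na(aa_c[i])) {
        excl_gap <- excl_gap + 1L  # ambiguous codon treated like a gap
      } else if (aa_a[i] != aa_b[i]) {
        if (aa_b[i] == aa_c[i]) x1 <- x1 + 1L
        else if (aa_a[i] == aa_c[i]) x2 <- x2 + 1L
        else excl_ad <- excl_ad + 1L
      }
    }
  } else {
    for (i in which(!gap)) {
      if (is.na(aa_a[i]) || is.na(aa_b[i]) || is.na(aa_c[i])) {
        excl_gap <- excl_gap + 1L
        next
      }
      if (!(aa_a[i] == aa_b[i] && aa_b[i] == aa_c[i])) {
        excl_nc <- excl_nc + 1L
        next
      }
      for (p in 1:3) {
        na_ <- substr(ca[i], p, p); nb <- substr(cb[i], p, p)
        nc <- substr(cci[i], p, p)
        if (na_ != nb) {
          if (nb == nc) x1 <- x1 + 1L
          else if (na_ == nc) x2 <- x2 + 1L
          else excl_ad <- excl_ad + 1L
        }
      }
    }
  }
  structure(list(x1 = x1, x2 = x2, y = x1 + x2,
                 excluded_all_differ = excl_ad, excluded_gap = excl_gap,
                 excluded_nonconserved = excl_nc, channel = channel),
            class = "substitution_assignment")
}

#' @export
print.substitution_assignment <- function(x, ...) {
  cat(sprintf("substitution assignment (%s): x1 = %d, x2 = %d (excluded: %d all-differ, %d gap)\n",
              x$channel, x$x1, x$x2, x$excluded_all_differ, x$excluded_gap))
  invisible(x)
}

#' Exact binomial test of symmetric substitution accumulation
#'
#' Under symmetric evolution the substitutions of a pair split as
#' X1 | (X1 + X2 = n) ~ Binomial(n, 1/2). The two-sided p-value doubles the
#' smaller tail and is capped at 1; \code{sided = "one"} gives the single
#' smaller-tail probability. n = 0 gives p = 1.
#'
#' @param x1,x2 non-negative substitution counts.
#' @param sided "two" (default) or "one".
#' @return p-value.
#' @examples
#' binom_symmetry_test(52, 8)   # strongly asymmetric
#' binom_symmetry_test(10, 10)  # p = 1
#' @export
binom_symmetry_test <- function(x1, x2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(x1) != 1L || length(x2) != 1L || is.na(x1) || is.na(x2) ||
      x1 < 0 || x2 < 0 || x1 != round(x1) || x2 != round(x2))
    stop("x1 and x2 must be single non-negative integers")
  n <- x1 + x2
  if (n == 0) return(1)
  tail <- stats::pbinom(min(x1, x2), n, 0.5)
  if (sided == "one") tail else min(1, 2 * tail)
}

#' Binomial meta-test for the number of asymmetric pairs
#'
#' Upper-tail probability P(X >= n_asymmetric) for X ~ Binomial(n_pairs,
#' p_asym), computed by direct term-by-term summation in log space (no
#' normal approximation). This is the genome-scale test of whether the
#' observed number of individually significant pairs could arise by chance
#' when each pair is asymmetric with probability \code{p_asym}.
#'
#' @param n_asymmetric observed number of significant pairs.
#' @param n_pairs number of pairs tested.
#' @param p_asym per-pair null probability (default 0.05).
#' @return p-value.
#' @examples
#' meta_test(26, 144)  # 1.33e-8
#' meta_test(9, 144)   # 0.295
#' @export
meta_test <- function(n_asymmetric, n_pairs, p_asym = 0.05) {
  if (p_asym <= 0 || p_asym >= 1) stop("p_asym must be in (0, 1)")
  if (n_asymmetric < 0 || n_asymmetric > n_pairs)
    stop("need 0 <= n_asymmetric <= n_pairs")
  if (n_asymmetric == 0) return(1)
  k <- n_asymmetric:n_pairs
  lt <- lchoose(n_pairs, k) + k * log(p_asym) + (n_pairs - k) * log1p(-p_asym)
  mx <- max(lt)
  exp(mx) * sum(exp(lt - mx))
}

#' Run the asymmetry screen over families
#'
#' For every family: find bidirectional best paralog pairs with their
#' closest cousin, assign substitutions by outgroup parsimony in the chosen
#' channel, test each pair for symmetry, and run the binomial meta-test
#' over all tested pairs.
#'
#' @param families list of \code{gene_family} objects, or a single named
#'   list of aligned sequence vectors (one per family).
#' @param matrices optional list of precomputed \code{rate_matrix} objects
#'   parallel to \code{families}; computed internally when NULL.
#' @param alpha per-pair significance level (default 0.05).
#' @param channel "aa" or "syn".
#' @param sided "two" or "one".
#' @param p_asym meta-test per-pair null probability (default 0.05).
#' @return list of class \code{"asymmetry_screen"}: \code{results}
#'   (per-pair data.frame with x1, x2, exclusions, p_value, significant)
#'   and \code{meta} (n_pairs, n_asymmetric, p_asym, p_value).
#' @export
run_asymmetry_screen <- function(families, matrices = NULL, alpha = 0.05,
                                 channel = c("aa", "syn"),
                                 sided = c("two", "one"), p_asym = 0.05) {
  channel <- match.arg(channel)
  sided <- match.arg(sided)
  rows <- list()
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    aln <- if (inherits(fam, "gene_family")) fam$alignment else fam
    fid <- if (inherits(fam, "gene_family")) fam$family_id
           else if (!is.null(names(families))) names(families)[fi]
           else sprintf("fam%03d", fi)
    m <- if (is.null(matrices)) rate_matrix(aln, fid) else matrices[[fi]]
    pairs <- bidirectional_best_pairs(m)
    if (!nrow(pairs)) next
    for (r in seq_len(nrow(pairs))) {
      asg <- assign_substitutions(aln[[pairs$gene_a[r]]],
                                  aln[[pairs$gene_b[r]]],
                                  aln[[pairs$cousin[r]]], channel = channel)
      p <- binom_symmetry_test(asg$x1, asg$x2, sided = sided)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fid, gene_a = pairs$gene_a[r], gene_b = pairs$gene_b[r],
        cousin = pairs$cousin[r], dS_ab = pairs$dS_ab[r],
        x1 = asg$x1, x2 = asg$x2,
        excluded_all_differ = asg$excluded_all_differ,
        excluded_gap = asg$excluded_gap,
        p_value = p, significant = p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(family = character(), gene_a = character(),
                  gene_b = character(), cousin = character(),
                  dS_ab = numeric(), x1 = integer(), x2 = integer(),
                  excluded_all_differ = integer(), excluded_gap = integer(),
                  p_value = numeric(), significant = logical(),
                  stringsAsFactors = FALSE)
  n_pairs <- nrow(results)
  n_asym <- sum(results$significant)
  meta_p <- if (n_pairs > 0) meta_test(n_asym, n_pairs, p_asym) else NA_real_
  structure(list(results = results,
                 meta = list(n_pairs = n_pairs, n_asymmetric = n_asym,
                             p_asym = p_asym, p_value = meta_p),
                 alpha = alpha, channel = channel, sided = sided),
            class = "asymmetry_screen")
}

#' @export
print.asymmetry_screen <- function(x, ...) {
  cat(sprintf("asymmetry screen (%s channel, %s-sided): %d / %d pairs significant at alpha = %g\n",
              x$channel, x$sided, x$meta$n_asymmetric, x$meta$n_pairs, x$alpha))
  if (!is.na(x$meta$p_value))
    cat(sprintf("meta-test P(X >= %d | n = %d, p = %g) = %.3g\n",
                x$meta$n_asymmetric, x$meta$n_pairs, x$meta$p_asym,
                x$meta$p_value))
  invisible(x)
}
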