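## Sister/cousin selection and individual (per-gene) dN_I, dS_I by the
## three-point formula. Distances come from a rate_matrix; the comparison
## window 0.01 <= dS <= 3 applies throughout (saturated pairs are treated
## as dS > 3), with both endpoints inclusive.

#' Find the sister (closest paralog by dS within the comparison window)
#'
#' The sister minimizes dS to the gene among family members with
#' 0.01 <= dS <= 3; neighbors closer than dS = 0.01 are skipped (repeatedly)
#' and saturated pairs are excluded. Ties are broken by lexicographically
#' smaller id.
#'
#' @param gene gene id.
#' @param m a \code{rate_matrix}.
#' @param ds_min,ds_max comparison window (defaults 0.01, 3).
#' @return sister id, or NA_character_ if no candidate is in the window.
#' @export
find_sister <- function(gene, m, ds_min = 0.01, ds_max = 3) {
  others <- setdiff(m$ids, gene)
  if (!length(others)) return(NA_character_)
  ds <- m$dS[gene, others]
  ok <- !m$saturated[gene, others] & ds >= ds_min & ds <= ds_max
  if (!any(ok)) return(NA_character_)
  cand <- others[ok]
  ds <- ds[ok]
  cand <- cand[order(ds, cand)]
  cand[1]
}

#' Find the cousin (closest valid outgroup) for a gene and its sister
#'
#' A cousin k must satisfy dS[i,k] > dS[i,j] and dS[j,k] > dS[i,j] (so it
#' lies outside the sister-pair branch) with both distances at most
#' \code{ds_max} and unsaturated; among valid cousins the one minimizing
#' dS[i,k] is chosen, ties broken by lexicographic id.
#'
#' @param gene,sister gene ids.
#' @param m a \code{rate_matrix}.
#' @param ds_max distance cap (default 3).
#' @return cousin id or NA_character_.
#' @export
find_cousin <- function(gene, sister, m, ds_max = 3) {
  others <- setdiff(m$ids, c(gene, sister))
  if (!length(others)) return(NA_character_)
  d_ij <- m$dS[gene, sister]
  d_ik <- m$dS[gene, others]
  d_jk <- m$dS[sister, others]
  ok <- !m$saturated[gene, others] & !m$saturated[sister, others] &
    d_ik > d_ij & d_jk > d_ij & d_ik <= ds_max & d_jk <= ds_max
  if (!any(ok)) return(NA_character_)
  cand <- others[ok]
  d_ik <- d_ik[ok]
  cand[order(d_ik, cand)][1]
}

#' Individual rates of gene i from the three pairwise distances
#'
#' The three-point decomposition \code{(d[i,j] + d[i,k] - d[j,k]) / 2}
#' recovers the branch length from i back to the duplication node under
#' additivity. Negative values (possible when noise makes the distances
#' non-additive) are retained; callers flag and later window-filter them.
#'
#' @param d_ij,d_ik,d_jk pairwise distances (dN or dS alike).
#' @return the individual rate of gene i.
#' @export
individual_rates <- function(d_ij, d_ik, d_jk) {
  (d_ij + d_ik - d_jk) / 2
}

#' Build the triplet table (gene, sister, cousin, individual rates)
#'
#' For every gene with a valid sister and cousin, records the six pairwise
#' distances and the individual dN_I, dS_I and omega_I = dN_I / dS_I
#' (NA with flag "omega_undefined" when dS_I <= 0; negative individual
#' rates are flagged "nonadditive").
#'
#' @param m a \code{rate_matrix}.
#' @param ds_min,ds_max sister comparison window.
#' @return data.frame, one row per gene with a complete triplet; columns
#'   family, gene, sister, cousin, dS_ij, dS_ik, dS_jk, dN_ij, dN_ik,
#'   dN_jk, dS_I, dN_I, omega_I, flags.
#' @export
triplet_table <- function(m, ds_min = 0.01, ds_max = 3) {
  rows <- list()
  for (g in m$ids) {
    s <- find_sister(g, m, ds_min, ds_max)
    if (is.na(s)) next
    k <- find_cousin(g, s, m, ds_max)
    if (is.na(k)) next
    dS_I <- individual_rates(m$dS[g, s], m$dS[g, k], m$dS[s, k])
    dN_I <- individual_rates(m$dN[g, s], m$dN[g, k], m$dN[s, k])
    flags <- character(0)
    if (dS_I < 0 || dN_I < 0) flags <- c(flags, "nonadditive")
    omega_I <- if (dS_I > 0) dN_I / dS_I else NA_real_
    if (dS_I <= 0) flags <- c(flags, "omega_undefined")
    rows[[g]] <- data.frame(
      family = m$family_id, gene = g, sister = s, cousin = k,
      dS_ij = m$dS[g, s], dS_ik = m$dS[g, k], dS_jk = m$dS[s, k],
      dN_ij = m$dN[g, s], dN_ik = m$dN[g, k], dN_jk = m$dN[s, k],
      dS_I = dS_I, dN_I = dN_I, omega_I = omega_I,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(family = character(), gene = character(),
                      sister = character(), cousin = character(),
                      dS_ij = numeric(), dS_ik = numeric(), dS_jk = numeric(),
                      dN_ij = numeric(), dN_ik = numeric(), dN_jk = numeric(),
                      dS_I = numeric(), dN_I = numeric(), omega_I = numeric(),
                      flags = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Keep triplets whose individual dS falls in the reliable window
#'
#' The analysis of recently duplicated genes restricts to individual dS
#' between \code{lo} and \code{hi} (inclusive); negative (non-additive)
#' values fall below \code{lo} and are dropped by the same rule.
#'
#' @param triplets data.frame from \code{\link{triplet_table}}.
#' @param lo,hi window bounds (defaults 0.005, 0.6).
#' @return filtered data.frame; attribute \code{"n_dropped"} records how
#'   many rows were removed.
#' @export
rate_window_filter <- function(triplets, lo = 0.005, hi = 0.6) {
  keep <- triplets$dS_I >= lo & triplets$dS_I <= hi
  out <- triplets[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
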