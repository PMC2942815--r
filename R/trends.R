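## dN/dS-versus-dS trend analysis: OLS regression of omega_I on dS_I with
## a t-based 95% CI on the slope, the >=100-substitution robustness
## control, and per-family average rates.

#' Fit the linear trend of dN/dS against dS
#'
#' Ordinary least squares of omega on dS; the slope confidence interval
#' comes from the t distribution. A negative slope indicates that purifying
#' selection strengthens with time since duplication.
#'
#' @param ds,omega numeric vectors (paired points), or a data.frame with
#'   columns \code{dS_I} and \code{omega_I} as the first argument.
#' @param conf confidence level (default 0.95).
#' @param subset_label free-text label carried into the result.
#' @return list of class \code{"trend_fit"}: slope, intercept, ci95_lo,
#'   ci95_hi, n, subset_label, undefined (TRUE when all ds are identical).
#' @export
fit_trend <- function(ds, omega = NULL, conf = 0.95, subset_label = "all") {
  if (is.data.frame(ds)) {
    omega <- ds$omega_I
    ds <- ds$dS_I
  }
  keep <- is.finite(ds) & is.finite(omega)
  ds <- ds[keep]; omega <- omega[keep]
  n <- length(ds)
  if (n < 3L) stop("fit_trend() needs at least 3 points with defined omega")
  if (stats::var(ds) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          ci95_lo = NA_real_, ci95_hi = NA_real_, n = n,
                          subset_label = subset_label, undefined = TRUE),
                     class = "trend_fit"))
  fit <- stats::lm(omega ~ ds)
  co <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, "ds", level = conf))
  structure(list(slope = unname(co[["ds"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 ci95_lo = unname(ci[1]), ci95_hi = unname(ci[2]), n = n,
                 subset_label = subset_label, undefined = FALSE),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  if (x$undefined) {
    cat("trend_fit [", x$subset_label, "]: undefined slope (no spread in dS)\n",
        sep = "")
  } else {
    cat(sprintf("trend_fit [%s]: slope = %.3f (95%% CI %.3f .. %.3f), n = %d\n",
                x$subset_label, x$slope, x$ci95_lo, x$ci95_hi, x$n))
  }
  invisible(x)
}

#' Restrict triplets to genes with enough substitutions to their sister
#'
#' Robustness control against artifacts of discrete substitution counts:
#' keeps genes whose raw nucleotide difference count to the sister is at
#' least \code{min_subs} (inclusive).
#'
#' @param triplets data.frame from \code{\link{triplet_table}}.
#' @param m the family's \code{rate_matrix} (source of \code{nt_diffs}),
#'   or a list of matrices named by family.
#' @param min_subs threshold (default 100).
#' @return filtered data.frame with an extra \code{nt_diffs_sister} column.
#' @export
substitution_floor_filter <- function(triplets, m, min_subs = 100) {
  get_m <- function(fam) {
    if (inherits(m, "rate_matrix")) m else m[[fam]]
  }
  nd <- vapply(seq_len(nrow(triplets)), function(r) {
    mm <- get_m(triplets$family[r])
    as.numeric(mm$nt_diffs[triplets$gene[r], triplets$sister[r]])
  }, numeric(1))
  triplets$nt_diffs_sister <- nd
  triplets[!is.na(nd) & nd >= min_subs, , drop = FALSE]
}

#' Per-family average rates
#'
#' The family's dN and dS are the averages of the pairwise values over all
#' unordered member pairs; the family omega is, by default, the ratio of
#' those averages (mean dN / mean dS), with mean-of-ratios available.
#'
#' @param matrices a \code{rate_matrix} or list of them.
#' @param omega_method "ratio-of-means" (default) or "mean-of-ratios".
#' @return data.frame: family_id, n_genes, mean_dN, mean_dS, family_omega,
#'   any_saturated.
#' @export
family_summaries <- function(matrices, omega_method = c("ratio-of-means",
                                                        "mean-of-ratios")) {
  omega_method <- match.arg(omega_method)
  if (inherits(matrices, "rate_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(m) {
    ut <- upper.tri(m$dS)
    ds <- m$dS[ut]; dn <- m$dN[ut]
    fin <- is.finite(ds) & is.finite(dn)
    mean_ds <- mean(ds[fin]); mean_dn <- mean(dn[fin])
    fo <- if (omega_method == "ratio-of-means") {
      if (mean_ds > 0) mean_dn / mean_ds else NA_real_
    } else {
      ok <- fin & ds > 0
      if (any(ok)) mean(dn[ok] / ds[ok]) else NA_real_
    }
    data.frame(family_id = m$family_id, n_genes = length(m$ids),
               mean_dN = mean_dn, mean_dS = mean_ds, family_omega = fo,
               any_saturated = any(m$saturated[ut]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
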