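## End-to-end pipeline: configuration, stage orchestration, TSV outputs,
## filter-count bookkeeping, and the packaged fixture of published
## asymmetric-pair substitution counts.

#' Pipeline configuration
#'
#' Collects every threshold of the analysis with its published default:
#' link identity 0.75 over coverage 0.20, family identity window
#' 0.25-0.98, per-gene divergence cap 0.80, family minimum size 3, sister
#' comparison window dS in [0.01, 3], individual-rate window [0.005, 0.6],
#' per-pair alpha 0.05, meta-test p 0.05, substitution floor 100.
#'
#' @param input path to a multi-FASTA (one sequence set) or a directory /
#'   vector of per-family FASTA files; may be NULL when sequences are
#'   passed to \code{\link{run_pipeline}} directly.
#' @param out_dir output directory (NULL: write nothing).
#' @param min_identity,min_coverage similarity link thresholds.
#' @param family_min_identity,family_max_identity,max_divergence,min_size
#'   family filter thresholds.
#' @param ds_min,ds_max sister comparison window.
#' @param window_lo,window_hi individual dS window.
#' @param alpha per-pair significance level.
#' @param p_asym meta-test per-pair null probability.
#' @param min_subs substitution floor for the trend control.
#' @param channel asymmetry channel, "aa" or "syn".
#' @param sided "two" or "one".
#' @param prealigned treat each input file as one pre-aligned family,
#'   skipping family discovery.
#' @param seed integer seed (recorded; the analysis itself is
#'   deterministic).
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(input = NULL, out_dir = NULL,
                       min_identity = 0.75, min_coverage = 0.20,
                       family_min_identity = 0.25, family_max_identity = 0.98,
                       max_divergence = 0.80, min_size = 3,
                       ds_min = 0.01, ds_max = 3,
                       window_lo = 0.005, window_hi = 0.6,
                       alpha = 0.05, p_asym = 0.05, min_subs = 100,
                       channel = "aa", sided = "two",
                       prealigned = FALSE, seed = 1L) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1,
            family_min_identity <= family_max_identity,
            ds_min <= ds_max, window_lo <= window_hi,
            alpha > 0, alpha < 1, p_asym > 0, p_asym < 1, min_subs >= 0)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: family building (or loading pre-aligned families) -> all-pairs
#' rates -> sister/cousin triplets with individual rates -> asymmetry
#' screen -> trend fits and family summaries. Per-stage tables are written
#' as TSV when \code{out_dir} is set, along with the resolved configuration
#' and a counts log attributing every drop to its filter.
#'
#' @param config a \code{\link{run_config}}.
#' @param seqs optional named character vector of sequences (overrides
#'   \code{config$input}); or a named list of pre-aligned family sequence
#'   vectors when \code{config$prealigned} is TRUE.
#' @return list of class \code{"run_report"}: families, matrices, triplets
#'   (raw and windowed), screen, trend, family_summary, counts.
#' @export
run_pipeline <- function(config, seqs = NULL) {
  stopifnot(inherits(config, "run_config"))
  counts <- list()

  ## --- stage: input ---------------------------------------------------
  fam_alns <- NULL
  if (is.null(seqs) && !is.null(config$input)) {
    paths <- config$input
    if (length(paths) == 1L && dir.exists(paths))
      paths <- list.files(paths, pattern = "\\.fa(sta)?$", full.names = TRUE)
    if (config$prealigned) {
      fam_alns <- lapply(paths, read_codon_fasta, aligned = TRUE)
      names(fam_alns) <- tools::file_path_sans_ext(basename(paths))
    } else {
      seqs <- do.call(c, lapply(paths, read_codon_fasta))
    }
  } else if (!is.null(seqs) && config$prealigned && is.list(seqs)) {
    fam_alns <- seqs
    seqs <- NULL
  }

  ## --- stage: families ------------------------------------------------
  if (is.null(fam_alns)) {
    if (is.null(seqs) || !length(seqs)) {
      counts$genes_in <- 0L
      return(empty_report(config, counts))
    }
    seqs <- validate_codon_sequences(seqs)
    counts$genes_in <- length(seqs)
    fb <- build_families(seqs, min_identity = config$min_identity,
                         min_coverage = config$min_coverage,
                         min_size = config$min_size,
                         family_min_identity = config$family_min_identity,
                         family_max_identity = config$family_max_identity,
                         max_divergence = config$max_divergence)
    families <- fb$families
    qc <- fb$qc
  } else {
    counts$genes_in <- sum(lengths(fam_alns))
    families <- lapply(names(fam_alns), function(fid) {
      aln <- validate_codon_sequences(fam_alns[[fid]], aligned = TRUE)
      structure(list(family_id = fid, members = names(aln), alignment = aln,
                     qc = list()), class = "gene_family")
    })
    names(families) <- names(fam_alns)
    qc <- data.frame(family_id = names(fam_alns),
                     n_in = lengths(fam_alns),
                     n_out = lengths(fam_alns),
                     accepted = TRUE, reason = "", stringsAsFactors = FALSE)
  }
  counts$families_kept <- length(families)
  counts$genes_in_families <- sum(vapply(families, function(f)
    length(f$members), integer(1)))
  if (!length(families)) return(empty_report(config, counts))

  ## --- stage: rates ---------------------------------------------------
  matrices <- lapply(families, function(f)
    rate_matrix(f$alignment, f$family_id))
  names(matrices) <- vapply(families, `[[`, character(1), "family_id")

  ## --- stage: triplets ------------------------------------------------
  trip <- do.call(rbind, c(lapply(matrices, triplet_table,
                                  ds_min = config$ds_min,
                                  ds_max = config$ds_max),
                           list(make.row.names = FALSE)))
  counts$triplets_computed <- nrow(trip)
  trip_win <- rate_window_filter(trip, config$window_lo, config$window_hi)
  counts$triplets_in_window <- nrow(trip_win)
  counts$triplets_dropped_window <- attr(trip_win, "n_dropped")

  ## --- stage: asymmetry -----------------------------------------------
  screen <- run_asymmetry_screen(families, matrices, alpha = config$alpha,
                                 channel = config$channel,
                                 sided = config$sided,
                                 p_asym = config$p_asym)
  counts$pairs_tested <- screen$meta$n_pairs
  counts$pairs_significant <- screen$meta$n_asymmetric
  counts$meta_p_value <- screen$meta$p_value

  ## --- stage: trends --------------------------------------------------
  trend <- NULL
  ok <- sum(is.finite(trip_win$omega_I))
  if (ok >= 3 && length(unique(trip_win$dS_I[is.finite(trip_win$omega_I)])) > 1)
    trend <- fit_trend(trip_win)
  fam_sum <- family_summaries(matrices)

  report <- structure(list(config = config, families = families, qc = qc,
                           matrices = matrices, triplets = trip,
                           triplets_windowed = trip_win, screen = screen,
                           trend = trend, family_summary = fam_sum,
                           counts = counts),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

empty_report <- function(config, counts) {
  counts$families_kept <- counts$families_kept %||% 0L
  counts$pairs_tested <- 0L
  counts$pairs_significant <- 0L
  report <- structure(list(config = config, families = list(), qc = data.frame(),
                           matrices = list(), triplets = data.frame(),
                           triplets_windowed = data.frame(),
                           screen = NULL, trend = NULL,
                           family_summary = data.frame(), counts = counts),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df) || !is.data.frame(df)) return()
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) ifelse(is.finite(col) | is.na(col), col, NA) else col
    })
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  wt(report$qc, "families.tsv")
  if (length(report$matrices))
    wt(do.call(rbind, c(lapply(report$matrices, rates_table),
                        list(make.row.names = FALSE))), "rates.tsv")
  wt(report$triplets, "triplets.tsv")
  wt(report$triplets_windowed, "triplets_windowed.tsv")
  if (!is.null(report$screen)) wt(report$screen$results, "pairs.tsv")
  wt(report$family_summary, "family_summary.tsv")
  ## resolved configuration, verbatim
  cfg <- report$config
  scal <- vapply(cfg, function(x)
    is.atomic(x) && length(x) == 1L && !is.null(x), logical(1))
  kv <- data.frame(key = names(cfg)[scal],
                   value = vapply(cfg[scal], as.character, character(1)))
  utils::write.table(kv, file.path(dir, "config.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cn <- report$counts
  kv2 <- data.frame(key = names(cn), value = vapply(cn, function(x)
    as.character(x %||% NA), character(1)))
  utils::write.table(kv2, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:\n")
  for (k in names(x$counts))
    cat(sprintf("  %-28s %s\n", k, format(x$counts[[k]])))
  if (!is.null(x$trend)) print(x$trend)
  invisible(x)
}

#' Load the packaged fixture of published asymmetric-pair counts
#'
#' Returns the 26 substitution-count pairs (fast copy vs slow copy, with
#' RefSeq identifiers) reported for asymmetrically evolving human paralog
#' pairs, exactly as printed. The loader validates the fixture against
#' frozen checksums (26 rows; count totals 939 and 350; first row 52 and
#' 8).
#'
#' @return data.frame: fast_id, slow_id, x_fast, x_slow, annotation.
#' @export
load_fixture_table1 <- function() {
  path <- system.file("extdata", "asymmetric_pairs_published.tsv",
                      package = "parasym", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) != 26L || sum(df$x_fast) != 939L || sum(df$x_slow) != 350L ||
      df$x_fast[1] != 52L || df$x_slow[1] != 8L)
    stop("asymmetric-pairs fixture failed its checksum")
  df
}

#' Asymmetry screen from precomputed substitution counts
#'
#' Counts-only mode: applies the exact binomial symmetry test to each
#' (x1, x2) row and the binomial meta-test over \code{n_pairs} (the number
#' of pairs the counts were screened from, defaulting to the number of
#' rows).
#'
#' @param counts data.frame with integer columns \code{x1} and \code{x2}
#'   (aliases \code{x_fast}/\code{x_slow} accepted).
#' @param n_pairs total pairs tested (>= nrow(counts)).
#' @param alpha per-pair significance level.
#' @param p_asym meta-test null probability.
#' @param sided "two" or "one".
#' @return list of class \code{"asymmetry_screen"} (without sequence-level
#'   columns).
#' @export
screen_from_counts <- function(counts, n_pairs = nrow(counts), alpha = 0.05,
                               p_asym = 0.05, sided = "two") {
  if (!"x1" %in% names(counts) && "x_fast" %in% names(counts)) {
    counts$x1 <- counts$x_fast
    counts$x2 <- counts$x_slow
  }
  stopifnot(all(c("x1", "x2") %in% names(counts)),
            n_pairs >= nrow(counts))
  p <- mapply(binom_symmetry_test, counts$x1, counts$x2,
              MoreArgs = list(sided = sided))
  results <- data.frame(counts, p_value = p, significant = p < alpha,
                        stringsAsFactors = FALSE)
  n_asym <- sum(results$significant)
  structure(list(results = results,
                 meta = list(n_pairs = n_pairs, n_asymmetric = n_asym,
                             p_asym = p_asym,
                             p_value = meta_test(n_asym, n_pairs, p_asym)),
                 alpha = alpha, channel = "counts", sided = sided),
            class = "asymmetry_screen")
}
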