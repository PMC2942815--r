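## Codon-level gene-family simulator with per-branch control of the
## synonymous rate and of omega (dN/dS), plus an optional one-sided
## acceleration of the non-synonymous rate — the truth-labeled test bed for
## every downstream stage.
##
## Branch lengths are expected synonymous substitutions per synonymous
## site. Candidate single-nucleotide mutations (uniform over positions and
## alternative nucleotides, no ts/tv bias) arrive as a Poisson process whose
## intensity is calibrated so the instantaneous synonymous flux per NG86
## synonymous site equals 1 per unit branch length; a synonymous candidate
## is always accepted, a non-synonymous one with probability omega (times
## accel_factor on the accelerated branch), and stop-creating candidates
## are rejected without consuming branch length. The calibration constant
## is refreshed every `chunk` units of branch length to track compositional
## drift.

#' Simulation configuration for a codon-level gene family
#'
#' @param tree an \code{ape::phylo} rooted tree with named leaves, or a
#'   newick string. Branch lengths are expected synonymous substitutions
#'   per synonymous site. Each branch is named by the node it leads to
#'   (leaf label, or internal label; unlabeled internal nodes get
#'   \code{"nodeN"}).
#' @param omega dN/dS target; a single non-negative number applied to all
#'   branches, or a named vector over branch names.
#' @param accel_branch optional branch name whose non-synonymous acceptance
#'   rate is multiplied by \code{accel_factor}.
#' @param accel_factor real >= 1.
#' @param n_codons number of codons (>= 1).
#' @param root_seq optional explicit root sequence (length \code{3 *
#'   n_codons}, no stop codons); default root is uniform over the 61 sense
#'   codons.
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   full configuration.
#' @param chunk calibration refresh interval in branch-length units.
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(tree, omega = 0.3, accel_branch = NULL,
                       accel_factor = 1, n_codons = 500, root_seq = NULL,
                       seed = 1L, chunk = 0.02) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo or newick string")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (anyDuplicated(tree$tip.label)) stop("leaf names must be unique")
  if (!is.numeric(n_codons) || n_codons < 1) stop("n_codons must be >= 1")
  n_codons <- as.integer(n_codons)
  branches <- branch_names(tree)
  if (length(omega) == 1L && is.null(names(omega)))
    omega <- stats::setNames(rep(as.numeric(omega), length(branches)), branches)
  if (!all(branches %in% names(omega)))
    stop("omega must name every branch: ",
         paste(setdiff(branches, names(omega)), collapse = ", "))
  omega <- omega[branches]
  if (any(omega < 0)) stop("omega must be non-negative")
  if (!is.null(accel_branch) && !accel_branch %in% branches)
    stop("accel_branch '", accel_branch, "' is not a branch of the tree")
  if (accel_factor < 1) stop("accel_factor must be >= 1")
  if (!is.null(root_seq)) {
    root_seq <- toupper(root_seq)
    if (nchar(root_seq) != 3L * n_codons)
      stop("root_seq length must be 3 * n_codons")
    if (grepl("[^ACGT]", root_seq)) stop("root_seq must be A/C/G/T only")
    if (any(is_stop_codon(split_codons(root_seq)) %in% TRUE))
      stop("root_seq contains stop codon(s)")
  }
  structure(list(tree = tree, branches = branches, omega = omega,
                 accel_branch = accel_branch, accel_factor = accel_factor,
                 n_codons = n_codons, root_seq = root_seq,
                 seed = as.integer(seed), chunk = chunk),
            class = "sim_config")
}

# name every edge of a phylo by its child node
branch_names <- function(tree) {
  ntip <- length(tree$tip.label)
  node_lab <- tree$node.label
  if (is.null(node_lab) || !length(node_lab) || all(node_lab == ""))
    node_lab <- paste0("node", seq_len(tree$Nnode))
  child <- tree$edge[, 2]
  out <- character(length(child))
  leaf <- child <= ntip
  out[leaf] <- tree$tip.label[child[leaf]]
  out[!leaf] <- node_lab[child[!leaf] - ntip]
  out
}

#' Simulate a gene family along a tree
#'
#' Evolves the root sequence to every leaf, recording per-branch realized
#' counts of accepted synonymous and non-synonymous codon substitutions.
#' Candidates that would create a stop codon are rejected and do not
#' consume branch length, so all intermediate and leaf sequences remain
#' valid coding sequences.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{"family_truth"}: \code{alignment} (named
#'   character vector of gap-free leaf sequences), \code{branch_counts}
#'   (data.frame: branch, length, omega, accel, syn, nonsyn),
#'   \code{root_seq}, \code{node_seqs} (internal node sequences), and
#'   \code{config}.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tb <- codon_tables()
  withr::with_seed(config$seed, {
    root <- if (is.null(config$root_seq)) {
      tb$sense[sample.int(length(tb$sense), config$n_codons, replace = TRUE)]
    } else {
      unname(tb$index[split_codons(config$root_seq)])
    }
    tree <- config$tree
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    root_node <- ntip + 1L
    seqs[[root_node]] <- root
    counts <- matrix(0L, nrow(tree$edge), 2,
                     dimnames = list(config$branches, c("syn", "nonsyn")))
    ## root-to-leaves: process an edge once its parent sequence exists
    ord <- integer(0)
    done <- rep(FALSE, nrow(tree$edge))
    have <- rep(FALSE, nnode); have[root_node] <- TRUE
    while (!all(done)) {
      ready <- which(!done & have[tree$edge[, 1]])
      if (!length(ready)) stop("tree is not a rooted connected tree")
      ord <- c(ord, ready)
      done[ready] <- TRUE
      have[tree$edge[ready, 2]] <- TRUE
    }
    for (e in ord) {
      par <- tree$edge[e, 1]; chl <- tree$edge[e, 2]
      bname <- config$branches[e]
      om <- config$omega[[bname]]
      if (!is.null(config$accel_branch) && bname == config$accel_branch)
        om <- om * config$accel_factor
      ev <- evolve_branch(seqs[[par]], tree$edge.length[e], om,
                          chunk = config$chunk, tb = tb)
      seqs[[chl]] <- ev$seq
      counts[e, ] <- c(ev$syn, ev$nonsyn)
    }
    codons <- tb$codons
    leaf_seqs <- vapply(seq_len(ntip),
                        function(i) paste(codons[seqs[[i]]], collapse = ""),
                        character(1))
    names(leaf_seqs) <- tree$tip.label
    node_seqs <- vapply((ntip + 1L):nnode,
                        function(i) paste(codons[seqs[[i]]], collapse = ""),
                        character(1))
    names(node_seqs) <- unique_node_labels(tree)
    bc <- data.frame(branch = config$branches,
                     length = tree$edge.length,
                     omega = unname(config$omega[config$branches]),
                     accel = if (is.null(config$accel_branch))
                       rep(FALSE, length(config$branches))
                     else config$branches == config$accel_branch,
                     syn = counts[, "syn"], nonsyn = counts[, "nonsyn"],
                     stringsAsFactors = FALSE, row.names = NULL)
    structure(list(alignment = leaf_seqs, branch_counts = bc,
                   root_seq = paste(codons[root], collapse = ""),
                   node_seqs = node_seqs, config = config),
              class = "family_truth")
  })
}

unique_node_labels <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab) || !length(lab) || all(lab == ""))
    lab <- paste0("node", seq_len(tree$Nnode))
  lab
}

# evolve a codon-index vector along one branch; returns new sequence and
# accepted substitution counts
evolve_branch <- function(seq, len, omega, chunk = 0.02, tb = codon_tables()) {
  syn_count <- 0L; nonsyn_count <- 0L
  n <- length(seq)
  m <- max(1, omega)  # thinning envelope for the non-synonymous class
  remaining <- len
  while (remaining > 1e-12) {
    dt <- min(chunk, remaining)
    remaining <- remaining - dt
    s_sites <- sum(tb$syn_sites[seq])
    n_syn_ch <- sum(tb$n_syn_ch[seq])
    if (n_syn_ch == 0L) break  # no synonymous change possible; degenerate
    beta <- s_sites / n_syn_ch  # per-change synonymous rate for unit dS flux
    lambda <- beta * 9 * n * m * dt
    ncand <- stats::rpois(1L, lambda)
    if (ncand == 0L) next
    cpos <- sample.int(n, ncand, replace = TRUE)
    eidx <- sample.int(9L, ncand, replace = TRUE)
    u <- stats::runif(ncand)
    for (k in seq_len(ncand)) {
      ci <- seq[cpos[k]]
      cls <- tb$nb_class[ci, eidx[k]]
      if (cls == 2L) next                      # stop-creating: rejected
      if (cls == 0L) {
        if (u[k] <= 1 / m) {
          seq[cpos[k]] <- tb$nb_target[ci, eidx[k]]
          syn_count <- syn_count + 1L
        }
      } else if (u[k] <= omega / m) {
        seq[cpos[k]] <- tb$nb_target[ci, eidx[k]]
        nonsyn_count <- nonsyn_count + 1L
      }
    }
  }
  list(seq = seq, syn = syn_count, nonsyn = nonsyn_count)
}

#' @export
print.family_truth <- function(x, ...) {
  cat("family_truth: ", length(x$alignment), " leaves x ",
      x$config$n_codons, " codons; substitutions per branch:\n", sep = "")
  print(x$branch_counts, row.names = FALSE)
  invisible(x)
}

#' Simulate the canonical duplication scenario (gene, sister, cousin)
#'
#' Three-leaf family: a recent duplication at depth \code{pair_depth}
#' produced copies \code{i} and \code{j}; \code{k} is a deeper outgroup
#' paralog at depth \code{outgroup_depth}. The post-duplication branch of
#' \code{i} carries the optional non-synonymous acceleration (the asymmetry
#' signal).
#'
#' @param pair_depth dS depth of the duplication (per post-duplication
#'   branch), 0 < pair_depth < outgroup_depth.
#' @param outgroup_depth dS depth of the outgroup split.
#' @param omega dN/dS on all branches.
#' @param accel_factor acceleration (>= 1) of i's non-synonymous rate.
#' @param n_codons codons per gene.
#' @param seed integer seed.
#' @param ... passed on to \code{\link{sim_config}}.
#' @return a \code{family_truth} with leaves \code{i}, \code{j}, \code{k}.
#' @export
duplication_scenario <- function(pair_depth, outgroup_depth, omega = 0.3,
                                 accel_factor = 1, n_codons = 500,
                                 seed = 1L, ...) {
  if (!(pair_depth > 0)) stop("pair_depth must be > 0")
  if (pair_depth >= outgroup_depth)
    stop("pair_depth must be smaller than outgroup_depth ",
         "(the cousin must be a valid outgroup)")
  nwk <- sprintf("((i:%.10g,j:%.10g)anc:%.10g,k:%.10g)root;",
                 pair_depth, pair_depth,
                 outgroup_depth - pair_depth, outgroup_depth)
  cfg <- sim_config(tree = nwk, omega = omega, accel_branch = "i",
                    accel_factor = accel_factor, n_codons = n_codons,
                    seed = seed, ...)
  simulate_family(cfg)
}

#' Write a simulated family to disk
#'
#' Writes the gap-free alignment as multi-FASTA, the tree as newick, and
#' the branch counts plus configuration as TSV/key-value sidecars.
#'
#' @param truth a \code{family_truth}.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of paths written.
#' @export
write_family <- function(truth, dir, prefix = "family") {
  stopifnot(inherits(truth, "family_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    alignment = file.path(dir, paste0(prefix, ".fasta")),
    tree = file.path(dir, paste0(prefix, ".nwk")),
    branch_counts = file.path(dir, paste0(prefix, "_branch_counts.tsv")),
    config = file.path(dir, paste0(prefix, "_config.tsv")))
  write_codon_fasta(truth$alignment, paths[["alignment"]])
  ape::write.tree(truth$config$tree, paths[["tree"]])
  utils::write.table(truth$branch_counts, paths[["branch_counts"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- truth$config
  kv <- data.frame(
    key = c("n_codons", "seed", "accel_branch", "accel_factor", "chunk",
            paste0("omega.", names(cfg$omega))),
    value = c(cfg$n_codons, cfg$seed,
              if (is.null(cfg$accel_branch)) "." else cfg$accel_branch,
              cfg$accel_factor, cfg$chunk, unname(cfg$omega)),
    stringsAsFactors = FALSE)
  utils::write.table(kv, paths[["config"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
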