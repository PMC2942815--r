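# Codon-level family simulator: determinism, conservation, calibration

test_that("omega = 0 forbids amino-acid change on every branch", {
  cfg <- sim_config("((A:0.2,B:0.2)n1:0.3,C:0.5)r;", omega = 0,
                    n_codons = 200, seed = 3)
  truth <- simulate_family(cfg)
  expect_true(all(truth$branch_counts$nonsyn == 0))
  expect_gt(sum(truth$branch_counts$syn), 0)
  aa <- unique(vapply(truth$alignment, parasym:::translate_cds, character(1)))
  expect_length(aa, 1)  # all leaves encode the same protein
})

test_that("zero branch lengths copy the root to every leaf", {
  cfg <- sim_config("((A:0,B:0)n1:0,C:0)r;", omega = 0.5, n_codons = 150,
                    seed = 8)
  truth <- simulate_family(cfg)
  expect_true(all(truth$alignment == truth$root_seq))
  expect_true(all(truth$branch_counts$syn == 0))
  expect_true(all(truth$branch_counts$nonsyn == 0))
})

test_that("identical configuration reproduces bit-identical output", {
  cfg <- sim_config("((A:0.1,B:0.1)n1:0.2,C:0.4)r;", omega = 0.3,
                    accel_branch = "A", accel_factor = 3, n_codons = 250,
                    seed = 123)
  t1 <- simulate_family(cfg)
  t2 <- simulate_family(cfg)
  expect_identical(t1$alignment, t2$alignment)
  expect_identical(t1$branch_counts, t2$branch_counts)
  t3 <- simulate_family(sim_config("((A:0.1,B:0.1)n1:0.2,C:0.4)r;",
                                   omega = 0.3, accel_branch = "A",
                                   accel_factor = 3, n_codons = 250,
                                   seed = 124))
  expect_false(identical(t1$alignment, t3$alignment))
})

test_that("no sequence ever contains a stop codon", {
  for (seed in 1:5) {
    truth <- duplication_scenario(0.2, 1.5, omega = 0.8, n_codons = 120,
                                  seed = seed)
    for (s in c(truth$alignment, truth$node_seqs, truth$root_seq))
      expect_false(any(is_stop_codon(parasym:::split_codons(s)) %in% TRUE))
  }
})

test_that("leaf-root differences never exceed substitutions on the path", {
  truth <- duplication_scenario(0.3, 1.0, omega = 0.5, n_codons = 200,
                                seed = 21)
  bc <- truth$branch_counts
  root_cod <- parasym:::split_codons(truth$root_seq)
  path_subs <- c(i = sum(bc$syn[bc$branch %in% c("i", "anc")]) +
                   sum(bc$nonsyn[bc$branch %in% c("i", "anc")]),
                 j = sum(bc$syn[bc$branch %in% c("j", "anc")]) +
                   sum(bc$nonsyn[bc$branch %in% c("j", "anc")]),
                 k = sum(bc$syn[bc$branch == "k"]) +
                   sum(bc$nonsyn[bc$branch == "k"]))
  for (leaf in names(truth$alignment)) {
    leaf_cod <- parasym:::split_codons(truth$alignment[[leaf]])
    nt_diff <- sum(parasym:::nt_hamming(root_cod, leaf_cod))
    expect_lte(nt_diff, path_subs[[leaf]])
  }
})

test_that("realized synonymous divergence is calibrated to branch length", {
  # tree ((A:0.1,B:0.1):0.3,C:0.4): A-B synonymous divergence targets 0.2
  reps <- 60
  ds <- vapply(seq_len(reps), function(s) {
    truth <- simulate_family(sim_config("((A:0.1,B:0.1)n1:0.3,C:0.4)r;",
                                        omega = 0.2, n_codons = 2000,
                                        seed = s))
    pairwise_rates(truth$alignment[["A"]], truth$alignment[["B"]])$dS
  }, numeric(1))
  se <- stats::sd(ds) / sqrt(reps)
  expect_lt(abs(mean(ds) - 0.2), 3 * se)
})

test_that("neutral evolution gives a realized dN/dS ratio near 1", {
  truth <- duplication_scenario(0.25, 0.8, omega = 1, n_codons = 6000,
                                seed = 77)
  tb <- parasym:::codon_tables()
  root <- unname(tb$index[parasym:::split_codons(truth$root_seq)])
  S <- sum(tb$syn_sites[root])
  N <- sum(tb$nonsyn_sites[root])
  bc <- truth$branch_counts
  ratio <- (sum(bc$nonsyn) / N) / (sum(bc$syn) / S)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("duplication_scenario validates depths and flags the accelerated branch", {
  expect_error(duplication_scenario(0.5, 0.5, n_codons = 50),
               "outgroup")
  expect_error(duplication_scenario(0, 0.5, n_codons = 50), "pair_depth")
  truth <- duplication_scenario(0.05, 0.4, omega = 0.3, accel_factor = 5,
                                n_codons = 100, seed = 2)
  bc <- truth$branch_counts
  expect_identical(bc$branch[bc$accel], "i")
})

test_that("sim_config rejects invalid inputs", {
  expect_error(sim_config("((A:0.1,B:0.1)n1:0.2,C:0.4)r;", omega = -1,
                          n_codons = 10), "non-negative")
  expect_error(sim_config("((A:0.1,B:0.1)n1:0.2,C:0.4)r;",
                          accel_branch = "Z", n_codons = 10), "accel_branch")
  expect_error(sim_config("((A:0.1,B:0.1)n1:0.2,C:0.4)r;", n_codons = 3,
                          root_seq = "ATGTAAATG"), "stop")
  expect_error(sim_config("((A:0.1,B:0.1)n1:0.2,C:0.4)r;", n_codons = 3,
                          root_seq = "ATGATG"), "3 \\* n_codons")
})

test_that("write_family writes FASTA, newick and sidecars that round-trip", {
  truth <- duplication_scenario(0.1, 0.5, omega = 0.3, n_codons = 60,
                                seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_family(truth, dir, prefix = "t")
  expect_true(all(file.exists(paths)))
  aln <- read_codon_fasta(paths[["alignment"]])
  expect_identical(aln[names(truth$alignment)], truth$alignment)
  tre <- ape::read.tree(paths[["tree"]])
  expect_setequal(tre$tip.label, c("i", "j", "k"))
  bc <- read.delim(paths[["branch_counts"]])
  expect_identical(sort(bc$branch), sort(truth$branch_counts$branch))
})
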