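# Asymmetry detection: best pairs, parsimony assignment, binomial tests

test_that("bidirectional best pairs require mutual sisters and a cousin", {
  m <- toy_matrix(sym_ds(c("i", "j", "k"), ij = 0.1, ik = 0.5, jk = 0.6))
  bp <- bidirectional_best_pairs(m)
  expect_equal(nrow(bp), 1)
  expect_identical(bp$gene_a, "i")
  expect_identical(bp$gene_b, "j")
  expect_identical(bp$cousin, "k")

  # a's sister is b but b's sister is c: a stays unpaired
  m2 <- toy_matrix(sym_ds(c("a", "b", "c", "d"),
                          ab = 0.3, bc = 0.2, ac = 0.6, ad = 0.9,
                          bd = 0.95, cd = 0.9))
  bp2 <- bidirectional_best_pairs(m2)
  expect_false("a" %in% c(bp2$gene_a, bp2$gene_b))

  # cousin tie on the dS sum breaks to the lexicographically smaller id
  m3 <- toy_matrix(sym_ds(c("i", "j", "x", "y"),
                          ij = 0.1, ix = 0.4, jx = 0.5,
                          iy = 0.4, jy = 0.5, xy = 0.2))
  bp3 <- bidirectional_best_pairs(m3)
  expect_identical(bp3$cousin[bp3$gene_a == "i"], "x")
})

test_that("outgroup parsimony assigns substitutions to the changed lineage", {
  # proteins: a = MKV, b = MRV, c = MRV -> the change is on a's lineage
  a <- paste(codons_for("MKV"), collapse = "")
  b <- paste(codons_for("MRV"), collapse = "")
  cc <- paste(codons_for("MRV"), collapse = "")
  asg <- assign_substitutions(a, b, cc, channel = "aa")
  expect_equal(asg$x1, 1)
  expect_equal(asg$x2, 0)
  expect_equal(asg$excluded_all_differ, 0)

  # all three differ: position excluded
  asg2 <- assign_substitutions(a, b, paste(codons_for("MSV"), collapse = ""),
                               channel = "aa")
  expect_equal(asg2$x1 + asg2$x2, 0)
  expect_equal(asg2$excluded_all_differ, 1)

  # outgroup equals a: change assigned to b
  asg3 <- assign_substitutions(a, b, a, channel = "aa")
  expect_equal(asg3$x2, 1)

  # gapped codon excluded separately
  ag <- sub("^...", "---", a)
  asg4 <- assign_substitutions(ag, b, cc, channel = "aa")
  expect_equal(asg4$excluded_gap, 1)
})

test_that("synonymous channel only counts amino-acid-conserved codons", {
  # codon 1: CTT/CTC/CTT all Leu; b carries the synonymous change
  # codon 2: AAA vs AGA vs AAA (Lys vs Arg): not conserved, excluded
  a <- "CTTAAA"; b <- "CTCAGA"; cc <- "CTTAAA"
  asg <- assign_substitutions(a, b, cc, channel = "syn")
  expect_equal(asg$x2, 1)
  expect_equal(asg$x1, 0)
  expect_equal(asg$excluded_nonconserved, 1)
})

test_that("accelerated branch inflates its own substitution count", {
  x1s <- x2s <- numeric(25)
  for (s in 1:25) {
    truth <- duplication_scenario(0.06, 0.4, omega = 0.4, accel_factor = 4,
                                  n_codons = 600, seed = 700 + s)
    asg <- assign_substitutions(truth$alignment[["i"]],
                                truth$alignment[["j"]],
                                truth$alignment[["k"]], channel = "aa")
    x1s[s] <- asg$x1; x2s[s] <- asg$x2
  }
  expect_gt(mean(x1s), 2 * mean(x2s))  # i (x1) carries the acceleration
})

test_that("binomial symmetry test: exact values, symmetry, monotone tails", {
  expect_equal(binom_symmetry_test(7, 7), 1)
  expect_equal(binom_symmetry_test(0, 0), 1)
  expect_equal(binom_symmetry_test(29, 1), 62 / 2^30, tolerance = 1e-12)
  expect_lt(binom_symmetry_test(52, 8), 0.05)
  expect_equal(binom_symmetry_test(3, 12), binom_symmetry_test(12, 3))
  # p decreases as the split grows more extreme at fixed total
  p_seq <- vapply(15:25, function(x1)
    binom_symmetry_test(x1, 30 - x1), numeric(1))
  expect_true(all(diff(p_seq) < 0))
  # one-sided is half the (uncapped) two-sided value
  expect_equal(binom_symmetry_test(20, 8, sided = "one") * 2,
               binom_symmetry_test(20, 8))
  expect_error(binom_symmetry_test(-1, 2), "non-negative")
})

test_that("meta-test matches closed forms and the distribution oracle", {
  expect_equal(meta_test(0, 144), 1)
  expect_equal(meta_test(144, 144), 0.05^144)
  # agreement with pbinom to >= 10 significant digits up to n = 10^4
  cases <- rbind(c(26, 144), c(9, 144), c(1, 10), c(300, 10000),
                 c(520, 10000), c(5, 10000))
  for (r in seq_len(nrow(cases))) {
    k <- cases[r, 1]; n <- cases[r, 2]
    ref <- stats::pbinom(k - 1, n, 0.05, lower.tail = FALSE)
    expect_lt(abs(meta_test(k, n) - ref) / ref, 1e-10)
  }
  expect_error(meta_test(5, 4), "n_asymmetric")
  expect_error(meta_test(2, 10, p_asym = 0), "p_asym")
})

test_that("screen flags the expected pairs on simulated families", {
  fams <- lapply(1:6, function(s)
    duplication_scenario(0.06, 0.45, omega = 0.4,
                         accel_factor = if (s <= 3) 8 else 1,
                         n_codons = 800, seed = 900 + s)$alignment)
  names(fams) <- paste0("fam", 1:6)
  scr <- run_asymmetry_screen(fams)
  expect_equal(scr$meta$n_pairs, 6)
  accel_sig <- scr$results$significant[scr$results$family %in%
                                         paste0("fam", 1:3)]
  expect_true(all(accel_sig))  # 8x acceleration is unmistakable
  expect_identical(nrow(scr$results), 6L)
})

test_that("all-identical family yields no testable pairs", {
  fam <- list(f = c(a = "ATGAAAGTT", b = "ATGAAAGTT", c = "ATGAAAGTT"))
  scr <- run_asymmetry_screen(fam)
  expect_equal(scr$meta$n_pairs, 0)
  expect_true(is.na(scr$meta$p_value))
})
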