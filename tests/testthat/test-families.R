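# Family building: similarity links, single-linkage clustering, filters

test_that("pairwise_similarity: self-identity, symmetry, random background", {
  truth <- duplication_scenario(0.1, 0.4, omega = 0.3, n_codons = 120,
                                seed = 13)
  a <- truth$alignment[["i"]]
  b <- truth$alignment[["j"]]
  self <- pairwise_similarity(a, a)
  expect_equal(self$identity_fraction, 1)
  expect_equal(self$coverage_fraction, 1)

  ab <- pairwise_similarity(a, b, "i", "j")
  ba <- pairwise_similarity(b, a, "j", "i")
  expect_equal(ab$identity_fraction, ba$identity_fraction, tolerance = 1e-9)
  expect_gt(ab$identity_fraction, 0.75)

  # unrelated random coding sequences: identity near the 0.25 background
  set.seed(99)
  tb <- parasym:::codon_tables()
  rand_seq <- function() paste(tb$codons[tb$sense][
    sample.int(61, 150, replace = TRUE)], collapse = "")
  idents <- replicate(25, {
    pairwise_similarity(rand_seq(), rand_seq())$identity_fraction
  })
  expect_gt(mean(idents), 0.15)
  expect_lt(mean(idents), 0.45)
})

test_that("single-linkage groups by transitivity and matches the oracle", {
  links <- data.frame(id_a = c("A", "B", "A"), id_b = c("B", "C", "C"),
                      identity_fraction = c(0.8, 0.8, 0.3),
                      coverage_fraction = 1)
  memb <- single_linkage_cluster(links)
  expect_length(unique(memb), 1)  # chain A-B-C is one group

  none <- single_linkage_cluster(transform(links, identity_fraction = 0.5))
  expect_length(unique(none), 3)  # all singletons

  # random instances against the exhaustive merge oracle
  set.seed(42)
  for (rep in 1:10) {
    ids <- paste0("g", 1:12)
    n_edges <- 18
    ed <- data.frame(id_a = sample(ids, n_edges, TRUE),
                     id_b = sample(ids, n_edges, TRUE),
                     identity_fraction = runif(n_edges, 0.5, 1),
                     coverage_fraction = runif(n_edges, 0, 1))
    ed <- ed[ed$id_a != ed$id_b, ]
    got <- single_linkage_cluster(ed, ids = ids)
    pass <- ed[ed$identity_fraction >= 0.75 & ed$coverage_fraction >= 0.20, ]
    expect_identical(got, oracle_components(ids, pass))
    # invariant to input order
    shuf <- ed[sample(nrow(ed)), ]
    expect_identical(single_linkage_cluster(shuf, ids = ids), got)
  }
})

test_that("filter_family applies the identity window", {
  same <- c(a = "ATGAAAGTTGCT", b = "ATGAAAGTTGCT", c = "ATGAAAGTTGCT")
  res <- filter_family(same)
  expect_s3_class(res, "family_rejection")
  expect_match(res$reason, "above")

  # three related simulated paralogs sit inside (25%, 98%)
  truth <- duplication_scenario(0.3, 1.2, omega = 0.5, n_codons = 150,
                                seed = 31)
  fam <- filter_family(truth$alignment)
  expect_s3_class(fam, "gene_family")
  expect_gte(fam$qc$identity, 0.25)
  expect_lte(fam$qc$identity, 0.98)

  # filtering an accepted family again changes nothing (idempotence)
  again <- filter_family(fam$alignment)
  expect_s3_class(again, "gene_family")
  expect_identical(again$members, fam$members)
  expect_identical(again$alignment, fam$alignment)
  expect_equal(again$qc$identity, fam$qc$identity)
})

test_that("a gene diverging > 80% from all others is removed, rest kept", {
  truth <- duplication_scenario(0.15, 0.6, omega = 0.4, n_codons = 200,
                                seed = 17)
  aln <- truth$alignment
  # outlier: permute every nucleotide of member i (A->C, C->A, G->T, T->G),
  # guaranteeing ~100% divergence from i and far > 80% from its relatives
  outlier <- chartr("ACGT", "CATG", aln[["i"]])
  aln <- c(aln, z_outlier = outlier)
  # oracle: recompute mean pairwise divergence by hand
  mat <- do.call(rbind, strsplit(aln, ""))
  div_z <- mean(vapply(1:3, function(i)
    mean(mat[4, ] != mat[i, ]), numeric(1)))
  expect_gt(div_z, 0.80)
  fam <- filter_family(aln, min_size = 3)
  expect_s3_class(fam, "gene_family")
  expect_identical(fam$qc$removed, "z_outlier")
  expect_setequal(fam$members, c("i", "j", "k"))
})

test_that("build_families separates unrelated simulated families", {
  t1 <- duplication_scenario(0.08, 0.2, omega = 0.3, n_codons = 150, seed = 61)
  t2 <- duplication_scenario(0.1, 0.25, omega = 0.3, n_codons = 150, seed = 62)
  seqs <- c(stats::setNames(t1$alignment, paste0("f1_", names(t1$alignment))),
            stats::setNames(t2$alignment, paste0("f2_", names(t2$alignment))))
  fb <- build_families(seqs)
  expect_length(fb$families, 2)
  members <- lapply(fb$families, `[[`, "members")
  grouped <- vapply(members, function(m)
    length(unique(substr(m, 1, 2))), integer(1))
  expect_true(all(grouped == 1))  # no mixing across families
})
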