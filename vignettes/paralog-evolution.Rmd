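---
title: "Individual rates and asymmetric evolution of recently duplicated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual rates and asymmetric evolution of recently duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parasym)
```

## The scientific question

When a gene duplicates, the two copies initially experience relaxed
purifying selection; over time most surviving copies come back under
strong constraint, and in a substantial fraction of pairs one copy
evolves much faster than the other. `parasym` implements the full
desk-scale analysis chain for studying these two phenomena in paralogous
gene families built from in-frame coding sequences:

1. **Families** — genes are linked when a global amino-acid alignment
   back-projected to nucleotides shows at least 75% identity over at
   least 20% of their average length; single-linkage clustering forms
   groups, which are then filtered (family identity within 25–98%,
   genes more than 80% divergent removed, at least 3 members).
2. **Rates** — all pairwise dN and dS values inside a family by
   Nei–Gojobori (1986) counting with Jukes–Cantor correction.
3. **Triplets** — for each gene \(i\), its *sister* \(j\) (closest
   paralog by dS within the window \(0.01 \le dS \le 3\)) and *cousin*
   \(k\) (outgroup: \(dS_{ik} > dS_{ij}\) and \(dS_{jk} > dS_{ij}\));
   the individual rate of \(i\) by the three-point decomposition
   \[
     d_I(i) = \frac{d_{ij} + d_{ik} - d_{jk}}{2},
   \]
   applied separately to dN and dS, with the analysis window
   \(0.005 \le dS_I \le 0.6\) for recent duplications.
4. **Asymmetry** — bidirectional best paralog pairs (each is the
   other's sister) with their closest cousin as outgroup; every
   divergent position where the outgroup agrees with one copy is a
   substitution assigned to the *other* copy; the conditional law
   \(X_1 \mid X_1+X_2 = n \sim \mathrm{Bin}(n, 1/2)\) under symmetric
   (Poisson) accumulation gives an exact per-pair test, and a binomial
   meta-test \(P(X \ge k \mid n, p = 0.05)\) asks whether the number of
   significant pairs exceeds chance.
5. **Trends** — OLS regression of \(\omega_I = dN_I/dS_I\) on
   \(dS_I\); a negative slope means purifying selection strengthens
   with time since duplication.

Every stage is validated against a built-in codon-level simulator with
known per-branch rates, so each estimator can be checked against truth
rather than only against itself.

## The simulator: a stated world

`simulate_family()` evolves a root sequence (uniform over the 61 sense
codons by default) along a rooted tree whose branch lengths are
*expected synonymous substitutions per synonymous site*. Candidate
single-nucleotide mutations are uniform over positions and alternative
nucleotides (no transition/transversion bias — a documented extension
point). A synonymous candidate is always accepted; a non-synonymous one
with probability \(\omega\) (times `accel_factor` on one designated
post-duplication branch — the asymmetry signal); a candidate creating a
stop codon is rejected without consuming branch length, so all
sequences remain valid CDS. The candidate intensity is calibrated so
the instantaneous synonymous flux per NG86 synonymous site equals one
per unit branch length; the calibration constant is refreshed every
0.02 branch-length units (`chunk`) to track compositional drift. With
this acceptance–rejection construction the expected dS of a branch
equals its length *by design*, which is exactly what the downstream
counting statistics need — no particular codon model (GY94 etc.) is
claimed. Monte-Carlo checks in the test suite confirm calibration
(mean NG86 dS between two depth-0.1 leaves within 3 standard errors of
0.2 over 60 replicates) and near-neutrality of the realized
non-synonymous/synonymous flux ratio at \(\omega = 1\) (within a
0.9–1.1 band; exact unity is not expected because stop-adjacent changes
are excluded asymmetrically from the two site classes).

What the simulator does **not** emulate: indels, recombination, gene
conversion, rate heterogeneity among sites or codons, codon-usage bias
and alternative genetic codes. A green simulation test therefore
establishes the correctness of the estimators under a clean
substitution process, not robustness to alignment error or conversion
tracts in real data.

```{r sim-example}
truth <- duplication_scenario(pair_depth = 0.1, outgroup_depth = 0.5,
                              omega = 0.3, accel_factor = 1,
                              n_codons = 1000, seed = 42)
truth$branch_counts
```

## Parameters that matter

| parameter | default | units / domain | why this value |
|---|---|---|---|
| link identity / coverage | 0.75 / 0.20 | fraction | published family-linking rule |
| family identity window | 0.25–0.98 | fraction of unanimous columns | published filter; 0.98 removes near-identical (too-recent) families |
| divergence removal | 0.80 | mean pairwise nt divergence | published single-gene filter |
| family minimum size | 3 | genes | an outgroup paralog must exist |
| sister window | dS in [0.01, 3] | subs/site | avoids allelic near-duplicates and saturated pairs |
| individual-rate window | dS\_I in [0.005, 0.6] | subs/site | restricts to recent duplications; removes negative (non-additive) values |
| per-pair alpha, meta p | 0.05 / 0.05 | probability | published test levels |
| substitution floor | 100 | nt differences to sister | published robustness control for discrete counts |
| simulator `chunk` | 0.02 | dS units | calibration refresh; small enough that drift within a chunk is negligible |

Both ends of every interval are inclusive ("between x and y" read
inclusively; the choice is asserted in tests).

## Numerical and convention choices

* **NG86 details.** Synonymous site counts use per-position
  denominators reduced by stop-producing changes; multi-position codon
  differences are averaged over the \(d!\) step orderings, discarding
  orderings through stop codons and renormalizing. If *every* ordering
  passes through a stop (possible for a handful of codon pairs), the
  differences are counted as non-synonymous and a warning is emitted.
  The full 61×61 table is checked against an independent brute-force
  path enumerator in the acceptance suite.
* **Saturation.** \(p_S\) or \(p_N \ge 3/4\) makes the Jukes–Cantor
  distance undefined; such pairs carry `saturated = TRUE` and distance
  `Inf`, and every downstream selection skips them (equivalently,
  treats them as dS > 3). Imported external tables flag dS > 3 the
  same way.
* **Ties.** Sister and cousin ties break to the lexicographically
  smaller gene id — determinism over any biological claim.
* **Negative individual rates** (non-additive distance noise) are kept
  and flagged `nonadditive`; the [0.005, 0.6] window then removes them,
  which is how the published window implicitly behaved.
* **Sidedness.** The per-pair binomial test is two-sided by doubling
  the smaller tail and capping at one (the original description does
  not state sidedness; all 26 published count pairs are significant
  under this stricter choice, so the reproduction does not hinge on
  it). A one-sided variant is available via `sided = "one"`.
* **Synonymous channel.** No published definition exists for assigning
  *synonymous* substitutions by parsimony; the convention here
  considers only nucleotide columns inside codons whose translation is
  identical across gene, sister and cousin, so that every assigned
  change is synonymous by construction. Codons not amino-acid-conserved
  across the triplet are excluded from this channel (tracked
  separately from gap and all-three-differ exclusions).
* **Family \(\omega\)** is the ratio of the family's average dN to its
  average dS (`ratio-of-means`), matching the definition of family dN
  and dS as pairwise averages; `mean-of-ratios` is available behind a
  flag because the source is ambiguous.
* **Filter order in `filter_family`**: divergent genes are removed
  first (most divergent first, statistics recomputed after each
  removal), then the identity window is applied to the surviving
  family. Removal-first can rescue a family whose identity was dragged
  out of range by one outlier; the published procedure does not state
  an order. Filtering is idempotent on accepted families (asserted).
* **Alignment.** Family discovery replaces the original genome-scale
  masking/BLAST stages with direct global amino-acid alignments
  (Needleman–Wunsch, BLOSUM62) back-projected to codons; multiple
  alignment of discovered groups uses mafft on translations,
  back-projected, with equal-length inputs (e.g. simulator output)
  taken as already aligned. Equivalence to the original mRNA-level 75%
  rule is approximate by construction.

## Design of the statistical acceptance checks

The genome-wide numbers printed for the original human dataset (97
families, 511/446 genes, mean individual dS 0.18, regression slope
−1.37) depend on a 2010 RefSeq snapshot and external tools and are not
reproducible at desk scale. The package instead proves its machinery on
truth-labeled simulations:

* **Type-I calibration.** 400 symmetric duplication families
  (\(\omega = 0.3\), pair depth 0.05, outgroup 0.5, 1000 codons) run
  through the full screen; the rejection count at \(\alpha = 0.05\)
  must fall in the exact binomial 99% band. The exact test is slightly
  conservative at realistic substitution counts (actual size ≈ 0.03–
  0.04), which the band accommodates.
* **Power monotonicity.** The same setting with acceleration factors
  1, 2, 5, 10. Power saturates at 1 beyond ~5×, so adjacent levels are
  required to be non-decreasing within Monte-Carlo tolerance and the
  grid strictly increasing end to end.
* **Parameter recovery.** Individual dS of the accelerated-lineage
  gene over 200 replicates is unbiased for the true post-duplication
  branch length (0.05) within three standard errors.
* **Trend recovery.** Families are simulated with a known linear rule
  \(\omega(t) = 0.65 - 0.8\,t\) in the duplication depth \(t\), and
  `fit_trend`'s 95% CI must cover −0.8 in at least 90 of 100
  replicates. The regime (depths 0.1–0.4, outgroup at depth + 0.1,
  8000 codons, 20 points per fit) is chosen so the regressor's
  measurement noise is far below its spread — the condition under
  which the OLS coverage property applies. This matters because
  \(\omega_I = dN_I / dS_I\) shares its noisy denominator with the
  regressor \(dS_I\): at short genes, small depths, or distant cousins
  (where the Jukes–Cantor correction amplifies variance) this
  errors-in-variables coupling biases the slope downward and coverage
  degrades well below nominal. That artifact is intrinsic to
  regressing a ratio on its own denominator and is a known caveat for
  dN/dS-versus-dS regressions generally; see Limitations.

## Worked example

```{r pipeline}
fams <- lapply(1:6, function(i)
  duplication_scenario(pair_depth = 0.04 + 0.02 * i, outgroup_depth = 0.5,
                       omega = 0.35, accel_factor = if (i <= 2) 5 else 1,
                       n_codons = 600, seed = 100 + i)$alignment)
names(fams) <- paste0("fam", 1:6)

report <- run_pipeline(run_config(prealigned = TRUE), seqs = fams)
report
report$screen$results[, c("family", "x1", "x2", "p_value", "significant")]
```

The two accelerated families (fam1, fam2) are strongly significant;
most symmetric families stay near a 50:50 substitution split, but one
(fam5, 39:17) is a chance rejection — with several pairs tested at
\(\alpha = 0.05\) occasional false positives are expected, which is
precisely why the genome-scale claim rests on the binomial meta-test
rather than on any single pair. The same screen applied to the
packaged table of published substitution counts:

```{r fixture}
scr <- screen_from_counts(load_fixture_table1(), n_pairs = 144)
scr
```

## Limitations

* NG86 counting with Jukes–Cantor correction replaces the original
  maximum-likelihood (codeml) pairwise estimates. Slopes and
  window-boundary decisions can shift slightly relative to an
  ML-estimated dataset; `import_rates()` accepts an externally
  computed pairwise table to reproduce the original estimator exactly.
* Individual-rate estimates inherit the variance of the cousin
  distances; beyond dS ≈ 1 to the cousin this noise grows quickly, and
  regressions of \(\omega_I\) on \(dS_I\) carry the ratio-denominator
  bias described above. Conclusions drawn from such regressions on
  real data deserve the same caution.
* Family discovery from coding sequences only approximates mRNA-level
  identity linking; repeat masking, manual curation and pseudogene
  removal are out of scope.
* The simulator's clean substitution process cannot certify behavior
  under gene conversion, indels, or alignment error.
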