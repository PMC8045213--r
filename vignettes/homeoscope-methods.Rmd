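---
title: "Models and methods behind homeoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind homeoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`homeoscope` analyses gene expression in allotetraploids relative to their
two diploid progenitors: which ortholog families are expressed where, how
total expression is inherited, and how the two parental gene copies
(homeologs) divide the work inside the polyploid. This vignette documents
the statistical models, the thresholds and their defaults, the design
decisions taken where several readings were defensible, and what the
synthetic-data generator does and does not emulate.

## Setting and notation

Two diploids — S, the maternal-type parent, and C, the paternal-type — and
one or two allotetraploids (T1, T2) formed from them. Each accession ×
tissue group has at least two (by default three) biological replicates.
Ortholog families link each species' own unigene ids; diagnostic SNPs are
positions where the two parental genomes carry fixed, different alleles, so
a tetraploid sequencing fragment covering such positions can be attributed
to one subgenome.

Per homeolog pair, relative homeolog expression is
`Rh = log2(C-homeolog / S-homeolog)` and the parental ortholog ratio is
`Rp = log2(C / S)`; `Rh > 0` means the C copy is more expressed, and
`Rh − Rp` measures departure from parental legacy (bias toward C when
positive).

## Quantification and filtering

* **FPKM** is `count / ((library_total/1e6) × (length/1e3))`, with the
  library total taken as the column sum of the count matrix.
* **Expressed** means mean FPKM across the group's replicates strictly
  greater than 1 *and* unigene length at least 200 bp. Whether the
  expression cutoff should apply per replicate or to the replicate mean is
  interpretive; the mean is used because expression level is defined as the
  replicate average throughout, and the choice is centralized in
  `call_expressed()` (`fpkm_expressed`, `min_gene_length_bp` in the config).
* **Family-level expression** uses any-member semantics — a family is
  expressed in an accession when at least one of its member genes for that
  species is — because copy numbers legitimately differ among species.
* **Coexpression gate**: only families expressed in the tetraploid and both
  parents (per tissue) enter the inheritance analysis; the specificity
  module reports every Venn region of the remaining families, including the
  parents-only region that bounds gene silencing or loss at the whole-gene
  level.
* **Replicate QC** computes Pearson correlation on `log2(FPKM + 1)` within
  each accession and flags within-tissue pairs falling below the
  between-tissue maximum. Pearson on logged values is a choice — the
  statistic is not dictated by the analysis, and Spearman behaves
  equivalently at these depths.

## Normalization

Library scaling uses the trimmed mean of M-values (TMM). Against a
reference library (the one whose upper-quartile count proportion is closest
to the mean — the conventional choice), per-gene log2 ratios M and average
log2 abundances A are computed over genes nonzero in both libraries, the
extremes are double-trimmed (30% on M, 5% on A), and the factor is the
precision-weighted mean of the retained M values (weights from the
binomial variance approximation). Factors are rescaled to geometric mean 1;
effective library size = raw size × factor. Cross-species contrasts run TMM
on the family-paired count matrix, which is the standard way to make
libraries of different species comparable through their orthologs.

## Differential expression

The two-group test is an exact conditional negative-binomial test. Counts
are made comparable by proportional rescaling to the geometric-mean library
size; replicate sums per group are then NB distributed with size `n/φ`
(sums of n iid NB(μ, φ) variables), and conditioning on the gene's total
removes the mean. The two-sided p-value sums the probabilities of all
splits as likely or less likely than the observed one (ties included up to
a relative 1e-12). At `φ = 0` the conditional law is exactly binomial, which
the tests exploit as an independent oracle.

The common dispersion φ maximizes the summed conditional log-likelihood
over genes, on library-equalized counts, with φ clamped to [0, 10]. The
equalization is a deliberate simplification: a proportional rescale rather
than an iterative quantile adjustment. On data with modest (±20%) library
spread the two agree well within the ±25% accuracy the recovery tests
demand, and the simpler form has no tuning state. A pooled
method-of-moments estimator (`dispersion_mom()`) is provided as a
cross-check; the suite asserts the two agree on clean simulated data.
Tagwise/moderated dispersion is deliberately out of scope: with three
replicates the common-dispersion exact test is the classic small-sample
choice.

Fold changes are computed on library-equalized group means with a 0.5
pseudo-count per group, keeping them finite for zero groups. Calls are
ternary: `up` needs `log2FC > 1` and `FDR < 0.05` (plus `P < 0.05` for the
homeolog-level variant only, where that extra gate is configured); `down`
symmetric; otherwise `equal`. BH adjustment is the standard step-up,
applied within one contrast at a time (T vs S, T vs C, S vs C each form
their own family; the choice of family is logged because it is a
convention, not a derivation).

## Inheritance classification

The three ternary calls map through a total decision table of the 27
triples: all-equal is *conserved*; the tetraploid strictly between
differing parents is *intermediate* (states I, XII); equal to one parent
and different from the other with parents differing is expression-level
dominance toward S (IV, IX) or C (II, XI); above or below both parents is
transgressive up (V, VI, VIII) or down (III, VII, X). The 14 remaining
triples are statistically inconsistent (e.g. `T = S`, `T = C`, `S > C`) and
are reported as *unassigned*, never folded into conserved. Roman numerals
are stable internal labels for the states inside each group; all reported
statistics are at the group level, so no reported number depends on which
numeral names which within-group configuration. Percentages use all
classified (coexpressed) families as the denominator, conserved included.

## Homeolog partitioning

A fragment is S-type if every base it shows matches the S allele at its
diagnostic positions, C-type if every base matches C, and ambiguous
otherwise — both for conflicting sites and for bases matching neither
parent, which models sequencing error without needing a quality model.
Per (unigene, sample, parent), each diagnostic SNP is covered by some
number of that parent's fragments and the homeolog count is the **mean** of
these per-SNP counts over the unigene's SNPs. The source procedure is
ambiguous between per-fragment and per-gene averaging; the per-gene mean
over SNPs is implemented, and a `sum` mode is exposed for sensitivity
analysis. Averaging makes counts non-integer; the exact tests round to the
nearest integer. Genes need ≥ 1 diagnostic SNP to be testable; no coverage
floor is imposed beyond that.

A pair is *testable* when both replicate-summed homeolog counts are
nonzero. A homeolog is *silent/lost* when its count is zero in **all**
replicates of the tissue while the partner homeolog shows expression and
the corresponding diploid ortholog is expressed; percentages use testable
genes (both diploid orthologs expressed, ≥ 1 homeolog observed) as the
denominator. The all-zero rule means silent calls are coverage-dependent:
at shallow depth a weakly expressed minor homeolog can be all-zero by
chance, inflating the silent tally — visible in the small demo run, and the
reason the recovery tests use deep simulated libraries.

## Homeolog bias

Homeolog DE contrasts the S- and C-homeolog replicate counts with the exact
test under equal library sizes — both homeologs come from the same
libraries, so within-sample ratios need no normalization. The bias test
asks whether the homeolog ratio departs from the parental ratio: one
Fisher's exact test per gene on
`[[C-homeolog, S-homeolog], [C-parent, S-parent]]` with replicate-summed
homeolog counts and replicate-summed TMM-normalized parental counts
(rounded). Two-sided p-values use the probability method over the
hypergeometric support. The fold-change gate is interpreted as
`|Rh − Rp| > 1`; with the table as constructed this is identical to gating
the table's log2 odds ratio, so the two candidate readings coincide.
Direction follows the sign of `Rh − Rp`. BH families are all tested pairs
per tetraploid × tissue, matching the DE convention; gates are
`FDR < 0.01`, `P < 0.05`.

Fisher's test assumes the split carries only counting noise. Gene-level
biological dispersion therefore makes it anti-conservative for the
*parental* margin, which comes from different individuals; the fold-change
gate is what keeps the false-call rate low, and the all-null simulation in
the test suite checks exactly that. The integration step cross-tabulates
homeolog DE against bias class with marginals and within-row percentages.

## The synthetic-data generator

`simulate_dataset()` draws, per ortholog family: a log-normal baseline
mean; an inheritance category (fractions configurable, remainder
conserved); parental and tetraploid means constructed so that every
"different" relation in the category has effect size `effect_log2fc`
(default 2, comfortably beyond the calling threshold of 1 — intermediate
genes get parents 2× that apart so the tetraploid can sit a full effect
away from both); a homeolog fate (S-bias, C-bias, silent-S, silent-C, or
parental legacy) with the homeolog ratio set to the parental ratio times
`2^(±bias_effect)`; and a proper accession subset for species-specific
families. Replicate counts are negative-binomial with common dispersion φ
(variance `μ + φμ²`; φ = 0 degenerates to Poisson), per-sample library
factors jittered ±20%, and a shared per-(gene, tissue) multiplier creating
the within-tissue vs between-tissue correlation structure the QC checks.

Fragments are generated from the tetraploid totals: the biological
replicate noise hits the gene's total, and each fragment's parental origin
is then sampled in proportion to the homeolog means, so the within-sample
S:C split is binomial given the total — origin assignment is a per-read
process, not a second biological variable. Each fragment spans 1–2 adjacent
diagnostic SNPs (SNPs per gene Poisson with mean 3, minimum 1) and carries
its origin's alleles; a small fraction (default 1%) is corrupted into the
ambiguous class. `fragment_site_fraction` (default 0.2) sets expected
SNP-informative coverage relative to the gene's expression, emulating that
most reads do not overlap a diagnostic site.

Default fractions mirror the study system's reported asymmetries: ~70%
conserved with dominance groups summing to ~15% and S-dominance above
C-dominance; more transgressive down than up; S-bias (14%) above C-bias
(7%); silent-S 3.5% below silent-C 5%. The generator emits a truth table
(category, bias class, silent flags, homeolog ratio, expressed accessions)
consistent with the generating means, and identical seeds give identical
datasets.

What it does **not** emulate: isoforms, positional/GC bias, mapping or
assembly artifacts, population differentiation between the two C
populations, correlated multi-tissue regulation beyond the shared
multiplier, and genuinely variable per-gene dispersions. Passing recovery
tests therefore demonstrate that the estimators are consistent under the
model the analysis assumes — not that real libraries satisfy that model.

## Numerical choices and degenerate inputs

* Exact-test tie tolerance: outcomes with probability within a relative
  1e-12 (NB test) or 1e-7 (Fisher, the convention shared with the standard
  implementations) of the observed one count as ties and are included.
* Zero totals give p = 1 by convention; all-zero libraries, zero-length
  genes and single-replicate groups are errors, not warnings.
* φ is clamped to [0, 10]; the Poisson limit is preferred whenever it is at
  least as likely as the interior optimum, so constant genes yield exactly 0.
* Homeolog counts are rounded only at the exact-test boundary; Rh/Rp use
  the unrounded values.
* TMM factors for a two-library pair with no doubly-nonzero genes fall back
  to 1.

## Problem sizes

The recovery and null-control tests run at 2,000–5,000 families with three
replicates — large enough that binomial sampling error on a 5% class is
under one percentage point, small enough that the whole suite and the
acceptance script each run in a few minutes on one core. The packaged demo
(`demo_scenario()`) uses 300 families across the full two-tetraploid,
two-population, two-tissue design purely as living documentation and a
determinism check.

## Known limitations

* Fisher's bias test inherits the anti-conservativeness discussed above;
  interpret bias percentages jointly with the null-control rate.
* Silent/lost percentages are coverage-dependent by construction.
* The per-gene-mean reading of multi-SNP averaging is one of two defensible
  readings of the source procedure; the `sum` mode exists to check that
  conclusions do not hinge on it.
* Cross-species DE rests on ortholog pairing and TMM over paired families;
  families with divergent copy numbers strain the one-to-one assumption.
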