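test_that("FPKM follows its closed form and is linear in counts", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 500, 2e6), 0)
  expect_equal(compute_fpkm(10, 2000, 1e7), 0.5)
  expect_error(compute_fpkm(5, 0, 1e6), "gene length")
  # linearity at fixed library size
  expect_equal(compute_fpkm(84, 1234, 5e6), 2 * compute_fpkm(42, 1234, 5e6))
})

test_that("TMM factors are 1 for identical or proportional libraries and are
           invariant to global rescaling", {
  set.seed(1)
  base <- matrix(rnbinom(2000, mu = 100, size = 5), ncol = 2)
  rownames(base) <- sprintf("g%04d", seq_len(nrow(base)))
  ident <- cbind(a = base[, 1], b = base[, 1])
  expect_equal(unname(tmm_factors(ident)), c(1, 1))

  doubled <- cbind(a = base[, 1], b = 2L * base[, 1])
  f <- tmm_factors(doubled)
  expect_lt(abs(log2(f[["b"]] / f[["a"]])), 0.01) # all signal is in lib size

  # rescaling every library's size by a common constant leaves factors
  # unchanged (up to the finite-library precision weights)
  f1 <- tmm_factors(base)
  f2 <- tmm_factors(base, lib_sizes = colSums(base) * 7)
  expect_equal(f1, f2, tolerance = 1e-4)

  expect_error(tmm_factors(cbind(a = base[, 1], b = 0L * base[, 1])), "all-zero")
})

test_that("TMM trims a DE spike: factors match the spike-free oracle within 2%", {
  set.seed(42)
  n <- 2000
  mu <- rlnorm(n, log(100), 1)
  counts <- sapply(1:3, function(j) rpois(n, mu))
  rownames(counts) <- sprintf("g%04d", 1:n)
  spiked <- counts
  hot <- sample(n, n * 0.05)
  spiked[hot, 3] <- spiked[hot, 3] * 8L
  f_spiked <- tmm_factors(spiked, ref_sample = 1)
  # oracle: recompute with the spiked genes removed entirely
  f_clean <- tmm_factors(spiked[-hot, ], lib_sizes = colSums(spiked), ref_sample = 1)
  expect_true(all(abs(log2(f_spiked / f_clean)) < log2(1.02)))
})

test_that("TMM agrees with the independent edgeR reference implementation", {
  set.seed(7)
  counts <- matrix(rnbinom(4000, mu = rlnorm(1000, log(80), 1), size = 4), ncol = 4)
  rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", 1:4)
  f_ref <- edgeR::calcNormFactors(counts, method = "TMM")
  f_own <- tmm_factors(counts)
  expect_equal(unname(f_own), unname(f_ref), tolerance = 1e-6)
})

test_that("expressed calls respect the strict FPKM cutoff and the length floor", {
  lens <- c(g1 = 300L, g2 = 150L, g3 = 500L)
  expect_true(call_expressed(c(g1 = 1.01), lens["g1"]))
  expect_false(call_expressed(c(g2 = 5.0), lens["g2"]))   # too short
  expect_false(call_expressed(c(g3 = 1.0), lens["g3"]))   # strict >
})

test_that("specificity regions equal brute-force set algebra and partition the families", {
  # three hand-assigned families across three accessions
  counts <- matrix(0L, nrow = 9, ncol = 6)
  rownames(counts) <- c(paste0("S_g", 1:3), paste0("C_g", 1:3), paste0("T1_g", 1:3))
  # fam1 expressed everywhere, fam2 only in T1, fam3 in S and C but not T1
  express <- list(S = c("S_g1", "S_g3"), C = c("C_g1", "C_g3"), T1 = c("T1_g1", "T1_g2"))
  samples <- make_samples(c("S", "C", "T1"), n_reps = 2)
  colnames(counts) <- samples$sample_id
  for (acc in names(express)) {
    ids <- samples$sample_id[samples$species_code == acc]
    counts[express[[acc]], ids] <- 1000L
  }
  cm <- new_hs_counts(counts, samples,
                      setNames(rep(1000L, nrow(counts)), rownames(counts)))
  prof <- expression_profile(cm, load_config())
  fam <- data.frame(
    family_id = rep(c("f1", "f2", "f3"), each = 3),
    species_code = rep(c("S", "C", "T1"), 3),
    gene_id = c("S_g1", "C_g1", "T1_g1", "S_g2", "C_g2", "T1_g2", "S_g3", "C_g3", "T1_g3")
  )
  spec <- specificity_analysis(prof, fam)
  expect_equal(spec$regions[["C&S&T1"]], 1)
  expect_equal(spec$regions[["T1"]], 1)
  expect_equal(spec$regions[["C&S"]], 1)
  expect_equal(sum(spec$regions), 3) # exhaustive, disjoint partition
})

test_that("replicate correlations are high within groups and lower between tissues", {
  sc <- sim_scenario(n_genes = 500, seed = 8, tissues = c("stem_apex", "leaf"),
                     fragment_site_fraction = 0.01,
                     mean_expression = c(meanlog = log(200), sdlog = 1))
  sim <- simulate_dataset(sc)
  qc <- replicate_correlation_qc(sim$counts)
  expect_gt(mean(qc$correlation[qc$type == "within"]),
            mean(qc$correlation[qc$type == "between"]))
  # an exactly duplicated sample correlates perfectly
  cm <- sim$counts
  dup <- cm$counts
  ids <- cm$samples$sample_id[cm$samples$accession == "S" & cm$samples$tissue == "stem_apex"]
  dup[, ids[2]] <- dup[, ids[1]]
  cm2 <- new_hs_counts(dup, cm$samples, cm$gene_lengths)
  qc2 <- replicate_correlation_qc(cm2)
  pair <- qc2[qc2$sample_a == ids[1] & qc2$sample_b == ids[2], ]
  expect_equal(pair$correlation, 1)
})
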