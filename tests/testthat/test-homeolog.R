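snps_u1 <- data.frame(unigene_id = "u1", pos = c(101L, 250L),
                      allele_S = c("A", "T"), allele_C = c("G", "C"),
                      stringsAsFactors = FALSE)

frag <- function(id, calls, sample = "T1_stem_apex_r1", gene = "u1") {
  data.frame(fragment_id = id, sample_id = sample, unigene_id = gene,
             allele_calls = calls, stringsAsFactors = FALSE)
}

test_that("fragments are binned by consistent parental alleles", {
  frags <- rbind(
    frag("f1", "101=A;250=T"),  # both S alleles
    frag("f2", "101=G;250=C"),  # both C alleles
    frag("f3", "101=A;250=C"),  # conflict -> ambiguous
    frag("f4", "101=C")         # matches neither parent -> ambiguous
  )
  part <- partition_fragments(frags, snps_u1)
  expect_equal(part$bin, c("S", "C", "ambiguous", "ambiguous"))
  # conservation: binned + ambiguous = total
  expect_equal(sum(table(part$bin)), nrow(frags))
})

test_that("fragments at unknown SNP positions are rejected, naming the fragment", {
  expect_error(partition_fragments(frag("fX", "999=A"), snps_u1), "fX")
})

test_that("homeolog counts average per-SNP coverage over the gene's SNPs", {
  one_snp <- snps_u1[1, ]
  frags <- rbind(
    do.call(rbind, lapply(1:10, function(i) frag(paste0("s", i), "101=A"))),
    do.call(rbind, lapply(1:4, function(i) frag(paste0("c", i), "101=G")))
  )
  hom <- homeolog_counts(partition_fragments(frags, one_snp), one_snp)
  expect_equal(hom$count_S, 10)
  expect_equal(hom$count_C, 4)

  # two SNPs with S coverage 10 and 12 -> mean 11
  frags2 <- rbind(
    do.call(rbind, lapply(1:8, function(i) frag(paste0("b", i), "101=A;250=T"))),
    do.call(rbind, lapply(1:2, function(i) frag(paste0("p", i), "101=A"))),
    do.call(rbind, lapply(1:4, function(i) frag(paste0("q", i), "250=T")))
  )
  part2 <- partition_fragments(frags2, snps_u1)
  hom2 <- homeolog_counts(part2, snps_u1)
  expect_equal(hom2$count_S, 11)
  # sum mode totals instead
  expect_equal(homeolog_counts(part2, snps_u1, mode = "sum")$count_S, 22)

  # all ambiguous -> zero counts, row retained and flagged
  amb <- rbind(frag("a1", "101=C"), frag("a2", "101=T"))
  hom3 <- homeolog_counts(partition_fragments(amb, snps_u1), snps_u1)
  expect_equal(hom3$count_S, 0)
  expect_equal(hom3$count_C, 0)
  expect_equal(hom3$n_ambiguous, 2L)
})

test_that("silent homeolog calls require all-zero counts with the partner and
           diploid ortholog expressed", {
  genes <- c("u1", "u2", "u3")
  S <- rbind(u1 = c(0, 0, 0), u2 = c(0, 1, 0), u3 = c(10, 12, 8))
  C <- rbind(u1 = c(40, 38, 55), u2 = c(30, 30, 30), u3 = c(0, 0, 0))
  colnames(S) <- colnames(C) <- paste0("r", 1:3)
  mats <- list(S = S, C = C)
  expS <- setNames(c(TRUE, TRUE, TRUE), genes)
  expC <- setNames(c(TRUE, TRUE, TRUE), genes)
  rep_ <- detect_silent_homeologs(mats, expS, expC)
  expect_true(rep_$flags$silent_S[rep_$flags$unigene_id == "u1"])
  expect_false(rep_$flags$silent_S[rep_$flags$unigene_id == "u2"]) # (0,1,0) not silent
  expect_true(rep_$flags$silent_C[rep_$flags$unigene_id == "u3"])
  expect_equal(rep_$n_testable, 3)

  # diploid ortholog not expressed -> untestable, not silent
  expS2 <- setNames(c(FALSE, TRUE, TRUE), genes)
  rep2 <- detect_silent_homeologs(mats, expS2, expC)
  expect_equal(rep2$n_silent_S, 0)
  expect_equal(rep2$n_testable, 2)
})

test_that("partition bins equal true origins on clean simulated fragments and
           aggregated ratios track the homeolog means", {
  sc <- tiny_scenario(n_genes = 250, seed = 13, ambiguous_frac = 0,
                      mean_expression = c(meanlog = log(400), sdlog = 0.5))
  sim <- simulate_dataset(sc)
  part <- partition_fragments(sim$fragments, sim$snps)
  expect_identical(part$bin, sim$fragments$true_origin)

  # per-gene count ratios converge on the simulated homeolog mean ratio
  hom <- homeolog_counts(part, sim$snps)
  tot <- aggregate(cbind(count_S, count_C) ~ unigene_id, hom, sum)
  tr <- sim$truth[match(tot$unigene_id, sim$truth$gene_id_T1), ]
  ok <- !is.na(tr$true_rh) & tot$count_S + tot$count_C > 300
  est_rh <- log2(tot$count_C[ok] / tot$count_S[ok])
  # replicate NB noise (phi = 0.1, n = 3) puts the sd of a per-gene log2
  # ratio near 0.37; the estimates must sit on the truth up to that floor
  expect_lt(median(abs(est_rh - tr$true_rh[ok])), 0.45)
  expect_lt(abs(median(est_rh - tr$true_rh[ok])), 0.1) # no systematic shift
})
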