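test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:80, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  # appending a p = 1 element never perturbs the relative order of the rest
  p <- runif(30)
  q1 <- bh_adjust(p); q2 <- bh_adjust(c(p, 1))[1:30]
  expect_identical(order(q1), order(q2))
})

test_that("NB exact test is symmetric and reduces to the exact binomial at phi 0", {
  # the observed split is the conditional mode -> all outcomes qualify
  expect_equal(nb_exact_test(c(10, 10, 10), c(10, 10, 10), phi = 0.1), 1)
  # phi = 0, single pooled observation per group: exact binomial two-sided tail
  expect_equal(nb_exact_test(30, 0, phi = 0),
               binom.test(30, 30, 0.5)$p.value, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:30) {
    a <- rpois(3, 60); b2 <- rpois(3, 60)
    phi <- runif(1, 0, 0.3)
    expect_equal(nb_exact_test(a, b2, phi = phi), nb_exact_test(b2, a, phi = phi),
                 tolerance = 1e-12)
  }
  # zero total -> p = 1 by convention
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), phi = 0.1), 1)
})

test_that("NB exact test agrees with edgeR's exact test on equal library sizes", {
  set.seed(23)
  n <- 300
  counts <- matrix(rnbinom(n * 6, mu = 80, size = 1 / 0.15), ncol = 6)
  rownames(counts) <- sprintf("g%03d", 1:n)
  hot <- 1:30
  counts[hot, 1:3] <- matrix(rnbinom(length(hot) * 3, mu = 320, size = 1 / 0.15), ncol = 3)
  grp <- factor(rep(c("a", "b"), each = 3))
  d <- edgeR::DGEList(counts = counts, group = grp, lib.size = rep(1e6, 6))
  d$common.dispersion <- 0.15
  p_ref <- edgeR::exactTest(d, dispersion = 0.15)$table$PValue
  p_own <- vapply(1:n, function(i) {
    nb_exact_test(counts[i, 1:3], counts[i, 4:6], phi = 0.15)
  }, numeric(1))
  # same conditional construction up to edgeR's internal smoothing; close on
  # the vast majority of genes and never far off on the rest
  expect_gt(cor(-log10(p_own), -log10(p_ref)), 0.999)
  expect_lt(median(abs(p_own - p_ref)), 0.01)
})

test_that("common-dispersion estimation recovers the truth and degenerates cleanly", {
  set.seed(31)
  n <- 800
  mu <- rlnorm(n, log(120), 0.8)
  pois <- cbind(sapply(1:3, function(j) rpois(n, mu)),
                sapply(1:3, function(j) rpois(n, mu)))
  grp <- factor(rep(c("a", "b"), each = 3))
  expect_lte(estimate_common_dispersion(pois, grp)$common_phi, 0.02)

  nb <- cbind(sapply(1:3, function(j) rnbinom(n, mu = mu, size = 5)),
              sapply(1:3, function(j) rnbinom(n, mu = mu, size = 5)))
  est <- estimate_common_dispersion(nb, grp)$common_phi
  expect_gt(est, 0.13); expect_lt(est, 0.28)  # phi_true = 0.2

  # method-of-moments fallback agrees on clean simulated data
  expect_lt(abs(dispersion_mom(nb, grp) - est), 0.08)

  const <- matrix(50L, nrow = 20, ncol = 6)
  expect_equal(estimate_common_dispersion(const, grp)$common_phi, 0)
  expect_error(estimate_common_dispersion(pois[, 1:3], factor(c("a", "a", "b"))),
               "no-replicate")
})

test_that("p-values are uniform under the Poisson null on high-count genes", {
  set.seed(17)
  n <- 1000
  counts <- matrix(rpois(n * 6, 200), ncol = 6)
  p <- vapply(1:n, function(i) nb_exact_test(counts[i, 1:3], counts[i, 4:6], phi = 0),
              numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ternary calls gate on fold change, FDR and optional raw P", {
  expect_equal(call_deg(1.5, 0.01), "up")
  expect_equal(call_deg(1.5, 0.20), "equal")
  expect_equal(call_deg(0.9, 0.001), "equal")
  expect_equal(call_deg(-1.5, 0.01), "down")
  expect_equal(call_deg(1.5, 0.01, p = 0.2, p_max = 0.05), "equal")
})

test_that("truly differential genes are detected with high power", {
  # |log2FC| = 2, mean 100, phi = 0.05, n = 3
  set.seed(19)
  n <- 400
  mu_a <- rep(100, n); mu_b <- mu_a * 2^sample(c(2, -2), n, TRUE)
  a <- sapply(1:3, function(j) rnbinom(n, mu = mu_a, size = 20))
  b2 <- sapply(1:3, function(j) rnbinom(n, mu = mu_b, size = 20))
  rownames(a) <- rownames(b2) <- sprintf("g%03d", 1:n)
  tab <- de_table(a, b2, lib_a = rep(1e6, 3), lib_b = rep(1e6, 3), phi = 0.05)
  expect_gte(mean(tab$call != "equal"), 0.90)
})
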