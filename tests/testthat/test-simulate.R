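test_that("identical seeds give identical datasets", {
  a <- simulate_dataset(tiny_scenario(n_genes = 80, seed = 11))
  b <- simulate_dataset(tiny_scenario(n_genes = 80, seed = 11))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(tiny_scenario(n_genes = 80, seed = 12))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("zero dispersion gives Poisson replicate noise around the mean", {
  # many replicates, no library jitter: each gene's replicate mean must land
  # within 3 standard errors of its generating mean (Poisson: var = mu)
  sc <- sim_scenario(n_genes = 25, n_reps = 400, nb_dispersion = 0,
                     library_size_jitter = 0,
                     category_fractions = c(intermediate = 0, S_dominance = 0,
                                            C_dominance = 0, transgressive_up = 0,
                                            transgressive_down = 0),
                     bias_fractions = c(S_bias = 0, C_bias = 0),
                     silent_fractions = c(silent_S = 0, silent_C = 0),
                     specific_expression_frac = 0, seed = 5)
  sim <- simulate_dataset(sc)
  s_ids <- sim$counts$samples$sample_id[sim$counts$samples$species_code == "S"]
  y <- sim$counts$counts[sim$truth$gene_id_S, s_ids]
  mu <- sim$truth$mu_S
  se <- sqrt(mu / length(s_ids))
  expect_true(all(abs(rowMeans(y) - mu) < 3.5 * se))
  # Poisson-consistent variance: index of dispersion near 1 on average
  vmr <- apply(y, 1, var) / rowMeans(y)
  expect_lt(abs(mean(vmr) - 1), 0.15)
})

test_that("a null scenario emits only conserved, unbiased truth", {
  sc <- tiny_scenario(
    n_genes = 100, seed = 2,
    category_fractions = c(intermediate = 0, S_dominance = 0, C_dominance = 0,
                           transgressive_up = 0, transgressive_down = 0),
    bias_fractions = c(S_bias = 0, C_bias = 0),
    silent_fractions = c(silent_S = 0, silent_C = 0)
  )
  sim <- simulate_dataset(sc)
  expect_true(all(sim$truth$true_group == "conserved"))
  expect_true(all(sim$truth$true_bias == "none"))
  expect_true(all(!sim$truth$silent_S & !sim$truth$silent_C))
  expect_true(all(sim$truth$mu_S == sim$truth$mu_C))
})

test_that("realized truth-label fractions match requested fractions", {
  # binomial 99% CI check on the bias labels at 5,000 genes; fragments are
  # irrelevant to the labels so coverage is kept minimal for speed
  sc <- sim_scenario(n_genes = 5000, seed = 9,
                     bias_fractions = c(S_bias = 0.15, C_bias = 0.05),
                     fragment_site_fraction = 0.005, snps_per_gene = 1)
  sim <- simulate_dataset(sc)
  fr <- c(S_bias = 0.15, C_bias = 0.05)
  for (nm in names(fr)) {
    n_hat <- sum(sim$truth$true_bias == nm)
    ci <- qbinom(c(0.005, 0.995), 5000, fr[[nm]])
    expect_gte(n_hat, ci[1]); expect_lte(n_hat, ci[2])
  }
})

test_that("truth means are internally consistent with the category labels", {
  sim <- simulate_dataset(tiny_scenario(n_genes = 600, seed = 4))
  tr <- sim$truth
  e <- 2 # scenario effect size
  with(tr[tr$true_group == "conserved", ], {
    expect_true(all(mu_S == mu_C & mu_T == mu_S))
  })
  with(tr[tr$true_group == "S_dominance", ], {
    expect_true(all(mu_T == mu_S))
    expect_true(all(abs(abs(log2(mu_S / mu_C)) - e) < 1e-12))
  })
  with(tr[tr$true_group == "intermediate", ], {
    expect_true(all(mu_T > pmin(mu_S, mu_C) & mu_T < pmax(mu_S, mu_C)))
    expect_true(all(abs(log2(mu_T / mu_S)) >= e - 1e-12))
    expect_true(all(abs(log2(mu_T / mu_C)) >= e - 1e-12))
  })
  with(tr[tr$true_group == "transgressive_up", ], {
    expect_true(all(mu_T >= 2^e * pmax(mu_S, mu_C) - 1e-9))
  })
  with(tr[tr$true_group == "transgressive_down", ], {
    expect_true(all(mu_T <= 2^-e * pmin(mu_S, mu_C) + 1e-9))
  })
  # biased genes: homeolog ratio departs from parental legacy by the bias effect
  biased <- !is.na(tr$true_rh) & tr$true_bias != "none"
  expect_true(all(abs(abs(tr$true_rh[biased] - tr$true_rp[biased]) - 2) < 1e-9))
  legacy <- !is.na(tr$true_rh) & tr$true_bias == "none"
  expect_true(all(abs(tr$true_rh[legacy] - tr$true_rp[legacy]) < 1e-9))
})

test_that("aggregated fragment coverage reflects the homeolog mean ratio", {
  # unbiased, conserved genes: pooled S:C fragment-site ratio ~ parental legacy (1:1)
  sc <- sim_scenario(n_genes = 400, seed = 21,
                     mean_expression = c(meanlog = log(300), sdlog = 0.3),
                     category_fractions = c(intermediate = 0, S_dominance = 0,
                                            C_dominance = 0, transgressive_up = 0,
                                            transgressive_down = 0),
                     bias_fractions = c(S_bias = 0, C_bias = 0),
                     silent_fractions = c(silent_S = 0, silent_C = 0),
                     specific_expression_frac = 0, ambiguous_frac = 0)
  sim <- simulate_dataset(sc)
  part <- partition_fragments(sim$fragments, sim$snps)
  ratio <- sum(part$n_sites[part$bin == "S"]) / sum(part$n_sites[part$bin == "C"])
  expect_lt(abs(log2(ratio)), 0.05)
})
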