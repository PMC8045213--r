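test_that("Rh and Rp follow their definitions and zero counts are untestable", {
  expect_equal(compute_rh(100, 100), 0)
  expect_equal(compute_rh(50, 200), 2)    # C-homeolog 4x the S-homeolog
  expect_true(is.na(compute_rh(0, 50)))
  expect_equal(compute_rp(10, 10), 0)
  expect_equal(compute_rp(25, 100), -2)
  expect_true(is.na(compute_rp(0, 5)))
  # antisymmetry under swapping the parental roles
  expect_equal(compute_rh(30, 240), -compute_rh(240, 30))
})

test_that("Fisher's exact p equals hypergeometric enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  expect_equal(fisher_exact_2x2(120, 30, 50, 50),
               fisher_enum_oracle(120, 30, 50, 50), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    tb <- matrix(rpois(4, 25), 2)
    p_own <- fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(p_own, fisher_enum_oracle(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
    expect_equal(p_own, stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(0, 0, 5, 5), 1) # degenerate margin
})

test_that("homeolog DE calls identical pairs equal and applies the raw-P gate", {
  S <- matrix(30, 5, 3, dimnames = list(paste0("g", 1:5), paste0("r", 1:3)))
  mats <- list(S = S, C = S)
  de <- homeolog_de_test(mats, phi = 0.05)
  expect_true(all(de$homeolog_de == "equal"))
  expect_true(all(de$p_value == 1))
  # strong 4x excess of the S-homeolog is detected
  mats2 <- list(S = S * 8, C = S * 2)
  de2 <- homeolog_de_test(mats2, phi = 0.01)
  expect_true(all(de2$homeolog_de == "S_higher"))
})

test_that("bias calls need significance plus the |Rh - Rp| > 1 gate, with the
           documented direction rule", {
  mk <- function(s_counts, c_counts, n = 40) {
    genes <- sprintf("g%03d", seq_len(n))
    S <- matrix(rep(s_counts, n), n, 3, byrow = TRUE, dimnames = list(genes, paste0("r", 1:3)))
    C <- matrix(rep(c_counts, n), n, 3, byrow = TRUE, dimnames = list(genes, paste0("r", 1:3)))
    list(S = S, C = C)
  }
  n <- 40
  mats <- mk(c(20, 20, 20), c(120, 110, 130))          # Rh ~ +2.6
  par_c <- setNames(rep(300, n), rownames(mats$S))     # Rp ~ 0
  par_s <- setNames(rep(300, n), rownames(mats$S))
  bt <- bias_table(mats, par_c, par_s, config = load_config())
  expect_true(all(bt$bias_class == "C_bias"))          # Rh > Rp
  # swapping the homeolog and parental roles flips the call
  bt2 <- bias_table(list(S = mats$C, C = mats$S), par_s, par_c, config = load_config())
  expect_true(all(bt2$bias_class == "S_bias"))
  expect_equal(bt2$rh, -bt$rh)

  # parental-legacy pair: same ratio in homeologs and parents -> no bias
  mats3 <- mk(c(20, 20, 20), c(120, 110, 130))
  bt3 <- bias_table(mats3, setNames(rep(600, n), rownames(mats3$S)),
                    setNames(rep(100, n), rownames(mats3$S)), config = load_config())
  expect_true(all(bt3$bias_class == "none"))

  # untestable pair: a zero homeolog
  mats4 <- mk(c(0, 0, 0), c(50, 50, 50))
  bt4 <- bias_table(mats4, par_c, par_s, config = load_config())
  expect_true(all(!bt4$testable))
  expect_true(all(is.na(bt4$bias_class)))
})

test_that("integration cross-tab conserves its marginals", {
  df <- data.frame(
    homeolog_de = c("equal", "equal", "S_higher", "C_higher", "equal"),
    bias_class = c("none", "S_bias", "S_bias", "none", "none"),
    stringsAsFactors = FALSE
  )
  it <- integrate_bias(df)
  expect_equal(it$n, 5)
  expect_equal(sum(it$counts), 5)
  expect_equal(unname(rowSums(it$counts)[c("S_higher", "equal", "C_higher")]),
               c(1, 3, 1))
  expect_equal(it$counts["equal", "none"], 2)
  expect_equal(it$row_percent["equal", "S_bias"], 100 / 3, tolerance = 1e-12)
  # single-cell case
  one <- integrate_bias(data.frame(homeolog_de = "equal", bias_class = "none"))
  expect_equal(one$counts["equal", "none"], 1)
  expect_equal(one$row_percent["equal", "none"], 100)
})
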