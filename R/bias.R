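# Relative homeolog contribution (Rh), parental ortholog ratio (Rp), homeolog
# differential expression, and homeolog expression bias (Rh vs Rp, Fisher's
# exact test), plus the integration cross-tabulation of the two
# classifications.

#' Relative homeolog expression
#'
#' `Rh = log2(C-homeolog / S-homeolog)`; positive values mean the paternal-type
#' (C) homeolog is the more expressed. Defined only for testable pairs (both
#' homeolog counts nonzero); otherwise `NA`.
#'
#' @param count_s,count_c S- and C-homeolog counts.
#' @return Rh, or `NA` where untestable.
#' @export
compute_rh <- function(count_s, count_c) {
  ifelse(count_s > 0 & count_c > 0, log2(count_c / count_s), NA_real_)
}

#' Relative parental ortholog expression
#'
#' `Rp = log2(C-parent / S-parent)` on normalized mean abundances across
#' replicates; same sign convention as [compute_rh()].
#'
#' @param abund_c,abund_s normalized parental abundances (C first, matching
#'   the ratio's numerator).
#' @return Rp, or `NA` where either abundance is zero.
#' @export
compute_rp <- function(abund_c, abund_s) {
  ifelse(abund_c > 0 & abund_s > 0, log2(abund_c / abund_s), NA_real_)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability method: with all margins fixed, the support
#' of the top-left cell is enumerated under the hypergeometric distribution
#' and the p-value is the sum of the probabilities of all tables as likely or
#' less likely than the observed one (ties included up to a relative 1e-7).
#'
#' @param a,b,c,d cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) hs_stop("fisher_exact_2x2: negative cell")
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Homeolog differential expression test
#'
#' Compares the S- and C-homeolog replicate counts of each gene as a two-group
#' negative-binomial exact test with equal library sizes (both homeologs come
#' from the same libraries, so within-sample ratios are normalization-free).
#' Counts are rounded to the nearest integer for the exact test. Calls use
#' the fold-change, FDR and raw-P gates configured for the homeolog-level
#' analysis.
#'
#' @param mats list with matrices `S` and `C` from
#'   [homeolog_count_matrices()].
#' @param phi common dispersion; `NULL` estimates it from the homeolog table.
#' @param config `hs_config`.
#' @return data.frame: gene_id, log2fc (C over S), p_value, fdr, homeolog_de
#'   (`S_higher` / `C_higher` / `equal`).
#' @export
homeolog_de_test <- function(mats, phi = NULL, config = load_config()) {
  S <- round(mats$S); C <- round(mats$C)
  storage.mode(S) <- "integer"; storage.mode(C) <- "integer"
  if (is.null(phi)) {
    both <- cbind(S, C)
    colnames(both) <- make.unique(colnames(both))
    grp <- factor(rep(c("S", "C"), c(ncol(S), ncol(C))))
    phi <- estimate_common_dispersion(both, grp,
                                      lib_sizes = rep(1, ncol(both)))$common_phi
  }
  de <- de_table(C, S, lib_a = rep(1, ncol(C)), lib_b = rep(1, ncol(S)), phi = phi,
                 abs_log2fc = config$abs_log2fc, fdr_max = config$fdr_homeolog_de,
                 p_max = config$p_homeolog_de)
  de$homeolog_de <- c(up = "C_higher", down = "S_higher", equal = "equal")[de$call]
  de$call <- NULL
  names(de)[names(de) == "gene_id"] <- "gene_id"
  de
}

#' Homeolog expression bias analysis
#'
#' For every testable homeolog pair (both homeolog counts nonzero, summed over
#' replicates) whose parental orthologs are both expressed, the replicate-sum
#' homeolog counts are contrasted against the replicate-sum normalized
#' parental counts in a single 2x2 Fisher's exact test per gene:
#' `[[C_homeolog, S_homeolog], [C_parent, S_parent]]`. P-values are
#' BH-adjusted across all tested pairs (one family per tetraploid x tissue).
#' A pair is biased when FDR and raw P pass their gates and `|Rh - Rp| > 1`
#' (the fold change of the ratio of ratios; with the table as constructed this
#' equals the gate on the table's log2 odds ratio): bias toward C when
#' `Rh > Rp`, toward S when `Rh < Rp`.
#'
#' @param mats homeolog count matrices ([homeolog_count_matrices()]).
#' @param parent_c,parent_s named vectors of replicate-summed, normalization-
#'   adjusted parental ortholog counts, named by tetraploid unigene id.
#' @param parent_expressed_c,parent_expressed_s named logical vectors of
#'   diploid expressed calls (same names).
#' @param config `hs_config`.
#' @param phi dispersion for the homeolog DE component (`NULL` = estimate).
#' @return data.frame per gene: rh, rp, testable, bias_testable, homeolog DE
#'   columns, p_bias, fdr_bias, bias_class (`S_bias` / `C_bias` / `none`).
#' @export
bias_table <- function(mats, parent_c, parent_s,
                       parent_expressed_c = NULL, parent_expressed_s = NULL,
                       config = load_config(), phi = NULL) {
  genes <- rownames(mats$S)
  hom_s <- round(rowSums(mats$S)); hom_c <- round(rowSums(mats$C))
  testable <- hom_s > 0 & hom_c > 0
  par_c <- round(parent_c[genes]); par_s <- round(parent_s[genes])
  par_c[is.na(par_c)] <- 0; par_s[is.na(par_s)] <- 0
  exp_c <- if (is.null(parent_expressed_c)) par_c > 0 else parent_expressed_c[genes] %in% TRUE
  exp_s <- if (is.null(parent_expressed_s)) par_s > 0 else parent_expressed_s[genes] %in% TRUE
  bias_testable <- testable & exp_c & exp_s & par_c > 0 & par_s > 0

  rh <- compute_rh(hom_s, hom_c)
  rp <- compute_rp(par_c, par_s)

  p_bias <- rep(NA_real_, length(genes))
  idx <- which(bias_testable)
  p_bias[idx] <- vapply(idx, function(i) {
    fisher_exact_2x2(hom_c[i], hom_s[i], par_c[i], par_s[i])
  }, numeric(1))
  fdr_bias <- rep(NA_real_, length(genes))
  fdr_bias[idx] <- bh_adjust(p_bias[idx])

  delta <- rh - rp
  sig <- bias_testable & !is.na(fdr_bias) &
    fdr_bias < config$fdr_bias & p_bias < config$p_bias &
    abs(delta) > config$abs_log2fc
  bias_class <- rep("none", length(genes))
  bias_class[sig & delta > 0] <- "C_bias"
  bias_class[sig & delta < 0] <- "S_bias"

  de <- homeolog_de_test(mats, phi = phi, config = config)
  out <- data.frame(
    gene_id = genes, rh = rh, rp = rp,
    testable = testable, bias_testable = bias_testable,
    log2fc_hom = de$log2fc[match(genes, de$gene_id)],
    p_de = de$p_value[match(genes, de$gene_id)],
    fdr_de = de$fdr[match(genes, de$gene_id)],
    homeolog_de = de$homeolog_de[match(genes, de$gene_id)],
    p_bias = p_bias, fdr_bias = fdr_bias, bias_class = bias_class,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$homeolog_de[!out$testable] <- NA_character_
  out$bias_class[!out$bias_testable] <- NA_character_
  hs_log("bias_table: %d genes, %d testable, %d bias-testable; S_bias %d, C_bias %d",
         length(genes), sum(testable), sum(bias_testable),
         sum(out$bias_class %in% "S_bias"), sum(out$bias_class %in% "C_bias"))
  out
}

#' Integrate homeolog DE and bias classifications
#'
#' Cross-tabulates the homeolog differential-expression call against the bias
#' class over pairs carrying both classifications, with marginals and
#' within-row percentages.
#'
#' @param bias data.frame from [bias_table()].
#' @return list: `counts` 3x3 integer matrix (rows homeolog_de, cols
#'   bias_class), `row_percent`, `n`.
#' @export
integrate_bias <- function(bias) {
  keep <- !is.na(bias$homeolog_de) & !is.na(bias$bias_class)
  de <- factor(bias$homeolog_de[keep], levels = c("S_higher", "equal", "C_higher"))
  bc <- factor(bias$bias_class[keep], levels = c("S_bias", "none", "C_bias"))
  counts <- table(homeolog_de = de, bias_class = bc)
  rp <- prop.table(counts, margin = 1) * 100
  rp[is.nan(rp)] <- 0
  list(counts = unclass(counts), row_percent = unclass(rp), n = sum(counts))
}
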