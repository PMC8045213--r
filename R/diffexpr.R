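# Two-group differential expression on counts: common-dispersion estimation by
# conditional maximum likelihood, a negative-binomial exact test, BH
# adjustment, and ternary up/down/equal calls.
#
# The NB is parameterized by mean mu and dispersion phi with
# variance mu + phi * mu^2; phi = 0 degenerates to Poisson.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a p-value vector, returned in input order and
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values (q-values), same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) hs_stop("bh_adjust: p must be numeric")
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) hs_stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# conditional NB log-likelihood of one phi for a matrix of library-equalized
# counts and a group assignment; terms free of phi are dropped
cond_nb_loglik <- function(phi, counts, group) {
  if (phi <= 0) return(cond_pois_loglik(counts, group))
  r <- 1 / phi
  ll <- 0
  for (lev in levels(group)) {
    y <- counts[, group == lev, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
      length(z) * lgamma(n * r) - sum(lgamma(z + n * r))
  }
  ll
}

# phi -> 0 limit: conditional on the group total the counts are multinomial;
# expressed relative to the same dropped terms as the NB branch, which leaves
# only the -z * log(n) term
cond_pois_loglik <- function(counts, group) {
  ll <- 0
  for (lev in levels(group)) {
    y <- counts[, group == lev, drop = FALSE]
    ll <- ll - sum(rowSums(y)) * log(ncol(y))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the likelihood of the within-group count splits conditional on
#' each gene's group totals, after equalizing library sizes by proportional
#' rescaling of counts to the geometric-mean library size. The estimate is
#' clamped to \[0, 10\].
#'
#' @param counts integer matrix, genes x samples.
#' @param group factor (or coercible) of length `ncol(counts)`; every level
#'   needs at least two replicates.
#' @param lib_sizes effective library sizes; defaults to column sums.
#' @return list with `common_phi` and the number of genes used.
#' @export
estimate_common_dispersion <- function(counts, group, lib_sizes = colSums(counts)) {
  group <- droplevels(as.factor(group))
  if (any(table(group) < 2L))
    hs_stop("estimate_common_dispersion: every group needs >= 2 replicates; no-replicate mode is unsupported")
  if (any(lib_sizes <= 0)) hs_stop("estimate_common_dispersion: library with zero total counts")
  eq <- sweep(counts, 2, geo_mean(lib_sizes) / lib_sizes, "*")
  keep <- rowSums(eq) > 0
  eq <- eq[keep, , drop = FALSE]
  if (nrow(eq) == 0) return(list(common_phi = 0, n_genes = 0L))
  f <- function(log_phi) cond_nb_loglik(exp(log_phi), eq, group)
  opt <- optimize(f, interval = c(log(1e-6), log(10)), maximum = TRUE, tol = 1e-4)
  phi <- exp(opt$maximum)
  # prefer the Poisson limit when it is at least as likely as the interior optimum
  if (cond_pois_loglik(eq, group) >= opt$objective || phi < 1.5e-6) phi <- 0
  phi <- min(max(phi, 0), 10)
  hs_log("estimate_common_dispersion: phi = %.4g over %d genes", phi, nrow(eq))
  list(common_phi = phi, n_genes = nrow(eq))
}

#' Method-of-moments common dispersion
#'
#' Pooled moment estimator on library-equalized counts: solves
#' sum(var - mean) = phi * sum(mean^2) across genes and groups. Provided as a
#' simple cross-check of the conditional-likelihood estimate.
#'
#' @inheritParams estimate_common_dispersion
#' @return non-negative dispersion estimate.
#' @export
dispersion_mom <- function(counts, group, lib_sizes = colSums(counts)) {
  group <- droplevels(as.factor(group))
  eq <- sweep(counts, 2, geo_mean(lib_sizes) / lib_sizes, "*")
  num <- 0; den <- 0
  for (lev in levels(group)) {
    y <- eq[, group == lev, drop = FALSE]
    m <- rowMeans(y)
    v <- apply(y, 1, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  max(0, num / den)
}

#' Negative-binomial exact test for a two-group count split
#'
#' Conditions on the gene's total library-equalized count and computes the
#' two-sided probability of a split as or less likely than the one observed,
#' under a common mean. Group sums of n iid NB(mu, phi) replicates are
#' NB(n * mu, phi / n), so the conditional support is enumerated with sizes
#' n_a/phi and n_b/phi. At phi = 0 this reduces to the exact binomial split.
#'
#' @param counts_a,counts_b replicate count vectors for the two groups.
#' @param lib_a,lib_b library sizes per replicate (default: equal).
#' @param phi common dispersion (>= 0).
#' @return two-sided p-value. A gene with zero total returns 1.
#' @export
nb_exact_test <- function(counts_a, counts_b, phi,
                          lib_a = rep(1, length(counts_a)),
                          lib_b = rep(1, length(counts_b))) {
  if (any(c(counts_a, counts_b) < 0)) hs_stop("nb_exact_test: negative counts")
  if (phi < 0) hs_stop("nb_exact_test: phi must be >= 0")
  gm <- geo_mean(c(lib_a, lib_b))
  y_a <- round(sum(counts_a * gm / lib_a))
  y_b <- round(sum(counts_b * gm / lib_b))
  nb_exact_test_sums(y_a, y_b, length(counts_a), length(counts_b), phi)
}

# exact conditional test on pre-equalized group sums
nb_exact_test_sums <- function(y_a, y_b, n_a, n_b, phi) {
  z <- y_a + y_b
  if (z == 0) return(1)
  support <- 0:z
  if (phi == 0) {
    probs <- dbinom(support, size = z, prob = n_a / (n_a + n_b))
  } else {
    r <- 1 / phi
    # common per-replicate mean cancels in the conditional; any positive value works
    mu <- z / (n_a + n_b)
    lp <- dnbinom(support, size = n_a * r, mu = n_a * mu, log = TRUE) +
      dnbinom(z - support, size = n_b * r, mu = n_b * mu, log = TRUE)
    lp <- lp - max(lp)
    probs <- exp(lp)
    probs <- probs / sum(probs)
  }
  p_obs <- probs[y_a + 1L]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Ternary up/down/equal call from effect size and significance
#'
#' `up` requires log2FC above the fold-change gate and FDR below its gate (and
#' raw P below its gate where one is configured, as for the homeolog-level
#' analysis); `down` is symmetric; everything else is `equal`.
#'
#' @param log2fc,fdr,p numeric vectors (p optional).
#' @param abs_log2fc,fdr_max,p_max gates.
#' @return character vector in `c("up", "down", "equal")`.
#' @export
call_deg <- function(log2fc, fdr, p = NULL, abs_log2fc = 1, fdr_max = 0.05, p_max = NULL) {
  sig <- fdr < fdr_max
  if (!is.null(p_max) && !is.null(p)) sig <- sig & p < p_max
  call <- rep("equal", length(log2fc))
  call[sig & log2fc > abs_log2fc] <- "up"
  call[sig & log2fc < -abs_log2fc] <- "down"
  call
}

#' Differential expression table for one pairwise contrast
#'
#' Runs the NB exact test gene by gene on two replicate count matrices with
#' the same genes in the same order, using effective (normalization-adjusted)
#' library sizes, then BH-adjusts within the contrast and applies the ternary
#' call. log2 fold changes are computed on library-equalized group mean
#' abundances with a 0.5 pseudo-count per group so fold changes stay bounded.
#'
#' @param counts_a,counts_b integer matrices, genes x replicates (group a over
#'   group b).
#' @param lib_a,lib_b effective library sizes per replicate column.
#' @param phi common dispersion; `NULL` estimates it from these data.
#' @param abs_log2fc,fdr_max,p_max call gates (see [call_deg()]).
#' @return data.frame: gene_id, log2fc, p_value, fdr, call.
#' @export
de_table <- function(counts_a, counts_b, lib_a = colSums(counts_a),
                     lib_b = colSums(counts_b), phi = NULL,
                     abs_log2fc = 1, fdr_max = 0.05, p_max = NULL) {
  stopifnot(nrow(counts_a) == nrow(counts_b))
  if (is.null(phi)) {
    both <- cbind(counts_a, counts_b)
    grp <- factor(rep(c("a", "b"), c(ncol(counts_a), ncol(counts_b))))
    phi <- estimate_common_dispersion(both, grp, c(lib_a, lib_b))$common_phi
  }
  gm <- geo_mean(c(lib_a, lib_b))
  eq_a <- sweep(counts_a, 2, gm / lib_a, "*")
  eq_b <- sweep(counts_b, 2, gm / lib_b, "*")
  ya <- round(rowSums(eq_a)); yb <- round(rowSums(eq_b))
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)
  p <- vapply(seq_len(nrow(counts_a)), function(i) {
    nb_exact_test_sums(ya[i], yb[i], n_a, n_b, phi)
  }, numeric(1))
  log2fc <- log2((rowMeans(eq_a) + 0.5) / (rowMeans(eq_b) + 0.5))
  fdr <- bh_adjust(p)
  data.frame(
    gene_id = rownames(counts_a) %||% as.character(seq_along(p)),
    log2fc = log2fc, p_value = p, fdr = fdr,
    call = call_deg(log2fc, fdr, p, abs_log2fc, fdr_max, p_max),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
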