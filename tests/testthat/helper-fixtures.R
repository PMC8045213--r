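# In-code fixtures shared across test files.

# minimal sample sheet: one accession per species code, one tissue
make_samples <- function(accessions = c("S", "C", "T1"), n_reps = 2,
                         tissue = "stem_apex") {
  do.call(rbind, lapply(accessions, function(a) {
    data.frame(
      sample_id = sprintf("%s_%s_r%d", a, tissue, seq_len(n_reps)),
      species_code = a, population = NA_character_,
      tissue = tissue, replicate = seq_len(n_reps),
      stringsAsFactors = FALSE
    )
  }))
}

# small deterministic count object
make_counts <- function(counts, accessions = c("S", "C"), n_reps = 2,
                        lengths = NULL, tissue = "stem_apex") {
  samples <- make_samples(accessions, n_reps, tissue)
  colnames(counts) <- samples$sample_id
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(lengths)) lengths <- setNames(rep(1000L, nrow(counts)), rownames(counts))
  new_hs_counts(counts, samples, lengths)
}

# literal step-up BH definition, used as the independent oracle
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# brute-force two-sided Fisher p by hypergeometric enumeration over the
# fixed margins, via the log-factorial formula (independent of dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b; N <- m + n
  lp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(N, k)
  }
  support <- max(0, k - n):min(k, m)
  probs <- exp(lp(support))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# tiny fast scenario for pipeline-level tests
tiny_scenario <- function(n_genes = 200, seed = 1, ...) {
  args <- list(n_genes = n_genes, seed = seed,
               mean_expression = c(meanlog = log(200), sdlog = 0.7))
  args <- utils::modifyList(args, list(...))
  do.call(sim_scenario, args)
}
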