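# Seeded generator of parental and allotetraploid count data, diagnostic
# SNPs, and fragment observations with ground-truth labels. The generator
# emulates the statistical structure the analysis assumes: negative-binomial
# replicate noise around per-gene means, parental divergence, inheritance
# categories realized as mean relations among the three species, homeolog
# shares set by parental legacy times an optional bias factor, silent
# homeologs, and species-specific expression of ortholog families.

BASES <- c("A", "C", "G", "T")

#' Simulation scenario
#'
#' Builds a validated scenario object. Defaults describe an allotetraploid /
#' two-diploid design with three biological replicates and the asymmetries
#' reported for this study system: more S-bias than C-bias (maternal-like
#' excess), and more silent C-homeologs than S-homeologs.
#'
#' @param n_genes number of ortholog families.
#' @param n_reps biological replicates per accession x tissue (>= 2).
#' @param tetraploids character vector of tetraploid species codes
#'   (`"T1"`, optionally `"T2"`).
#' @param c_populations accession names for populations of the C diploid; a
#'   single `"C"` keeps one undifferentiated population.
#' @param tissues tissues profiled.
#' @param mean_expression `c(meanlog=, sdlog=)` of the log-normal baseline
#'   per-gene expression mean.
#' @param baseline_min floor applied to the baseline mean (0 = none).
#' @param nb_dispersion common NB dispersion phi (variance `mu + phi mu^2`);
#'   0 gives Poisson noise.
#' @param library_size_jitter multiplicative uniform jitter half-width for
#'   per-sample depth factors (0.2 = +/-20%).
#' @param parent_divergence_frac probability that a transgressive gene also
#'   has divergent parents (divergence of intermediate/dominance genes is
#'   category-implied; conserved genes cannot diverge).
#' @param effect_log2fc effect size of every "different" mean relation.
#' @param category_fractions named fractions over `intermediate`,
#'   `S_dominance`, `C_dominance`, `transgressive_up`, `transgressive_down`;
#'   the remainder is conserved.
#' @param bias_fractions named fractions `S_bias`, `C_bias`.
#' @param bias_effect_log2fc |Rh - Rp| for biased genes.
#' @param silent_fractions named fractions `silent_S`, `silent_C`.
#' @param specific_expression_frac fraction of families expressed in only a
#'   proper subset of accessions.
#' @param snps_per_gene Poisson mean of diagnostic SNPs per tetraploid gene
#'   (minimum 1).
#' @param fragment_site_fraction expected SNP-informative fragment coverage
#'   per SNP as a fraction of the homeolog's expression level (models reads
#'   not overlapping diagnostic sites).
#' @param max_frag_span maximum diagnostic SNPs spanned by one fragment.
#' @param ambiguous_frac fraction of fragments corrupted into the ambiguous
#'   class (conflicting sites, or a base matching neither parent).
#' @param tissue_effect_sd log-normal sd of the shared per-(gene, tissue)
#'   expression multiplier (first tissue is the reference).
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return scenario list, class `hs_scenario`.
#' @export
sim_scenario <- function(n_genes = 5000, n_reps = 3,
                         tetraploids = "T1", c_populations = "C",
                         tissues = "stem_apex",
                         mean_expression = c(meanlog = log(100), sdlog = 1),
                         baseline_min = 0,
                         nb_dispersion = 0.1,
                         library_size_jitter = 0.2,
                         parent_divergence_frac = 0.5,
                         effect_log2fc = 2,
                         category_fractions = c(intermediate = 0.055,
                                                S_dominance = 0.09,
                                                C_dominance = 0.06,
                                                transgressive_up = 0.03,
                                                transgressive_down = 0.06),
                         bias_fractions = c(S_bias = 0.14, C_bias = 0.07),
                         bias_effect_log2fc = 2,
                         silent_fractions = c(silent_S = 0.035, silent_C = 0.05),
                         specific_expression_frac = 0.3,
                         snps_per_gene = 3,
                         fragment_site_fraction = 0.2,
                         max_frag_span = 2,
                         ambiguous_frac = 0.01,
                         tissue_effect_sd = 0.5,
                         seed = 1) {
  sc <- as.list(environment())
  if (sc$n_reps < 2) hs_stop("scenario: n_reps must be >= 2")
  need <- c("intermediate", "S_dominance", "C_dominance",
            "transgressive_up", "transgressive_down")
  if (!all(need %in% names(sc$category_fractions)))
    hs_stop("scenario: category_fractions must name %s", paste(need, collapse = ", "))
  fr <- c(sc$category_fractions, sc$bias_fractions, sc$silent_fractions,
          sc$specific_expression_frac, sc$ambiguous_frac, sc$parent_divergence_frac)
  if (any(fr < 0 | fr > 1)) hs_stop("scenario: fractions must lie in [0, 1]")
  if (sum(sc$category_fractions) > 1) hs_stop("scenario: category_fractions sum > 1")
  if (sum(sc$bias_fractions) + sum(sc$silent_fractions) > 1)
    hs_stop("scenario: bias + silent fractions sum > 1")
  if (sc$nb_dispersion < 0) hs_stop("scenario: nb_dispersion must be >= 0")
  if (!all(sc$tetraploids %in% c("T1", "T2"))) hs_stop("scenario: tetraploids must be T1/T2")
  structure(sc, class = "hs_scenario")
}

# NB draw with phi = 0 degenerating to Poisson
rnb <- function(mu, phi) {
  y <- integer(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    y[pos] <- if (phi == 0) rpois(sum(pos), mu[pos])
              else rnbinom(sum(pos), size = 1 / phi, mu = mu[pos])
  }
  y
}

#' Simulate a full dataset with ground truth
#'
#' Generates per-gene parental means, tetraploid totals per the assigned
#' inheritance category, homeolog means per parental legacy times the
#' assigned bias factor, replicate NB counts, diagnostic SNPs, and
#' SNP-informative fragments whose parental origin is sampled from the
#' homeolog means. Identical seeds yield identical output.
#'
#' @param scenario `hs_scenario` from [sim_scenario()].
#' @return list of class `hs_simdata`: `counts` (`hs_counts`, diploids +
#'   tetraploid totals, with gene lengths), `snps`, `fragments` (with a
#'   `true_origin` column), `families`, `truth` (per-family ground-truth
#'   labels), `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "hs_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n_genes
  e <- sc$effect_log2fc
  phi <- sc$nb_dispersion
  tets <- sc$tetraploids
  accs <- c("S", sc$c_populations, tets)
  acc_species <- c("S", rep("C", length(sc$c_populations)), tets)
  names(acc_species) <- accs

  ## --- gene-level truth -----------------------------------------------------
  b <- rlnorm(n, sc$mean_expression[["meanlog"]], sc$mean_expression[["sdlog"]])
  b <- pmax(b, sc$baseline_min)
  cat_pr <- c(sc$category_fractions,
              conserved = 1 - sum(sc$category_fractions))
  category <- sample(names(cat_pr), n, replace = TRUE, prob = cat_pr)
  sgn <- sample(c(1, -1), n, replace = TRUE)
  div_trans <- runif(n) < sc$parent_divergence_frac

  mu_s <- mu_c <- mu_t <- b
  i <- category == "intermediate"
  mu_s[i] <- b[i] * 2^(sgn[i] * e); mu_c[i] <- b[i] * 2^(-sgn[i] * e)
  i <- category == "S_dominance"
  mu_c[i] <- b[i] * 2^(sgn[i] * e)                       # T stays equal to S
  i <- category == "C_dominance"
  mu_s[i] <- b[i] * 2^(sgn[i] * e)                       # T stays equal to C
  i <- category == "transgressive_up"
  lo <- i & div_trans & sgn > 0; mu_c[lo] <- b[lo] * 2^(-e)
  lo <- i & div_trans & sgn < 0; mu_s[lo] <- b[lo] * 2^(-e)
  mu_t[i] <- b[i] * 2^e
  i <- category == "transgressive_down"
  hi <- i & div_trans & sgn > 0; mu_c[hi] <- b[hi] * 2^e
  hi <- i & div_trans & sgn < 0; mu_s[hi] <- b[hi] * 2^e
  mu_t[i] <- b[i] * 2^(-e)

  # homeolog fate: bias, silent, or plain parental legacy
  fate_pr <- c(sc$bias_fractions["S_bias"], sc$bias_fractions["C_bias"],
               sc$silent_fractions["silent_S"], sc$silent_fractions["silent_C"])
  fate_pr <- c(fate_pr, none = 1 - sum(fate_pr))
  names(fate_pr) <- c("S_bias", "C_bias", "silent_S", "silent_C", "none")
  fate <- sample(names(fate_pr), n, replace = TRUE, prob = fate_pr)
  bias_class <- ifelse(fate %in% c("S_bias", "C_bias"), fate, "none")
  silent_s <- fate == "silent_S"
  silent_c <- fate == "silent_C"
  delta <- ifelse(bias_class == "C_bias", sc$bias_effect_log2fc,
                  ifelse(bias_class == "S_bias", -sc$bias_effect_log2fc, 0))
  q <- (mu_c / mu_s) * 2^delta          # target C:S homeolog ratio
  h_c <- mu_t * q / (1 + q)
  h_s <- mu_t - h_c
  h_s[silent_s] <- 0; h_c[silent_s] <- mu_t[silent_s]
  h_c[silent_c] <- 0; h_s[silent_c] <- mu_t[silent_c]

  # species-specificity: proper, non-empty accession subsets for a fraction
  expr_acc <- matrix(TRUE, n, length(accs), dimnames = list(NULL, accs))
  spec <- which(runif(n) < sc$specific_expression_frac)
  if (length(spec)) {
    sub <- matrix(runif(length(spec) * length(accs)) < 0.6,
                  nrow = length(spec))
    none_on <- rowSums(sub) == 0
    sub[cbind(which(none_on), sample.int(length(accs), sum(none_on), TRUE))] <- TRUE
    all_on <- rowSums(sub) == length(accs)
    sub[cbind(which(all_on), sample.int(length(accs), sum(all_on), TRUE))] <- FALSE
    expr_acc[spec, ] <- sub
  }

  ## --- ids, lengths, families ----------------------------------------------
  species_list <- c("S", "C", tets)
  gid <- function(sp) sprintf("%s_g%06d", sp, seq_len(n))
  gene_ids <- lapply(setNames(species_list, species_list), gid)
  lens <- lapply(setNames(species_list, species_list), function(sp) {
    l <- pmax(150L, as.integer(round(rlnorm(n, log(1000), 0.45))))
    setNames(l, gene_ids[[sp]])
  })
  families <- do.call(rbind, lapply(species_list, function(sp) {
    data.frame(family_id = sprintf("fam%06d", seq_len(n)), species_code = sp,
               gene_id = gene_ids[[sp]], stringsAsFactors = FALSE)
  }))
  families <- families[order(families$family_id, families$species_code), ]
  rownames(families) <- NULL

  ## --- samples and library factors ------------------------------------------
  samples <- expand.grid(replicate = seq_len(sc$n_reps), tissue = sc$tissues,
                         accession = accs, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("accession", "tissue", "replicate")]
  samples$species_code <- acc_species[samples$accession]
  samples$population <- ifelse(samples$accession == samples$species_code,
                               NA_character_, samples$accession)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$accession, samples$tissue,
                               samples$replicate)
  j <- sc$library_size_jitter
  libfac <- runif(nrow(samples), 1 - j, 1 + j)

  # shared per-(gene, tissue) multiplier; first tissue is reference
  m_tissue <- matrix(1, n, length(sc$tissues), dimnames = list(NULL, sc$tissues))
  if (length(sc$tissues) > 1) {
    for (t in sc$tissues[-1]) m_tissue[, t] <- rlnorm(n, 0, sc$tissue_effect_sd)
  }

  ## --- diagnostic SNPs per tetraploid gene ----------------------------------
  k <- 1L + rpois(n, max(0, sc$snps_per_gene - 1))
  snps_by_tet <- list()
  for (tt in tets) {
    len_t <- unname(lens[[tt]])
    kk <- pmin(k, len_t)   # cannot exceed positions available
    pos_list <- lapply(seq_len(n), function(g) sort(sample.int(len_t[g], kk[g])))
    tot <- sum(kk)
    a_s <- sample(BASES, tot, replace = TRUE)
    shift <- sample.int(3, tot, replace = TRUE)
    a_c <- BASES[((match(a_s, BASES) - 1L + shift) %% 4L) + 1L]
    snps_by_tet[[tt]] <- data.frame(
      unigene_id = rep(gene_ids[[tt]], kk),
      pos = unlist(pos_list),
      allele_S = a_s, allele_C = a_c,
      gene_idx = rep(seq_len(n), kk),
      stringsAsFactors = FALSE
    )
  }
  k_by_tet <- lapply(tets, function(tt) pmin(k, unname(lens[[tt]])))
  names(k_by_tet) <- tets

  ## --- counts and fragments --------------------------------------------------
  n_rows <- n * length(species_list)
  counts <- matrix(0L, n_rows, nrow(samples),
                   dimnames = list(unlist(gene_ids, use.names = FALSE),
                                   samples$sample_id))
  row_off <- setNames((seq_along(species_list) - 1L) * n, species_list)
  frag_chunks <- list()
  for (si in seq_len(nrow(samples))) {
    acc <- samples$accession[si]; sp <- acc_species[[acc]]
    tis <- samples$tissue[si]
    fac <- libfac[si] * m_tissue[, tis] * as.numeric(expr_acc[, acc])
    sid <- samples$sample_id[si]
    if (!sp %in% tets) {
      mu <- (if (sp == "S") mu_s else mu_c) * fac
      counts[row_off[[sp]] + seq_len(n), si] <- rnb(mu, phi)
    } else {
      # gene-level biological noise hits the total; each fragment's parental
      # origin is then sampled in proportion to the homeolog means, so the
      # within-sample S:C split is binomial given the total
      y_tot <- rnb(mu_t * fac, phi)
      counts[row_off[[sp]] + seq_len(n), si] <- y_tot
      p_c <- ifelse(h_s + h_c > 0, h_c / (h_s + h_c), 0)
      frag_chunks[[sid]] <- sim_fragments_sample(
        sid, gene_ids[[sp]], snps_by_tet[[sp]], k_by_tet[[sp]], y_tot, p_c, sc)
    }
  }
  fragments <- data.table::rbindlist(frag_chunks)
  fragments <- as.data.frame(fragments, stringsAsFactors = FALSE)

  ## --- truth table ------------------------------------------------------------
  expressed_sig <- apply(expr_acc, 1, function(r) paste(accs[r], collapse = "&"))
  truth <- data.frame(
    family_id = sprintf("fam%06d", seq_len(n)),
    gene_id_S = gene_ids[["S"]], gene_id_C = gene_ids[["C"]],
    true_group = category,
    true_bias = bias_class,
    silent_S = silent_s, silent_C = silent_c,
    mu_S = mu_s, mu_C = mu_c, mu_T = mu_t,
    true_rh = ifelse(h_s > 0 & h_c > 0, log2(h_c / h_s), NA_real_),
    true_rp = log2(mu_c / mu_s),
    expressed_accessions = expressed_sig,
    stringsAsFactors = FALSE
  )
  for (tt in tets) truth[[paste0("gene_id_", tt)]] <- gene_ids[[tt]]

  meta <- samples[, c("sample_id", "species_code", "population", "tissue", "replicate")]
  cm <- new_hs_counts(counts, meta, unlist(unname(lens)))
  snps <- do.call(rbind, lapply(snps_by_tet, function(s) s[setdiff(names(s), "gene_idx")]))
  rownames(snps) <- NULL
  hs_log("simulate_dataset: %d families, %d samples, %d fragments (seed %d)",
         n, nrow(samples), nrow(fragments), sc$seed)
  structure(list(counts = cm, snps = snps, fragments = fragments,
                 families = families, truth = truth, scenario = sc),
            class = "hs_simdata")
}

# fragments for one tetraploid sample: per-fragment parental origin drawn
# with probability proportional to the homeolog means, each fragment spanning
# 1..max_frag_span adjacent diagnostic SNPs; expected per-SNP coverage is
# fragment_site_fraction * total count
sim_fragments_sample <- function(sid, genes, snps, k, y_tot, p_c, sc) {
  span_max <- pmax(1L, pmin(k, sc$max_frag_span))
  e_span <- (1 + span_max) / 2
  n_f <- round(y_tot * sc$fragment_site_fraction * k / e_span)
  g <- rep(seq_along(genes), n_f)
  fr <- NULL
  if (length(g)) {
    origin <- ifelse(runif(length(g)) < p_c[g], "C", "S")
    s <- 1L + floor(runif(length(g)) * span_max[g])
    start <- 1L + floor(runif(length(g)) * (k[g] - s + 1L))
    fr <- data.table::data.table(gene_idx = g, origin = origin, span = s,
                                 start = start)
  }
  if (is.null(fr) || nrow(fr) == 0) {
    return(data.table::data.table(fragment_id = character(0), sample_id = character(0),
                                  unigene_id = character(0), allele_calls = character(0),
                                  true_origin = character(0)))
  }
  # SNP row lookup: offset of each gene's first SNP in `snps` (generated in order)
  off <- c(0L, cumsum(k))[seq_along(genes)]
  amb <- runif(nrow(fr)) < sc$ambiguous_frac
  calls <- character(nrow(fr))
  for (v in sort(unique(fr$span))) {
    idx <- which(fr$span == v)
    rows0 <- off[fr$gene_idx[idx]] + fr$start[idx] - 1L
    parts <- vector("list", v)
    for (jj in seq_len(v)) {
      r <- rows0 + jj
      base <- ifelse(fr$origin[idx] == "S", snps$allele_S[r], snps$allele_C[r])
      corrupt <- amb[idx] & jj == 1L
      if (any(corrupt)) {
        if (v >= 2L) {
          # conflicting site: first site shows the other parent's allele
          base[corrupt] <- ifelse(fr$origin[idx][corrupt] == "S",
                                  snps$allele_C[r][corrupt], snps$allele_S[r][corrupt])
        } else {
          # single-site fragment: a base matching neither parent
          base[corrupt] <- vapply(which(corrupt), function(w) {
            sample(setdiff(BASES, c(snps$allele_S[r[w]], snps$allele_C[r[w]])), 1)
          }, character(1))
        }
      }
      parts[[jj]] <- paste0(snps$pos[r], "=", base)
    }
    calls[idx] <- do.call(function(...) paste(..., sep = ";"), parts)
  }
  data.table::data.table(
    fragment_id = sprintf("f%07d", seq_len(nrow(fr))),
    sample_id = sid,
    unigene_id = genes[fr$gene_idx],
    allele_calls = calls,
    true_origin = ifelse(amb, "ambiguous", fr$origin)
  )
}

#' Packaged demonstration scenario
#'
#' A compact scenario emulating the full study design: maternal-type diploid
#' S, two populations of the paternal-type diploid C, two independently
#' formed allotetraploids, two tissues, three replicates, with the default
#' asymmetric bias and silencing fractions.
#'
#' @param n_genes number of families (kept small so the demo runs in seconds).
#' @param seed RNG seed.
#' @return `hs_scenario`.
#' @export
demo_scenario <- function(n_genes = 300, seed = 42) {
  sim_scenario(n_genes = n_genes, seed = seed,
               tetraploids = c("T1", "T2"),
               c_populations = c("acuARX", "acuQL"),
               tissues = c("stem_apex", "leaf"),
               mean_expression = c(meanlog = log(200), sdlog = 0.8))
}

#' Write a simulated dataset to a directory
#'
#' Emits counts.tsv, samples.tsv, lengths.tsv, snps.tsv, fragments.tsv,
#' families.tsv and truth.tsv in the canonical TSV dialects.
#'
#' @param sim `hs_simdata`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simdata <- function(sim, dir) {
  stopifnot(inherits(sim, "hs_simdata"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"),
                     file.path(dir, "samples.tsv"))
  write_gene_lengths(sim$counts$gene_lengths, file.path(dir, "lengths.tsv"))
  write_snp_table(sim$snps, file.path(dir, "snps.tsv"))
  write_fragments(sim$fragments, file.path(dir, "fragments.tsv"))
  write_family_map(sim$families, file.path(dir, "families.tsv"))
  hs_write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
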