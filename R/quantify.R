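# Expression-level computation (FPKM), TMM normalization, expressed-gene
# filtering, replicate QC, and species-specificity / coexpression set analysis
# over ortholog families.

#' Fragments per kilobase per million (FPKM)
#'
#' @param count read count(s) for the gene.
#' @param gene_length_bp gene (unigene) length in bp, >= 1.
#' @param library_total_counts total mapped fragments in the library, >= 1.
#' @return `count / ((library_total / 1e6) * (gene_length / 1e3))`.
#' @export
compute_fpkm <- function(count, gene_length_bp, library_total_counts) {
  if (any(gene_length_bp < 1)) hs_stop("compute_fpkm: zero or negative gene length")
  if (any(library_total_counts < 1)) hs_stop("compute_fpkm: library total must be >= 1")
  count / ((library_total_counts / 1e6) * (gene_length_bp / 1e3))
}

#' FPKM matrix for a count object
#'
#' @param x `hs_counts` with gene lengths.
#' @return numeric matrix, genes x samples.
#' @export
fpkm_matrix <- function(x) {
  stopifnot(inherits(x, "hs_counts"))
  if (is.null(x$gene_lengths)) hs_stop("fpkm_matrix: gene lengths are required for FPKM")
  lib <- colSums(x$counts)
  sweep(x$counts / (x$gene_lengths / 1e3), 2, lib / 1e6, "/")
}

# -- TMM ----------------------------------------------------------------------

# one pairwise TMM factor (Robinson-Oshlack): double-trimmed (M 30%, A 5%)
# precision-weighted mean of per-gene log ratios against the reference
tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                     log_ratio_trim = 0.3, abundance_trim = 0.05) {
  op <- obs / lib_obs
  rp <- ref / lib_ref
  fin <- obs > 0 & ref > 0
  logR <- log2(op[fin] / rp[fin])
  absE <- (log2(op[fin]) + log2(rp[fin])) / 2
  v <- (lib_obs - obs[fin]) / (lib_obs * obs[fin]) +
    (lib_ref - ref[fin]) / (lib_ref * ref[fin])
  n <- length(logR)
  if (n == 0) return(1)
  loL <- floor(n * log_ratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * abundance_trim) + 1; hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f) || abs(f) < 1e-6) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values factors across libraries. Per-gene log-ratios (M)
#' and log-abundances (A) against a reference library are double-trimmed
#' (M: 30%, A: 5%), the retained M values are averaged with inverse
#' binomial-variance weights, and the factors are rescaled to geometric mean 1.
#' Genes with a zero count in either library of a pair are excluded from that
#' pair's M/A values. Effective library size = raw size x factor.
#'
#' @param counts integer matrix, genes x samples (>= 2 samples).
#' @param lib_sizes library sizes; default column sums.
#' @param ref_sample reference column name or index; default is the library
#'   whose upper-quartile (of count proportions) is closest to the mean
#'   upper-quartile.
#' @return named vector of normalization factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts), ref_sample = NULL) {
  if (ncol(counts) < 2) hs_stop("tmm_factors: >= 2 samples required")
  if (any(lib_sizes == 0)) hs_stop("tmm_factors: sample with all-zero counts")
  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, lib_sizes, "/"), 2, quantile, probs = 0.75)
    ref_sample <- which.min(abs(f75 - mean(f75)))
  }
  if (is.character(ref_sample)) ref_sample <- match(ref_sample, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_sample) return(1)
    tmm_pair(counts[, j], counts[, ref_sample], lib_sizes[j], lib_sizes[ref_sample])
  }, numeric(1))
  f <- f / geo_mean(f)
  setNames(f, colnames(counts))
}

# -- expressed-gene calls -----------------------------------------------------

#' Expression profile: FPKM, per-group means, and expressed calls
#'
#' Groups are (accession, tissue) combinations. A gene is expressed in a group
#' when its mean FPKM across the group's replicates is strictly greater than
#' `fpkm_expressed` and its length is at least `min_gene_length_bp` (the
#' reliable-unigene filter).
#'
#' @param x `hs_counts` with gene lengths.
#' @param config `hs_config` (or list) supplying `fpkm_expressed` and
#'   `min_gene_length_bp`.
#' @return list: `fpkm` (genes x samples), `group_mean_fpkm` (genes x groups),
#'   `expressed` (logical, genes x groups), `groups` (data.frame accession,
#'   tissue, group id).
#' @export
expression_profile <- function(x, config = load_config()) {
  fpkm <- fpkm_matrix(x)
  s <- x$samples
  grp_id <- paste(s$accession, s$tissue, sep = "|")
  groups <- unique(data.frame(group = grp_id, accession = s$accession,
                              tissue = s$tissue, species_code = s$species_code,
                              stringsAsFactors = FALSE))
  gm <- vapply(groups$group, function(g) {
    rowMeans(fpkm[, grp_id == g, drop = FALSE])
  }, numeric(nrow(fpkm)))
  rownames(gm) <- rownames(fpkm)
  expressed <- call_expressed(gm, x$gene_lengths,
                              min_fpkm = config$fpkm_expressed,
                              min_length_bp = config$min_gene_length_bp)
  hs_log("expression_profile: %d genes, %d groups; expressed calls per group: %s",
         nrow(gm), ncol(gm), paste(colSums(expressed), collapse = ", "))
  list(fpkm = fpkm, group_mean_fpkm = gm, expressed = expressed, groups = groups)
}

#' Expressed-gene filter
#'
#' @param mean_fpkm matrix (or vector) of replicate-mean FPKM values.
#' @param gene_lengths lengths (bp) aligned with rows of `mean_fpkm`.
#' @param min_fpkm expressed iff mean FPKM strictly exceeds this (default 1).
#' @param min_length_bp reliable-unigene length floor (default 200).
#' @return logical matrix/vector of expressed calls.
#' @export
call_expressed <- function(mean_fpkm, gene_lengths, min_fpkm = 1, min_length_bp = 200) {
  ok_len <- gene_lengths >= min_length_bp
  if (is.matrix(mean_fpkm)) {
    sweep(mean_fpkm > min_fpkm, 1, ok_len, "&")
  } else {
    (mean_fpkm > min_fpkm) & ok_len
  }
}

# -- specificity / coexpression sets ------------------------------------------

#' Species-specificity and coexpression analysis over ortholog families
#'
#' A family counts as expressed in an accession when at least one of its member
#' genes for that accession's species is expressed there (any-member
#' semantics; copy numbers may differ among species). Every region of the
#' resulting n-set Venn partition is reported, keyed by the sorted accession
#' signature (e.g. `"T1"` = tetraploid-specific; `"C&S"` = expressed in both
#' parents but absent from the tetraploid, the silencing-or-loss region).
#'
#' @param profile result of [expression_profile()].
#' @param families ortholog family map (see [read_family_map()]).
#' @param accessions accessions to include; default all in the profile.
#' @param tissue restrict to one tissue; default: expressed in any tissue.
#' @return list: `membership` (family_id, signature), `regions` (named counts
#'   over signatures), `n_excluded` (families with no member in any supplied
#'   accession), `n_unexpressed` (families expressed nowhere).
#' @export
specificity_analysis <- function(profile, families, accessions = NULL, tissue = NULL) {
  grp <- profile$groups
  if (!is.null(tissue)) grp <- grp[grp$tissue == tissue, , drop = FALSE]
  if (is.null(accessions)) accessions <- unique(grp$accession)
  grp <- grp[grp$accession %in% accessions, , drop = FALSE]
  if (nrow(grp) == 0) hs_stop("specificity_analysis: no matching accession groups")

  # expressed gene set per accession (any tissue within the restriction)
  acc_expr <- lapply(split(grp$group, grp$accession), function(g) {
    rownames(profile$expressed)[rowSums(profile$expressed[, g, drop = FALSE]) > 0]
  })
  acc_species <- vapply(split(grp$species_code, grp$accession), `[`, character(1), 1)

  fam_split <- split(paste(families$species_code, families$gene_id, sep = "\r"),
                     families$family_id)
  sigs <- vapply(fam_split, function(members) {
    sp <- sub("\r.*", "", members)
    gid <- sub(".*\r", "", members)
    hit <- vapply(names(acc_expr), function(a) {
      any(gid[sp == acc_species[[a]]] %in% acc_expr[[a]])
    }, logical(1))
    present <- any(sp %in% acc_species)
    if (!present) return(NA_character_)
    paste(sort(names(acc_expr)[hit]), collapse = "&")
  }, character(1))

  n_excluded <- sum(is.na(sigs))
  membership <- data.frame(family_id = names(sigs)[!is.na(sigs)],
                           signature = sigs[!is.na(sigs)],
                           row.names = NULL, stringsAsFactors = FALSE)
  n_unexpressed <- sum(membership$signature == "")
  expressed_any <- membership[membership$signature != "", , drop = FALSE]
  regions <- table(expressed_any$signature)
  regions <- setNames(as.integer(regions), names(regions))
  hs_log("specificity_analysis: %d families (%d excluded, %d unexpressed), %d regions",
         length(sigs), n_excluded, n_unexpressed, length(regions))
  list(membership = membership, regions = regions,
       n_excluded = n_excluded, n_unexpressed = n_unexpressed)
}

# -- replicate QC -------------------------------------------------------------

#' Replicate correlation QC
#'
#' Pearson correlation of log2(FPKM + 1) for every pair of samples within the
#' same accession. Within-group pairs (same tissue) are flagged when their
#' correlation falls below the accession's maximum between-tissue correlation.
#'
#' @param x `hs_counts` with gene lengths.
#' @return data.frame: sample_a, sample_b, accession, type (within/between),
#'   correlation, flagged.
#' @export
replicate_correlation_qc <- function(x) {
  lf <- log2(fpkm_matrix(x) + 1)
  s <- x$samples
  out <- list()
  for (acc in unique(s$accession)) {
    ids <- s$sample_id[s$accession == acc]
    if (length(ids) < 2) next
    # only genes informative for this accession
    sub <- lf[rowSums(lf[, ids, drop = FALSE]) > 0, ids, drop = FALSE]
    cm <- cor(sub, method = "pearson")
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    tis <- setNames(s$tissue, s$sample_id)
    df <- data.frame(
      sample_a = rownames(cm)[pairs[, 1]], sample_b = colnames(cm)[pairs[, 2]],
      accession = acc,
      type = ifelse(tis[rownames(cm)[pairs[, 1]]] == tis[colnames(cm)[pairs[, 2]]],
                    "within", "between"),
      correlation = cm[pairs], stringsAsFactors = FALSE
    )
    max_between <- if (any(df$type == "between")) max(df$correlation[df$type == "between"]) else -Inf
    df$flagged <- df$type == "within" & df$correlation < max_between
    out[[acc]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$flagged))
    hs_log("replicate_correlation_qc: %d within-group pair(s) flagged", sum(res$flagged))
  res
}
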