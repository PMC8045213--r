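# Partition allotetraploid fragments into parental homeolog bins via
# diagnostic SNPs, aggregate homeolog-level counts, and flag silent/lost
# homeologs.

# expand serialized allele calls into one row per (fragment, site)
expand_allele_calls <- function(fragments) {
  sp <- strsplit(fragments$allele_calls, ";", fixed = TRUE)
  n <- lengths(sp)
  flat <- unlist(sp, use.names = FALSE)
  eq <- regmatches(flat, regexpr("=", flat, fixed = TRUE), invert = TRUE)
  long <- data.table::data.table(
    frag_idx = rep(seq_len(nrow(fragments)), n),
    pos = suppressWarnings(as.integer(vapply(eq, `[`, character(1), 1L))),
    base = vapply(eq, `[`, character(1), 2L)
  )
  if (anyNA(long$pos))
    hs_stop("fragments: malformed allele_calls for fragment %s",
            fragments$fragment_id[long$frag_idx[which(is.na(long$pos))[1]]])
  long$unigene_id <- fragments$unigene_id[long$frag_idx]
  long
}

#' Partition fragments into parental homeolog bins
#'
#' A fragment is assigned to the S bin when every base it shows matches the
#' maternal-type (S) diagnostic allele at its position, to the C bin when every
#' base matches the paternal-type (C) allele, and to `ambiguous` otherwise
#' (conflicting sites, or a base matching neither parent -- the
#' sequencing-error class). Every observed position must exist in the SNP
#' table for that unigene.
#'
#' @param fragments fragment table (see [read_fragments()]).
#' @param snps diagnostic-SNP table (see [read_snp_table()]).
#' @return the fragment table with columns `bin` (`"S"`, `"C"`, `"ambiguous"`)
#'   and `n_sites` appended.
#' @export
partition_fragments <- function(fragments, snps) {
  fragments <- validate_fragments(as.data.frame(fragments))
  snps <- validate_snp_table(as.data.frame(snps))
  long <- expand_allele_calls(fragments)
  snp_dt <- data.table::as.data.table(snps)
  data.table::setkey(snp_dt, unigene_id, pos)
  long <- snp_dt[long, on = c("unigene_id", "pos")]
  unknown <- is.na(long$allele_S)
  if (any(unknown)) {
    bad <- unique(fragments$fragment_id[long$frag_idx[unknown]])
    hs_stop("fragments reference unknown SNP position(s); fragment_id: %s",
            paste(head(bad, 10), collapse = ", "))
  }
  long[, `:=`(m_s = base == allele_S, m_c = base == allele_C)]
  agg <- long[, .(all_s = all(m_s), all_c = all(m_c), n_sites = .N), by = frag_idx]
  bin <- rep("ambiguous", nrow(fragments))
  bin[agg$frag_idx[agg$all_s]] <- "S"
  bin[agg$frag_idx[agg$all_c]] <- "C"
  fragments$bin <- bin
  fragments$n_sites <- 0L
  fragments$n_sites[agg$frag_idx] <- agg$n_sites
  hs_log("partition_fragments: %d fragments -> S %d, C %d, ambiguous %d",
         nrow(fragments), sum(bin == "S"), sum(bin == "C"), sum(bin == "ambiguous"))
  fragments
}

#' Homeolog-level counts from partitioned fragments
#'
#' For each (unigene, sample, parent): every diagnostic SNP of the unigene is
#' covered by some number of that parent's fragments, and the homeolog count
#' is the mean of these per-SNP counts over the unigene's diagnostic SNPs
#' (equivalently, total informative fragment-site observations divided by the
#' number of diagnostic SNPs). Counts may therefore be non-integer; exact
#' tests downstream round them. An alternative `"sum"` mode totals the per-SNP
#' counts instead, for sensitivity analysis. Ambiguous fragments are excluded
#' from counts but reported.
#'
#' @param partitioned output of [partition_fragments()].
#' @param snps diagnostic-SNP table (defines each unigene's SNP denominator).
#' @param mode `"mean"` (default) or `"sum"` aggregation over SNPs.
#' @return data.frame: unigene_id, sample_id, count_S, count_C, n_snps_used,
#'   n_ambiguous.
#' @export
homeolog_counts <- function(partitioned, snps, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (is.null(partitioned$bin)) hs_stop("homeolog_counts: run partition_fragments first")
  snps <- validate_snp_table(as.data.frame(snps))
  n_snps <- table(snps$unigene_id)
  long <- expand_allele_calls(partitioned)
  long$sample_id <- partitioned$sample_id[long$frag_idx]
  long$bin <- partitioned$bin[long$frag_idx]
  inf <- long[long$bin != "ambiguous"]
  # per (unigene, sample, parent): total fragment-site observations and
  # distinct sites seen
  agg <- inf[, .(pairs = .N, sites = data.table::uniqueN(pos)),
             by = .(unigene_id, sample_id, bin)]
  wide <- as.data.frame(data.table::dcast(agg, unigene_id + sample_id ~ bin,
                                          value.var = c("pairs", "sites"), fill = 0))
  for (cl in c("pairs_S", "pairs_C", "sites_S", "sites_C"))
    if (is.null(wide[[cl]])) wide[[cl]] <- rep(0, nrow(wide))
  amb <- partitioned[partitioned$bin == "ambiguous", c("unigene_id", "sample_id")]
  amb_n <- data.table::as.data.table(amb)[, .(n_ambiguous = .N), by = .(unigene_id, sample_id)]
  # rows that only have ambiguous fragments still appear, flagged with zeros
  wide <- merge(wide, amb_n, by = c("unigene_id", "sample_id"), all = TRUE)
  for (cl in c("pairs_S", "pairs_C", "sites_S", "sites_C", "n_ambiguous"))
    wide[[cl]][is.na(wide[[cl]])] <- 0
  denom <- as.numeric(n_snps[wide$unigene_id])
  no_snp <- is.na(denom)
  if (any(no_snp)) {
    hs_log("homeolog_counts: excluding %d row(s) for unigene(s) without diagnostic SNPs",
           sum(no_snp))
    wide <- wide[!no_snp, , drop = FALSE]; denom <- denom[!no_snp]
  }
  out <- data.frame(
    unigene_id = wide$unigene_id, sample_id = wide$sample_id,
    count_S = if (mode == "mean") wide$pairs_S / denom else as.numeric(wide$pairs_S),
    count_C = if (mode == "mean") wide$pairs_C / denom else as.numeric(wide$pairs_C),
    n_snps_used = pmax(wide$sites_S, wide$sites_C),
    n_ambiguous = as.integer(wide$n_ambiguous),
    stringsAsFactors = FALSE
  )
  hs_log("homeolog_counts: %d (unigene, sample) rows (%s over SNPs)", nrow(out), mode)
  out
}

#' Homeolog count matrices for one tetraploid tissue
#'
#' Reshapes the long homeolog count table into aligned genes x replicate
#' matrices for the S- and C-homeolog, restricted to the given samples.
#'
#' @param hom long table from [homeolog_counts()].
#' @param sample_ids replicate sample ids (one tetraploid x tissue group).
#' @return list with matrices `S` and `C` (same dimnames) .
#' @export
homeolog_count_matrices <- function(hom, sample_ids) {
  sub <- hom[hom$sample_id %in% sample_ids, , drop = FALSE]
  genes <- sort(unique(sub$unigene_id))
  S <- C <- matrix(0, length(genes), length(sample_ids),
                   dimnames = list(genes, sample_ids))
  iS <- cbind(match(sub$unigene_id, genes), match(sub$sample_id, sample_ids))
  S[iS] <- sub$count_S
  C[iS] <- sub$count_C
  list(S = S, C = C)
}

#' Detect silent or lost homeologs
#'
#' A homeolog is silent/lost when its count is zero in all replicates of the
#' tissue while the other homeolog shows expression (nonzero count in at least
#' one replicate) and the corresponding diploid ortholog is expressed. Genes
#' are testable when both diploid orthologs are expressed and at least one
#' homeolog was observed; percentages use the testable denominator.
#'
#' @param mats list of matrices from [homeolog_count_matrices()].
#' @param parent_expressed_S,parent_expressed_C named logical vectors: is the
#'   ortholog expressed in the corresponding diploid? Names are tetraploid
#'   unigene ids (aligned via the family map upstream).
#' @return list: `flags` data.frame (unigene_id, silent_S, silent_C, testable),
#'   `n_testable`, `n_silent_S`, `n_silent_C`, `pct_silent_S`, `pct_silent_C`.
#' @export
detect_silent_homeologs <- function(mats, parent_expressed_S, parent_expressed_C) {
  genes <- rownames(mats$S)
  expS <- parent_expressed_S[genes]; expS[is.na(expS)] <- FALSE
  expC <- parent_expressed_C[genes]; expC[is.na(expC)] <- FALSE
  zero_S <- rowSums(mats$S > 0) == 0
  zero_C <- rowSums(mats$C > 0) == 0
  testable <- expS & expC & !(zero_S & zero_C)
  silent_S <- testable & zero_S & !zero_C
  silent_C <- testable & zero_C & !zero_S
  n_testable <- sum(testable)
  res <- list(
    flags = data.frame(unigene_id = genes, silent_S = unname(silent_S),
                       silent_C = unname(silent_C), testable = unname(testable),
                       stringsAsFactors = FALSE),
    n_testable = n_testable,
    n_silent_S = sum(silent_S), n_silent_C = sum(silent_C),
    pct_silent_S = 100 * sum(silent_S) / max(1, n_testable),
    pct_silent_C = 100 * sum(silent_C) / max(1, n_testable)
  )
  hs_log("detect_silent_homeologs: %d testable, silent S %d (%.2f%%), silent C %d (%.2f%%)",
         n_testable, res$n_silent_S, res$pct_silent_S, res$n_silent_C, res$pct_silent_C)
  res
}
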