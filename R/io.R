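# Readers/writers for the tabular formats shared by every stage.
#
# Conventions (all formats): tab-separated, UTF-8, '#' comment lines ignored,
# '.' denotes a missing value. Downstream modules consume only the validated
# objects returned here, never raw paths.

SPECIES_CODES <- c("S", "C", "T1", "T2")
TISSUES <- c("stem_apex", "leaf")

# -- low-level TSV helpers ----------------------------------------------------

hs_read_tsv <- function(path, colClasses = NULL) {
  if (!file.exists(path)) hs_stop("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(lines)]
  if (length(lines) < 1L) hs_stop("empty table: %s", path)
  dt <- data.table::fread(
    text = lines, sep = "\t", header = TRUE, na.strings = ".",
    colClasses = colClasses, keepLeadingZeros = TRUE
  )
  as.data.frame(dt, stringsAsFactors = FALSE)
}

hs_write_tsv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]][is.na(df[[j]])] <- "."
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = ".", eol = "\n")
  invisible(path)
}

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) hs_stop("%s: missing column(s): %s", what, paste(miss, collapse = ", "))
}

# -- sample metadata ----------------------------------------------------------

#' Validate sample metadata
#'
#' Checks the invariants of the sample sheet: unique sample ids, known species
#' codes and tissues, positive integer replicates, and at least two replicates
#' in every (species, population, tissue) group (dispersion estimation and the
#' exact tests require replication).
#'
#' @param samples data.frame with columns `sample_id`, `species_code`,
#'   `population`, `tissue`, `replicate`.
#' @return the validated data.frame, with an `accession` column added
#'   (population id when present, otherwise the species code).
#' @export
validate_samples <- function(samples) {
  need_cols(samples, c("sample_id", "species_code", "population", "tissue", "replicate"),
            "samples")
  samples$sample_id <- as.character(samples$sample_id)
  samples$species_code <- as.character(samples$species_code)
  samples$population <- as.character(samples$population)
  samples$tissue <- as.character(samples$tissue)
  if (anyDuplicated(samples$sample_id))
    hs_stop("samples: duplicated sample_id: %s",
            paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(samples$species_code), SPECIES_CODES)
  if (length(bad)) hs_stop("samples: unknown species_code: %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(samples$tissue), TISSUES)
  if (length(bad)) hs_stop("samples: unknown tissue: %s", paste(bad, collapse = ", "))
  rep_num <- suppressWarnings(as.integer(samples$replicate))
  if (anyNA(rep_num) || any(rep_num < 1L))
    hs_stop("samples: replicate must be a positive integer")
  samples$replicate <- rep_num
  samples$accession <- ifelse(is.na(samples$population) | samples$population == "",
                              samples$species_code, samples$population)
  grp <- paste(samples$accession, samples$tissue)
  n_by_grp <- table(grp)
  if (any(n_by_grp < 2L))
    hs_stop("samples: group(s) with < 2 replicates: %s",
            paste(names(n_by_grp)[n_by_grp < 2L], collapse = ", "))
  samples
}

# -- count matrix -------------------------------------------------------------

#' Read a gene-level count matrix with its sample metadata
#'
#' The count table is a TSV whose first column is `gene_id` and whose remaining
#' columns are sample ids; cells are non-negative integers. Metadata rows and
#' count columns must match one-to-one.
#'
#' @param path count TSV.
#' @param meta_path sample-metadata TSV (`sample_id`, `species_code`,
#'   `population`, `tissue`, `replicate`).
#' @param lengths_path optional gene-length TSV (`gene_id`, `length_bp`);
#'   required later for FPKM.
#' @return an object of class `hs_counts`: list with `counts` (integer matrix,
#'   genes x samples), `samples` (validated metadata), `gene_lengths` (named
#'   integer vector or `NULL`).
#' @export
read_count_matrix <- function(path, meta_path, lengths_path = NULL) {
  raw <- hs_read_tsv(path)
  need_cols(raw, "gene_id", "counts")
  gene_ids <- as.character(raw$gene_id)
  if (anyDuplicated(gene_ids))
    hs_stop("counts: duplicated gene_id: %s",
            paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  mat_cols <- setdiff(names(raw), "gene_id")
  m <- matrix(0L, nrow = length(gene_ids), ncol = length(mat_cols),
              dimnames = list(gene_ids, mat_cols))
  for (j in mat_cols) {
    v <- raw[[j]]
    vi <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vi) | vi < 0 | vi != floor(vi))
    if (length(bad))
      hs_stop("counts: non-integer or negative value '%s' at gene %s, sample %s",
              as.character(v[bad[1]]), gene_ids[bad[1]], j)
    m[, j] <- as.integer(vi)
  }
  samples <- validate_samples(hs_read_tsv(meta_path))
  extra <- setdiff(colnames(m), samples$sample_id)
  if (length(extra)) hs_stop("counts: sample column(s) absent from metadata: %s",
                             paste(extra, collapse = ", "))
  miss <- setdiff(samples$sample_id, colnames(m))
  if (length(miss)) hs_stop("metadata sample(s) absent from count columns: %s",
                            paste(miss, collapse = ", "))
  m <- m[, samples$sample_id, drop = FALSE]
  lens <- NULL
  if (!is.null(lengths_path)) lens <- read_gene_lengths(lengths_path, gene_ids)
  hs_log("read_count_matrix: %d genes x %d samples from %s", nrow(m), ncol(m), path)
  new_hs_counts(m, samples, lens)
}

#' Construct a validated count-matrix object in memory
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param samples sample metadata (see [validate_samples()]).
#' @param gene_lengths optional named vector of gene lengths (bp).
#' @return `hs_counts` object.
#' @export
new_hs_counts <- function(counts, samples, gene_lengths = NULL) {
  samples <- validate_samples(samples)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    hs_stop("counts matrix must carry gene and sample dimnames")
  if (any(counts < 0)) hs_stop("counts: negative entries")
  if (anyDuplicated(rownames(counts))) hs_stop("counts: duplicated gene ids")
  if (!identical(colnames(counts), samples$sample_id))
    counts <- counts[, samples$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (anyNA(gene_lengths)) hs_stop("gene_lengths missing for some genes")
    if (any(gene_lengths < 1)) hs_stop("gene_lengths must be positive")
  }
  structure(list(counts = counts, samples = samples, gene_lengths = gene_lengths),
            class = "hs_counts")
}

#' @export
print.hs_counts <- function(x, ...) {
  cat(sprintf("hs_counts: %d genes x %d samples (%d accessions, %d tissues)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$accession)),
              length(unique(x$samples$tissue))))
  invisible(x)
}

#' Write a count matrix (and optionally its metadata) as canonical TSV
#'
#' @param x `hs_counts` object.
#' @param path output count TSV.
#' @param meta_path optional output metadata TSV.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "hs_counts"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  hs_write_tsv(df, path)
  if (!is.null(meta_path)) {
    meta <- x$samples[, c("sample_id", "species_code", "population", "tissue", "replicate")]
    hs_write_tsv(meta, meta_path)
  }
  invisible(path)
}

read_gene_lengths <- function(path, gene_ids = NULL) {
  df <- hs_read_tsv(path)
  need_cols(df, c("gene_id", "length_bp"), "lengths")
  lens <- as.integer(df$length_bp)
  if (anyNA(lens) || any(lens < 1)) hs_stop("lengths: length_bp must be a positive integer")
  lens <- setNames(lens, as.character(df$gene_id))
  if (!is.null(gene_ids)) {
    miss <- setdiff(gene_ids, names(lens))
    if (length(miss)) hs_stop("lengths: missing gene(s): %s",
                              paste(head(miss, 5), collapse = ", "))
    lens <- lens[gene_ids]
  }
  lens
}

write_gene_lengths <- function(lengths, path) {
  hs_write_tsv(data.frame(gene_id = names(lengths), length_bp = as.integer(lengths)), path)
}

# -- diagnostic SNP table -----------------------------------------------------

#' Read a diagnostic-SNP table
#'
#' Each row records a unigene position at which the two parental genomes carry
#' fixed, distinct alleles (`allele_S` for the maternal-type diploid, `allele_C`
#' for the paternal-type diploid). Positions are 1-based on the unigene.
#'
#' @param path TSV with columns `unigene_id`, `pos`, `allele_S`, `allele_C`.
#' @return validated data.frame.
#' @export
read_snp_table <- function(path) {
  validate_snp_table(hs_read_tsv(path, colClasses = list(character = "unigene_id")))
}

#' @rdname read_snp_table
#' @param snps data.frame to validate in place of a file.
#' @export
validate_snp_table <- function(snps) {
  need_cols(snps, c("unigene_id", "pos", "allele_S", "allele_C"), "snps")
  snps$unigene_id <- as.character(snps$unigene_id)
  snps$pos <- as.integer(snps$pos)
  if (anyNA(snps$pos) || any(snps$pos < 1L)) hs_stop("snps: pos must be a positive integer")
  bases <- c("A", "C", "G", "T")
  if (!all(snps$allele_S %in% bases) || !all(snps$allele_C %in% bases))
    hs_stop("snps: alleles must be one of A/C/G/T")
  same <- snps$allele_S == snps$allele_C
  if (any(same))
    hs_stop("snps: allele_S == allele_C at %s:%d",
            snps$unigene_id[which(same)[1]], snps$pos[which(same)[1]])
  key <- paste(snps$unigene_id, snps$pos)
  if (anyDuplicated(key))
    hs_stop("snps: duplicated (unigene_id, pos): %s", key[duplicated(key)][1])
  snps
}

#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  hs_write_tsv(snps[, c("unigene_id", "pos", "allele_S", "allele_C")], path)
}

# -- fragment allele observations ---------------------------------------------

#' Read fragment allele observations
#'
#' A fragment records the bases a single sequencing fragment shows at one or
#' more diagnostic positions of a unigene, serialized as `pos=base`
#' semicolon-joined. Reading can stream in chunks so that arbitrarily large
#' fragment files need only constant memory per chunk.
#'
#' @param path fragments TSV (`fragment_id`, `sample_id`, `unigene_id`,
#'   `allele_calls`).
#' @param chunk_size rows per chunk when `callback` is given.
#' @param callback optional function applied to each chunk (data.frame); when
#'   supplied the function returns the callback results invisibly instead of
#'   the full table.
#' @return data.frame of fragments, or callback results.
#' @export
read_fragments <- function(path, chunk_size = 50000L, callback = NULL) {
  if (!file.exists(path)) hs_stop("file not found: %s", path)
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  header <- NULL
  while (is.null(header)) {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) hs_stop("empty fragments file: %s", path)
    if (!startsWith(trimws(ln), "#") && nzchar(ln)) header <- strsplit(ln, "\t", fixed = TRUE)[[1]]
  }
  want <- c("fragment_id", "sample_id", "unigene_id", "allele_calls")
  if (!all(want %in% header)) hs_stop("fragments: header must contain %s",
                                      paste(want, collapse = ", "))
  parse_chunk <- function(lines) {
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) return(NULL)
    dt <- data.table::fread(text = c(paste(header, collapse = "\t"), lines),
                            sep = "\t", header = TRUE,
                            colClasses = list(character = want))
    validate_fragments(as.data.frame(dt))
  }
  if (is.null(callback)) {
    out <- parse_chunk(readLines(con))
    hs_log("read_fragments: %d fragments from %s", nrow(out), path)
    return(out)
  }
  results <- list()
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    chunk <- parse_chunk(lines)
    if (!is.null(chunk)) results[[length(results) + 1L]] <- callback(chunk)
  }
  invisible(results)
}

#' @rdname read_fragments
#' @param fragments data.frame to validate.
#' @export
validate_fragments <- function(fragments) {
  need_cols(fragments, c("fragment_id", "sample_id", "unigene_id", "allele_calls"),
            "fragments")
  for (j in c("fragment_id", "sample_id", "unigene_id", "allele_calls"))
    fragments[[j]] <- as.character(fragments[[j]])
  empty <- is.na(fragments$allele_calls) | fragments$allele_calls == ""
  if (any(empty)) hs_stop("fragments: empty allele_calls for fragment %s",
                          fragments$fragment_id[which(empty)[1]])
  key <- paste(fragments$sample_id, fragments$fragment_id)
  if (anyDuplicated(key))
    hs_stop("fragments: duplicated fragment_id within sample: %s",
            fragments$fragment_id[which(duplicated(key))[1]])
  fragments
}

#' @rdname read_fragments
#' @export
write_fragments <- function(fragments, path) {
  hs_write_tsv(fragments[, c("fragment_id", "sample_id", "unigene_id", "allele_calls")],
               path)
}

# -- ortholog family map ------------------------------------------------------

#' Read an ortholog-family map
#'
#' Links gene ids across species: one row per (family, species, gene). A
#' (species, gene) pair may belong to at most one family; families may lack
#' members in some species.
#'
#' @param path families TSV (`family_id`, `species_code`, `gene_id`).
#' @return validated data.frame.
#' @export
read_family_map <- function(path) {
  validate_family_map(hs_read_tsv(path))
}

#' @rdname read_family_map
#' @param families data.frame to validate.
#' @export
validate_family_map <- function(families) {
  need_cols(families, c("family_id", "species_code", "gene_id"), "families")
  for (j in names(families)) families[[j]] <- as.character(families[[j]])
  bad <- setdiff(unique(families$species_code), SPECIES_CODES)
  if (length(bad)) hs_stop("families: unknown species_code: %s", paste(bad, collapse = ", "))
  key <- paste(families$species_code, families$gene_id)
  if (anyDuplicated(key))
    hs_stop("families: (species, gene) in more than one family: %s",
            key[duplicated(key)][1])
  families
}

#' @rdname read_family_map
#' @export
write_family_map <- function(families, path) {
  hs_write_tsv(families[, c("family_id", "species_code", "gene_id")], path)
}

# -- run configuration --------------------------------------------------------

hs_config_defaults <- function() {
  list(
    fpkm_expressed    = 1.0,   # expressed iff mean FPKM strictly > this
    min_gene_length_bp = 200L, # reliable-unigene length floor
    abs_log2fc        = 1.0,   # fold-change gate, all DE-type calls
    fdr_deg           = 0.05,  # total-expression DEG FDR gate
    fdr_homeolog_de   = 0.05,  # homeolog-vs-homeolog DE FDR gate
    p_homeolog_de     = 0.05,  # raw-P gate, homeolog DE only
    fdr_bias          = 0.01,  # Fisher bias FDR gate
    p_bias            = 0.05,  # raw-P gate, bias test
    rng_seed          = 1L,
    paths             = list()
  )
}

#' Load a run configuration
#'
#' Reads a YAML key-value file of threshold overrides; keys not present keep
#' their defaults (the study's published gates). Unknown keys are an error so
#' that typos cannot silently revert a threshold to its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return a named list of effective settings, class `hs_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- hs_config_defaults()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) hs_stop("config: unknown key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  for (k in c("fpkm_expressed", "abs_log2fc")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) hs_stop("config: %s must be >= 0", k)
  }
  for (k in c("fdr_deg", "fdr_homeolog_de", "p_homeolog_de", "fdr_bias", "p_bias")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] > 1)
      hs_stop("config: %s must be in (0, 1]", k)
  }
  if (cfg$min_gene_length_bp < 1) hs_stop("config: min_gene_length_bp must be >= 1")
  scal <- cfg[setdiff(names(cfg), "paths")]
  hs_log("config: %s", paste(sprintf("%s=%s", names(scal), unlist(scal)), collapse = ", "))
  structure(cfg, class = "hs_config")
}
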