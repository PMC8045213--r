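# Orchestration: compose the stages (simulate -> partition -> quantify ->
# deg -> inherit -> bias -> report) over a run directory, with per-stage
# artifacts and a machine-readable run summary. Every stage is rerunnable in
# isolation from the artifacts already on disk.

#' Wide family map for a set of species
#'
#' @param families family map (long form).
#' @param species species codes to pivot into columns.
#' @return data.frame `family_id`, one `gene_<code>` column per species;
#'   only families with a member in every requested species are kept.
#' @export
family_gene_map <- function(families, species) {
  out <- NULL
  for (sp in species) {
    sub <- families[families$species_code == sp, c("family_id", "gene_id")]
    names(sub)[2] <- paste0("gene_", sp)
    out <- if (is.null(out)) sub else merge(out, sub, by = "family_id")
  }
  out[order(out$family_id), , drop = FALSE]
}

samples_of <- function(cm, accession, tissue) {
  s <- cm$samples
  s$sample_id[s$accession == accession & s$tissue == tissue]
}

default_c_accession <- function(cm) {
  s <- cm$samples
  sort(unique(s$accession[s$species_code == "C"]))[1]
}

# families x samples matrix taking each accession's own member genes
paired_family_matrix <- function(cm, fam, gene_cols, sample_sets) {
  mats <- mapply(function(gc, ids) {
    m <- cm$counts[fam[[gc]], ids, drop = FALSE]
    rownames(m) <- fam$family_id
    m
  }, gene_cols, sample_sets, SIMPLIFY = FALSE)
  do.call(cbind, mats)
}

#' Inheritance-of-expression analysis for one tetraploid and tissue
#'
#' Restricts to ortholog families coexpressed in the tetraploid and both
#' diploid parents in this tissue, TMM-normalizes the paired family counts
#' across the three accessions' libraries, runs the NB exact test for the
#' three contrasts (T vs S, T vs C, S vs C; each BH-adjusted as its own
#' family), and classifies every family through the twelve-state decision
#' table.
#'
#' @param cm `hs_counts` (all accessions).
#' @param families family map.
#' @param profile [expression_profile()] result for `cm`.
#' @param config `hs_config`.
#' @param tetraploid tetraploid species code (`"T1"` / `"T2"`).
#' @param tissue tissue to analyze.
#' @param c_accession which C-diploid population stands for parent C
#'   (default: first alphabetically).
#' @return list: `calls` (per-family ternary calls, state, group), `de`
#'   (long DE table for the three contrasts), `summary`
#'   ([summarize_inheritance()]), `n_coexpressed`.
#' @export
inheritance_analysis <- function(cm, families, profile, config = load_config(),
                                 tetraploid = "T1", tissue = NULL,
                                 c_accession = NULL) {
  if (is.null(tissue)) tissue <- cm$samples$tissue[1]
  if (is.null(c_accession)) c_accession <- default_c_accession(cm)
  fam <- family_gene_map(families, c("S", "C", tetraploid))
  ids <- list(T = samples_of(cm, tetraploid, tissue),
              S = samples_of(cm, "S", tissue),
              C = samples_of(cm, c_accession, tissue))
  grp <- profile$groups
  gcol <- function(acc) grp$group[grp$accession == acc & grp$tissue == tissue]
  expr <- profile$expressed
  coexpr <- expr[fam[[paste0("gene_", tetraploid)]], gcol(tetraploid)] &
    expr[fam$gene_S, gcol("S")] & expr[fam$gene_C, gcol(c_accession)]
  fam <- fam[coexpr, , drop = FALSE]
  hs_log("inheritance_analysis[%s, %s]: %d coexpressed families", tetraploid,
         tissue, nrow(fam))
  gene_cols <- c(paste0("gene_", tetraploid), "gene_S", "gene_C")
  paired <- paired_family_matrix(cm, fam, gene_cols, ids)
  full_lib <- colSums(cm$counts)[colnames(paired)]
  eff_lib <- full_lib * tmm_factors(paired, full_lib)
  idx <- rep(c("T", "S", "C"), vapply(ids, length, 1L))
  de <- list()
  for (ctr in list(c("T", "S"), c("T", "C"), c("S", "C"))) {
    a <- paired[, idx == ctr[1], drop = FALSE]
    b2 <- paired[, idx == ctr[2], drop = FALSE]
    la <- eff_lib[idx == ctr[1]]; lb <- eff_lib[idx == ctr[2]]
    tab <- de_table(a, b2, la, lb, phi = NULL, abs_log2fc = config$abs_log2fc,
                    fdr_max = config$fdr_deg)
    tab$contrast <- paste0(ctr[1], "_vs_", ctr[2])
    names(tab)[names(tab) == "gene_id"] <- "family_id"
    de[[tab$contrast[1]]] <- tab
  }
  calls <- classify_inheritance(de$T_vs_S$call, de$T_vs_C$call, de$S_vs_C$call)
  calls <- cbind(data.frame(family_id = fam$family_id, stringsAsFactors = FALSE), calls)
  list(calls = calls, de = do.call(rbind, de), summary = summarize_inheritance(calls),
       n_coexpressed = nrow(fam))
}

#' Homeolog contribution, bias and silent/lost analysis for one tetraploid
#' and tissue
#'
#' Builds the homeolog count matrices from partitioned fragments, pairs them
#' with TMM-normalized parental ortholog counts via the family map, and runs
#' the homeolog DE test, the Rh-vs-Rp Fisher bias test, the silent/lost
#' accounting, and the DE x bias integration.
#'
#' @param cm `hs_counts`.
#' @param hom homeolog count table ([homeolog_counts()]).
#' @param families family map.
#' @param profile [expression_profile()] result.
#' @param config `hs_config`.
#' @param tetraploid,tissue,c_accession as in [inheritance_analysis()].
#' @return list: `bias` (per-gene table), `integration`, `silent`,
#'   `n_testable`.
#' @export
bias_analysis <- function(cm, hom, families, profile, config = load_config(),
                          tetraploid = "T1", tissue = NULL, c_accession = NULL) {
  if (is.null(tissue)) tissue <- cm$samples$tissue[1]
  if (is.null(c_accession)) c_accession <- default_c_accession(cm)
  fam <- family_gene_map(families, c("S", "C", tetraploid))
  tet_ids <- samples_of(cm, tetraploid, tissue)
  mats <- homeolog_count_matrices(hom, tet_ids)
  keep <- rownames(mats$S) %in% fam[[paste0("gene_", tetraploid)]]
  mats$S <- mats$S[keep, , drop = FALSE]; mats$C <- mats$C[keep, , drop = FALSE]
  fam <- fam[match(rownames(mats$S), fam[[paste0("gene_", tetraploid)]]), ]

  ids_s <- samples_of(cm, "S", tissue); ids_c <- samples_of(cm, c_accession, tissue)
  paired <- paired_family_matrix(cm, fam, c("gene_S", "gene_C"),
                                 list(S = ids_s, C = ids_c))
  full_lib <- colSums(cm$counts)[colnames(paired)]
  eff_lib <- full_lib * tmm_factors(paired, full_lib)
  norm <- sweep(paired, 2, geo_mean(eff_lib) / eff_lib, "*")
  idx <- rep(c("S", "C"), c(length(ids_s), length(ids_c)))
  par_s <- rowSums(norm[, idx == "S", drop = FALSE])
  par_c <- rowSums(norm[, idx == "C", drop = FALSE])
  tet_gene <- fam[[paste0("gene_", tetraploid)]]
  names(par_s) <- names(par_c) <- tet_gene

  grp <- profile$groups
  gcol <- function(acc) grp$group[grp$accession == acc & grp$tissue == tissue]
  exp_s <- setNames(profile$expressed[fam$gene_S, gcol("S")], tet_gene)
  exp_c <- setNames(profile$expressed[fam$gene_C, gcol(c_accession)], tet_gene)

  bias <- bias_table(mats, par_c, par_s, parent_expressed_c = exp_c,
                     parent_expressed_s = exp_s, config = config)
  silent <- detect_silent_homeologs(mats, exp_s, exp_c)
  list(bias = bias, integration = integrate_bias(bias), silent = silent,
       n_testable = sum(bias$testable))
}

load_run_inputs <- function(dir, need_fragments = FALSE) {
  req <- c("counts.tsv", "samples.tsv", "lengths.tsv", "families.tsv")
  if (need_fragments) req <- c(req, "snps.tsv", "fragments.tsv")
  miss <- req[!file.exists(file.path(dir, req))]
  if (length(miss))
    hs_stop("missing upstream artifact(s) %s in %s: run the simulate stage (or provide inputs) first",
            paste(miss, collapse = ", "), dir)
  out <- list(
    counts = read_count_matrix(file.path(dir, "counts.tsv"),
                               file.path(dir, "samples.tsv"),
                               file.path(dir, "lengths.tsv")),
    families = read_family_map(file.path(dir, "families.tsv"))
  )
  if (need_fragments) {
    out$snps <- read_snp_table(file.path(dir, "snps.tsv"))
    out$fragments <- read_fragments(file.path(dir, "fragments.tsv"))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order against a run directory.
#' The `simulate` stage writes the input tables from a scenario; later stages
#' read their upstream artifacts from the directory, so any stage can be
#' rerun in isolation. Identical scenario, config and seed give identical
#' artifacts.
#'
#' @param out_dir run directory.
#' @param scenario `hs_scenario` for the simulate stage (ignored if inputs
#'   already present and simulate not requested).
#' @param config `hs_config`.
#' @param stages subset of
#'   `c("simulate", "partition", "quantify", "deg", "inherit", "bias", "report")`.
#' @param seed overrides the scenario seed when given.
#' @return the run summary (named list), invisibly; also written as
#'   `run_summary.json`.
#' @export
run_pipeline <- function(out_dir, scenario = NULL, config = load_config(),
                         stages = c("simulate", "partition", "quantify", "deg",
                                    "inherit", "bias", "report"),
                         seed = NULL) {
  all_stages <- c("simulate", "partition", "quantify", "deg", "inherit", "bias", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "run_summary.json")
  summ <- if (file.exists(summary_path)) {
    jsonlite::read_json(summary_path, simplifyVector = TRUE)
  } else list()
  summ$package_version <- as.character(utils::packageVersion("homeoscope"))
  summ$thresholds <- unclass(config)[setdiff(names(config), "paths")]

  if ("simulate" %in% stages) {
    if (is.null(scenario)) hs_stop("simulate stage needs a scenario")
    if (!is.null(seed)) scenario$seed <- seed
    sim <- simulate_dataset(scenario)
    write_simdata(sim, out_dir)
    summ$seed <- scenario$seed
    summ$simulate <- list(n_families = scenario$n_genes,
                          n_samples = ncol(sim$counts$counts),
                          n_fragments = nrow(sim$fragments))
  }

  inp <- NULL
  get_inputs <- function(frag) {
    if (is.null(inp) || (frag && is.null(inp$fragments)))
      inp <<- load_run_inputs(out_dir, need_fragments = frag)
    inp
  }

  if ("partition" %in% stages) {
    x <- get_inputs(TRUE)
    part <- partition_fragments(x$fragments, x$snps)
    hom <- homeolog_counts(part, x$snps)
    hs_write_tsv(hom, file.path(out_dir, "homeolog_counts.tsv"))
    summ$partition <- list(
      n_fragments = nrow(part),
      bins = as.list(table(part$bin)),
      n_unigene_sample_rows = nrow(hom)
    )
  }

  tets <- function(x) intersect(c("T1", "T2"), unique(x$counts$samples$species_code))
  tissues <- function(x) unique(x$counts$samples$tissue)

  if ("quantify" %in% stages) {
    x <- get_inputs(FALSE)
    profile <- expression_profile(x$counts, config)
    gm <- data.frame(gene_id = rownames(profile$group_mean_fpkm),
                     profile$group_mean_fpkm, check.names = FALSE)
    hs_write_tsv(gm, file.path(out_dir, "mean_fpkm.tsv"))
    ex <- data.frame(gene_id = rownames(profile$expressed),
                     profile$expressed, check.names = FALSE)
    hs_write_tsv(ex, file.path(out_dir, "expressed.tsv"))
    qc <- replicate_correlation_qc(x$counts)
    hs_write_tsv(qc, file.path(out_dir, "replicate_qc.tsv"))
    venn <- list()
    c_accs <- sort(unique(x$counts$samples$accession[x$counts$samples$species_code == "C"]))
    for (tt in tets(x)) {
      spec <- specificity_analysis(profile, x$families,
                                   accessions = c(tt, "S", c_accs))
      venn[[tt]] <- list(regions = as.list(spec$regions),
                         n_excluded = spec$n_excluded,
                         n_unexpressed = spec$n_unexpressed)
    }
    if (length(tets(x)) == 2) {
      spec <- specificity_analysis(profile, x$families, accessions = tets(x))
      venn$tetraploid_pair <- list(regions = as.list(spec$regions))
    }
    jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summ$quantify <- list(
      n_genes = nrow(profile$fpkm),
      expressed_per_group = as.list(colSums(profile$expressed)),
      venn = venn,
      qc_flagged_pairs = sum(qc$flagged)
    )
  }

  if (any(c("deg", "inherit") %in% stages)) {
    x <- get_inputs(FALSE)
    profile <- expression_profile(x$counts, config)
    inherit_out <- list(); de_out <- list(); summ_inherit <- list()
    for (tt in tets(x)) for (ti in tissues(x)) {
      res <- inheritance_analysis(x$counts, x$families, profile, config,
                                  tetraploid = tt, tissue = ti)
      key <- paste(tt, ti, sep = "|")
      res$de$tetraploid <- tt; res$de$tissue <- ti
      res$calls$tetraploid <- tt; res$calls$tissue <- ti
      de_out[[key]] <- res$de
      inherit_out[[key]] <- res$calls
      grp_sum <- res$summary$by_group
      summ_inherit[[key]] <- list(
        n_coexpressed = res$n_coexpressed,
        group_percent = as.list(setNames(grp_sum$percent, grp_sum$group))
      )
    }
    de_all <- do.call(rbind, de_out); rownames(de_all) <- NULL
    hs_write_tsv(de_all, file.path(out_dir, "deg.tsv"))
    if ("inherit" %in% stages) {
      calls_all <- do.call(rbind, inherit_out); rownames(calls_all) <- NULL
      hs_write_tsv(calls_all, file.path(out_dir, "inheritance.tsv"))
      summ$inherit <- summ_inherit
    }
    summ$deg <- list(n_tests = nrow(de_all),
                     calls = as.list(table(de_all$call)))
  }

  if ("bias" %in% stages) {
    x <- get_inputs(FALSE)
    hom_path <- file.path(out_dir, "homeolog_counts.tsv")
    if (!file.exists(hom_path))
      hs_stop("missing homeolog_counts.tsv: run the partition stage first")
    hom <- hs_read_tsv(hom_path)
    profile <- expression_profile(x$counts, config)
    bias_out <- list(); silent_rows <- list(); summ_bias <- list()
    for (tt in tets(x)) for (ti in tissues(x)) {
      res <- bias_analysis(x$counts, hom, x$families, profile, config,
                           tetraploid = tt, tissue = ti)
      key <- paste(tt, ti, sep = "|")
      res$bias$tetraploid <- tt; res$bias$tissue <- ti
      bias_out[[key]] <- res$bias
      silent_rows[[key]] <- data.frame(
        tetraploid = tt, tissue = ti,
        n_testable = res$silent$n_testable,
        n_silent_S = res$silent$n_silent_S, pct_silent_S = res$silent$pct_silent_S,
        n_silent_C = res$silent$n_silent_C, pct_silent_C = res$silent$pct_silent_C
      )
      summ_bias[[key]] <- list(
        n_testable = res$n_testable,
        bias_classes = as.list(table(res$bias$bias_class[res$bias$bias_testable])),
        homeolog_de = as.list(table(res$bias$homeolog_de[res$bias$testable])),
        integration_counts = as.data.frame(res$integration$counts),
        silent = silent_rows[[key]][, -(1:2)]
      )
    }
    bias_all <- do.call(rbind, bias_out); rownames(bias_all) <- NULL
    hs_write_tsv(bias_all, file.path(out_dir, "bias.tsv"))
    silent_all <- do.call(rbind, silent_rows); rownames(silent_all) <- NULL
    hs_write_tsv(silent_all, file.path(out_dir, "silent_loss.tsv"))
    summ$bias <- summ_bias
  }

  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if ("report" %in% stages) {
    writeLines(report_run(out_dir), file.path(out_dir, "report.md"))
  }
  invisible(summ)
}

fmt_table <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) format(round(x, 2), trim = TRUE) else x)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}

#' Human-readable report for a completed (or partial) run
#'
#' Renders markdown tables mirroring the study's reporting shapes:
#' coexpression/specificity region counts, inheritance group percentages,
#' silent/lost homeolog counts, and bias tallies. Stages without artifacts
#' are noted and skipped.
#'
#' @param run_dir run directory.
#' @return character vector of markdown lines.
#' @export
report_run <- function(run_dir) {
  out <- c("# homeoscope run report", "")
  sp <- file.path(run_dir, "run_summary.json")
  if (file.exists(sp)) {
    s <- jsonlite::read_json(sp, simplifyVector = TRUE)
    out <- c(out, sprintf("Package version %s; seed %s.",
                          s$package_version %||% "?", s$seed %||% "?"), "")
  }
  vp <- file.path(run_dir, "venn.json")
  out <- c(out, "## Specific and coexpressed ortholog families")
  if (file.exists(vp)) {
    venn <- jsonlite::read_json(vp, simplifyVector = TRUE)
    for (nm in names(venn)) {
      reg <- venn[[nm]]$regions
      df <- data.frame(region = names(reg), families = unlist(reg))
      out <- c(out, "", sprintf("### %s", nm), fmt_table(df))
    }
  } else out <- c(out, "", "_quantify stage not run._")
  out <- c(out, "", "## Inheritance of expression (group percentages)")
  ip <- file.path(run_dir, "inheritance.tsv")
  if (file.exists(ip)) {
    calls <- hs_read_tsv(ip)
    for (key in unique(paste(calls$tetraploid, calls$tissue))) {
      sub <- calls[paste(calls$tetraploid, calls$tissue) == key, ]
      sm <- summarize_inheritance(sub)$by_group
      out <- c(out, "", sprintf("### %s (n = %d)", key, nrow(sub)), fmt_table(sm))
    }
  } else out <- c(out, "", "_inherit stage not run._")
  out <- c(out, "", "## Silent/lost homeologs")
  lp <- file.path(run_dir, "silent_loss.tsv")
  if (file.exists(lp)) {
    out <- c(out, "", fmt_table(hs_read_tsv(lp)))
  } else out <- c(out, "", "_bias stage not run._")
  out <- c(out, "", "## Homeolog expression and bias")
  bp <- file.path(run_dir, "bias.tsv")
  if (file.exists(bp)) {
    bias <- hs_read_tsv(bp)
    for (key in unique(paste(bias$tetraploid, bias$tissue))) {
      sub <- bias[paste(bias$tetraploid, bias$tissue) == key & bias$testable %in% TRUE, ]
      df <- data.frame(
        measure = c("testable pairs", "S_higher", "equal", "C_higher",
                    "S_bias", "none", "C_bias"),
        count = c(nrow(sub),
                  sum(sub$homeolog_de %in% "S_higher"), sum(sub$homeolog_de %in% "equal"),
                  sum(sub$homeolog_de %in% "C_higher"),
                  sum(sub$bias_class %in% "S_bias"), sum(sub$bias_class %in% "none"),
                  sum(sub$bias_class %in% "C_bias"))
      )
      out <- c(out, "", sprintf("### %s", key), fmt_table(df))
    }
  } else out <- c(out, "", "_bias stage not run._")
  out
}
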