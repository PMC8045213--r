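#!/usr/bin/env Rscript
# FPKM quantification, expressed-gene filtering (mean FPKM > 1, length >= 200
# bp), replicate-correlation QC, and the coexpression/specificity Venn
# partition over ortholog families.
library(homeoscope)

`%||%` <- function(a, b) if (is.null(a)) b else a
run_dir <- "results/run"
summ <- run_pipeline(run_dir, stages = "quantify")

for (tet in setdiff(names(summ$quantify$venn), "tetraploid_pair")) {
  reg <- summ$quantify$venn[[tet]]$regions
  all_key <- names(reg)[lengths(strsplit(names(reg), "&", fixed = TRUE)) ==
                          max(lengths(strsplit(names(reg), "&", fixed = TRUE)))]
  cat(sprintf("%s: %d families coexpressed in tetraploid and both parents; %d tetraploid-specific\n",
              tet, reg[[all_key[1]]], reg[[tet]] %||% 0))
}
cat(sprintf("Replicate QC: %d within-group pair(s) flagged below the between-tissue ceiling\n",
            summ$quantify$qc_flagged_pairs))
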