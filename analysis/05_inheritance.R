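#!/usr/bin/env Rscript
# Classify inheritance of expression: each coexpressed family's three ternary
# DE calls map through the twelve-state decision table into conserved,
# intermediate, S-/C-dominance, transgressive up/down, or unassigned; then
# compare the calls with the simulator's ground truth.
library(homeoscope)

run_dir <- "results/run"
summ <- run_pipeline(run_dir, stages = "inherit")

calls <- read.delim(file.path(run_dir, "inheritance.tsv"), na.strings = ".")
truth <- read.delim(file.path(run_dir, "truth.tsv"), na.strings = ".")
for (key in unique(paste(calls$tetraploid, calls$tissue))) {
  sub <- calls[paste(calls$tetraploid, calls$tissue) == key, ]
  sm <- summarize_inheritance(sub)$by_group
  cat(sprintf("\n%s (n = %d classified families):\n", key, nrow(sub)))
  print(sm, row.names = FALSE)
  tr <- truth$true_group[match(sub$family_id, truth$family_id)]
  cat(sprintf("agreement with simulated truth: %.1f%%\n",
              100 * mean(sub$group == tr)))
}
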