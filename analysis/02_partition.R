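#!/usr/bin/env Rscript
# Partition tetraploid fragments into parental homeolog bins via the
# diagnostic SNPs and aggregate homeolog-level counts.
library(homeoscope)

run_dir <- "results/run"
summ <- run_pipeline(run_dir, stages = "partition")

bins <- summ$partition$bins
cat(sprintf("Partitioned %d fragments: %d S-type, %d C-type, %d ambiguous (%.2f%%)\n",
            summ$partition$n_fragments, bins$S, bins$C, bins$ambiguous,
            100 * bins$ambiguous / summ$partition$n_fragments))
cat(sprintf("Homeolog count table: %d (unigene, sample) rows -> %s\n",
            summ$partition$n_unigene_sample_rows,
            file.path(run_dir, "homeolog_counts.tsv")))
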