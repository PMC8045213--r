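#!/usr/bin/env Rscript
# Negative-binomial exact-test differential expression for every tetraploid x
# tissue: T vs S, T vs C and S vs C on TMM-normalized family counts, each
# contrast BH-adjusted separately, calls at |log2FC| > 1 and FDR < 0.05.
library(homeoscope)

run_dir <- "results/run"
summ <- run_pipeline(run_dir, stages = "deg")

deg <- read.delim(file.path(run_dir, "deg.tsv"), na.strings = ".")
cat(sprintf("%d exact tests over %d coexpressed-family contrasts\n",
            nrow(deg), length(unique(paste(deg$tetraploid, deg$tissue)))))
tab <- with(deg, table(contrast, call))
print(tab)
cat(sprintf("Overall: %.1f%% of tests called up or down\n",
            100 * mean(deg$call != "equal")))
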