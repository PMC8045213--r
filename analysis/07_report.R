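#!/usr/bin/env Rscript
# Render the consolidated run report (markdown) from the per-stage artifacts.
library(homeoscope)

run_dir <- "results/run"
run_pipeline(run_dir, stages = "report")
cat(sprintf("Report written to %s\n", file.path(run_dir, "report.md")))
cat(readLines(file.path(run_dir, "report.md")), sep = "\n")
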