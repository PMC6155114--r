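#!/usr/bin/env Rscript
# Render the run report (edge partition, hubs, negative-edge classes,
# hierarchy, DUF predictions) to results/report.txt and echo it.

library(gcnet)

res <- readRDS("scratch/run.rds")
lines <- report_run(res, file = "results/report.txt")
cat(lines, sep = "\n")
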