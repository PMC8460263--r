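#!/usr/bin/env Rscript

# Stage 4: Costes automatic thresholding + thresholded Manders coefficients
# for every (dye, protein) scene pair, ROI-restricted.
#
# Note the known limitation this stage surfaces: once rims carry signal, the
# automatic threshold scales with rim brightness, so tM1 reads out rim
# geometry rather than recruitment amplitude, and on rim-free early scenes
# the regression slope sign (hence the threshold) is unstable. The
# pearson_below and converged columns let users see both effects.

# Run from the repository root: Rscript analysis/04_coloc.R
library(dropletrim)
source("analysis/config.R")

cfg <- pipeline_config()
cfg$stages <- c("simulate", "segment", "quantify", "coloc")
run_pipeline(cfg)

co <- read.csv(file.path(cfg$output_dir, "coloc.csv"))
cat(sprintf("colocalization on %d scene pairs; %d converged searches\n",
            nrow(co), sum(co$converged)))
agg <- aggregate(cbind(tM1, tM2) ~ time_hr, co, mean)
cat("mean tM1 by time (h):\n")
print(round(agg, 3), row.names = FALSE)
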