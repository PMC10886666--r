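#!/usr/bin/env Rscript
# Self-supervised feature-extraction study: train the patch-identity
# encoder on neighbouring-pair datasets and sweep the compression layer
# (conv2d vs dense) and the pair budget per slide. Writes
# results/feature_sweep.csv.
#
# Desk-scale version of the full sweep: 20 slides, 32-px thumbnails,
# widths {1536, 128, 64, 32, 16}. At this data volume the experiment sits
# in the low-pair regime, where accuracy improves as the compression
# layer narrows towards 64 features and then degrades under further
# compression, and convolutional compression beats dense.

library(wsimil)

dir.create("results", showWarnings = FALSE)
seed <- 20260928L

cat("building pair datasets (streamed slides)...\n")
datasets <- build_pair_datasets(20, 2048L, pair_budgets = c("3", "10", "all"),
                                input_px = 32L, seed = seed)
for (b in names(datasets)) {
  cat(sprintf("  budget %-3s: %d training patches\n", b,
              length(datasets[[b]]$train_imgs)))
}

sweep <- rbind(
  pairing_sweep(datasets["all"], widths = c(1536L, 128L, 64L, 32L, 16L),
                modes = c("conv2d", "dense"), input_px = 32L,
                epochs = 30L, train_seeds = 1:2),
  pairing_sweep(datasets[c("3", "10")], widths = 64L, modes = "conv2d",
                input_px = 32L, epochs = 30L, train_seeds = 1:2)
)
utils::write.csv(sweep, "results/feature_sweep.csv", row.names = FALSE)

agg <- stats::aggregate(accuracy ~ pairs + mode + width, sweep, mean)
print(agg[order(agg$pairs, agg$mode, -agg$width), ], row.names = FALSE)

wide <- function(m, w) agg$accuracy[agg$mode == m & agg$width == w &
                                    agg$pairs == "all"]
cat(sprintf("\nconv2d: acc(1536) = %.3f, acc(64) = %.3f, acc(32) = %.3f\n",
            wide("conv2d", 1536), wide("conv2d", 64), wide("conv2d", 32)))
cat(sprintf("conv2d - dense at width 64: %+.3f\n",
            wide("conv2d", 64) - wide("dense", 64)))
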