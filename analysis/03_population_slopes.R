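#!/usr/bin/env Rscript
# Step 3: population comparison of natural-scene and square signals.
# Plots each cell's normalized full / patch / context effect against its
# normalized square effect and fits lines through the origin by
# orthogonal least squares, with cell-bootstrap 95% CIs.
#
# Writes results/slopes.json and results/scatter.csv.

suppressMessages(library(bosig))

tab <- read.csv("results/effects.csv")
out <- list()
for (cond in c("full", "patch", "context")) {
  y <- tab[[paste0("norm_", cond)]]
  fit <- bootstrap_slope_ci(tab$norm_square, y, B = 1000, seed = 1)
  out[[cond]] <- list(slope_pct = 100 * fit$slope,
                      ci_pct = 100 * fit$ci, n = fit$n)
  cat(sprintf("%-8s relative strength %5.1f%%  (95%% CI %5.1f to %5.1f)\n",
              cond, 100 * fit$slope, 100 * fit$ci[1], 100 * fit$ci[2]))
}
jsonlite::write_json(out, "results/slopes.json", auto_unbox = TRUE,
                     digits = NA)

scatter <- do.call(rbind, lapply(c("full", "patch", "context"),
  function(cond) {
    can <- canonicalize_scatter(tab$norm_square,
                                tab[[paste0("norm_", cond)]])
    data.frame(cell = tab$cell, condition = cond, x = can$x, y = can$y)
  }))
write.csv(scatter, "results/scatter.csv", row.names = FALSE)
cat("wrote results/slopes.json, results/scatter.csv\n")
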