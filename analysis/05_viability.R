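#!/usr/bin/env Rscript
# Live/dead bookkeeping on a SYNTHETIC counts table (labelled as such; the
# study's manual counts are not deposited) plus the geometric
# expected-cell-death arithmetic that scales 2D per-exposure death rates by
# the fraction of cells actually exposed in a 3D phantom. Writes summaries
# under results/viability/.

library(gasphantom)

set.seed(5)
mk <- function(condition, orientation, mean_live, n = 6) {
  live <- pmin(pmax(round(rnorm(n, mean_live, 4)), 0), 100)
  data.frame(sample_id = sprintf("%s_%s_%d", condition, orientation, 1:n),
             condition = condition, orientation = orientation,
             calcein_n = live, ethidium_n = 100 - live)
}
counts <- rbind(mk("pre", "none", 88), mk("sham", "none", 84),
                mk("post", "bubbles_up", 75), mk("post", "bubbles_down", 66))

by_cond <- viability_summary(counts)
by_orient <- viability_summary(counts[counts$condition == "post", ],
                               by = c("condition", "orientation"))

dir.create("results/viability", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(counts, "results/viability/counts_synthetic.csv",
                 row.names = FALSE)
utils::write.csv(by_cond, "results/viability/summary_by_condition.csv",
                 row.names = FALSE)
utils::write.csv(by_orient, "results/viability/summary_by_orientation.csv",
                 row.names = FALSE)

print(by_cond, row.names = FALSE)
print(by_orient, row.names = FALSE)

cat("\ngeometric expectation from 2D literature rates:\n")
cat(sprintf("  50%% bubble contact x 30%% contact death  -> %.0f%% death\n",
            expected_cell_death(0.50, 30)))
cat(sprintf("  20%% ppO2 exposure  x 20%% exposure death -> %.0f%% death\n",
            expected_cell_death(0.20, 20)))
cat("finding: once only a fraction of the 3D population is exposed, the\n")
cat("expected death (4-15%) brackets the ~11-16% reductions such dive\n")
cat("exposures produce, despite the much larger 2D per-exposure rates.\n")
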