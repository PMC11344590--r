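#!/usr/bin/env Rscript

# Stage 4: report tables.
#
# Two table layouts summarise where retrieval is trivial versus challenging:
# the best/worst superfamilies for one model (mean AUROC, average true labels
# per query, query count; only groups with more than `min_queries` queries),
# and the superfamilies with the largest AUROC difference between two models,
# in both directions.

suppressMessages(library(remhombench))

eval_dir <- "results/eval"
read_rec <- function(m) {
  utils::read.delim(file.path(eval_dir,
                              sprintf("metrics_toy30_%s_superfamily.tsv", m)))
}
weak <- read_rec("plm_weak")
strong <- read_rec("plm_strong")
random <- read_rec("random")

tb <- top_bottom_groups(weak, n = 3, min_queries = 5)
utils::write.table(tb, file.path(eval_dir, "top_bottom_plm_weak.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("plm_weak: best and worst superfamilies (groups with > 5 queries):\n")
tb$auroc <- round(tb$auroc, 3)
print(tb, row.names = FALSE)

delta <- model_delta_table(strong, random, n = 3)
utils::write.table(delta, file.path(eval_dir, "delta_strong_vs_random.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nlargest per-superfamily AUROC differences, plm_strong vs random:\n")
delta[, c("auroc_a", "auroc_b", "delta")] <-
  round(delta[, c("auroc_a", "auroc_b", "delta")], 3)
print(delta, row.names = FALSE)
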