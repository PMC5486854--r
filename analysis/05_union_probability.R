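#!/usr/bin/env Rscript
# Step 5: the combination argument. Each weak cue (phonology, first-order
# co-occurrence) predicts valence at about 55%; if they err independently,
# at least one is right with probability P(A) + P(B) - P(A)P(B).

library(phonovalence)
dir.create("results", showWarnings = FALSE)

grid <- expand.grid(pA = c(0.55, 0.6, 0.7), pB = c(0.55, 0.6, 0.7))
grid$union <- union_probability(grid$pA, grid$pB)
write.table(grid, "results/union_probability.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
u <- union_probability(0.55, 0.55)
cat(sprintf("two independent 55%% cues -> union %.4f (~%.0f%%)\n", u, 100 * u))
cat("table over a small grid in results/union_probability.tsv\n")
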