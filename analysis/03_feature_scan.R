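#!/usr/bin/env Rscript
# Step 3: per-feature valence scans on the full lexicons (pooled
# two-sample t per feature, dichotomized at presence) and the
# cross-language intersection of significant predictors.

library(phonovalence)
dir.create("results", showWarnings = FALSE)

scans <- list()
for (lg in c("zh", "nl", "en", "de")) {
  lex <- read_lexicon(file.path("scratch/lexicons", paste0(lg, ".tsv")))
  scan <- feature_scan(feature_matrix(lex))
  scans[[lg]] <- scan
  write.table(scan, file.path("results", paste0("feature_scan_", lg, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  nf <- scan[scan$feature == "nasal_first", ]
  cat(sprintf("%s: nasal_first t(%d) = %+.2f, p = %.2e, direction %+d; %d features untestable\n",
              lg, nf$df, nf$t, nf$p, nf$direction, sum(!scan$testable)))
}

venn <- shared_predictors(scans, alpha = 0.05)
print(venn)
write.table(venn$cells, "results/venn_cells.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(venn$core, "results/venn_core_directions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
if ("nasal_first" %in% venn$core$feature) {
  cat("nasal_first is significant in every language, positive in Chinese\n")
  cat("and negative elsewhere - the shared sound-symbolic cue.\n")
}
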