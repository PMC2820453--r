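#!/usr/bin/env Rscript
# Step 2 — fold-change classification of the two contrasts.
#
# Linear fold changes with the inclusive two-fold rule: nitrogen
# fixation vs nitrogen excess (induction) and 10-min ammonium shock vs
# nitrogen fixation (repression kinetics).

suppressMessages(library(nifregulon))

expr <- read_expression("results/synthetic/expression.tsv")
fc_nfix <- classify_contrast(expr, "nfix", "nexcess")
fc_shock <- classify_contrast(expr, "shock10", "nfix")

dir.create("results", showWarnings = FALSE)
write.table(fc_nfix, "results/folds_nfix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fc_shock, "results/folds_shock.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

s1 <- summarize_contrast(fc_nfix$label)
s2 <- summarize_contrast(fc_shock$label)
cat(sprintf("nitrogen fixation vs excess: %d up, %d down, %d unchanged\n",
            s1["up"], s1["down"], s1["unchanged"]))
cat(sprintf("10-min ammonium shock vs nitrogen fixation: %d up, %d down (%d altered)\n",
            s2["up"], s2["down"], s2["up"] + s2["down"]))
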