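#!/usr/bin/env Rscript
# Step 3 — regulon inference and set analyses.
#
# The nitrogen-fixation-inducible regulon is the intersection: up under
# nitrogen fixation AND down 10 min after ammonium shock. The ortholog
# table then cuts it to the core subset conserved in both reference
# diazotrophs, and the category map summarises its functional makeup.

suppressMessages(library(nifregulon))

fc_nfix <- read.delim("results/folds_nfix.tsv")
fc_shock <- read.delim("results/folds_shock.tsv")
reg <- infer_regulon(setNames(fc_nfix$label, fc_nfix$locus_id),
                     setNames(fc_shock$label, fc_shock$locus_id))
write_regulon(reg, "results/regulon.tsv")
members <- regulon_members(reg)
cat(sprintf("regulon: %d genes (of %d up-regulated)\n", length(members),
            sum(reg$up_in_nfix)))

orth <- read_ortholog_table("results/synthetic/orthologs.tsv")
refs <- setdiff(names(orth), "locus_id")
core <- core_subset(members, orth, refs)
writeLines(core, "results/core_subset.txt")
cat(sprintf("core subset conserved in {%s}: %d genes\n",
            paste(refs, collapse = ", "), length(core)))

cmap <- read_category_map("results/synthetic/category_map.tsv")
summ <- categorize_functions(core, cmap)
write.table(summ, "results/core_subset_categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("core-subset functional categories:\n")
for (i in seq_len(nrow(summ)))
  cat(sprintf("  %-22s %3d (%4.1f%%)\n", summ$category[i], summ$n[i],
              100 * summ$proportion[i]))
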