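#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study dataset.
#
# Emulates the design the pipeline is built for: a 1,000-gene bacterial
# genome carrying a 58-gene, 49-kb nitrogen-fixation island (11 operons,
# 52 regulon genes, NifA-UAS + sigma-54 promoters planted upstream of
# each operon leader), 114 further regulon genes elsewhere, and a
# three-condition expression matrix (nitrogen fixation, nitrogen excess,
# 10-min ammonium shock) with log-normal noise. All downstream steps
# read the files written here.

suppressMessages(library(nifregulon))

out <- "results/synthetic"
spec <- simulation_spec(seed = 20100107)
paths <- simulate_dataset(spec, out)

truth <- paths$truth
cat("synthetic dataset written to", out, "\n")
cat(sprintf("  genes: %d | regulon: %d (island %d + outside %d)\n",
            spec$n_genes, length(truth$regulon_loci),
            length(truth$island$member_loci),
            spec$n_regulon_outside))
cat(sprintf("  island: %s..%s, %d genes, %d bp\n",
            truth$island$first_locus, truth$island$last_locus,
            truth$island$last_index - truth$island$first_index + 1L,
            truth$island$span_bp))
cat(sprintf("  planted operons: %d (%d genes)\n", length(truth$operons),
            sum(lengths(lapply(truth$operons, `[[`, "members")))))
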