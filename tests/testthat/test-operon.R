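flag_table <- function(loci, yes) {
  data.frame(locus_id = loci,
             nifa_flag = ifelse(loci %in% yes, "Yes", "No"),
             rpon_flag = ifelse(loci %in% yes, "Yes", "No"),
             stringsAsFactors = FALSE)
}

ann_from <- function(starts, len, strands) {
  genome_annotation("chr", data.frame(
    locus_id = sprintf("g%02d", seq_along(starts)), name = NA,
    start = starts, end = starts + len, strand = strands,
    product = NA, category = NA), max(starts + len) + 100L)
}

test_that("operon extension follows strand, gap and promoter rules", {
  # lone Yes/Yes gene -> a one-gene operon
  ann <- ann_from(0L, 500L, "+")
  ops <- predict_operons(ann, flag_table("g01", "g01"))
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$members[[1]], "g01")
  # opposite-strand neighbour stops the operon
  ann <- ann_from(c(0L, 600L), 500L, c("+", "-"))
  ops <- predict_operons(ann, flag_table(c("g01", "g02"), "g01"))
  expect_equal(ops$n_genes, 1L)
  # same strand, small gap: absorbed; large gap: not
  ann <- ann_from(c(0L, 600L, 2000L), 500L, rep("+", 3))
  ops <- predict_operons(ann, flag_table(sprintf("g%02d", 1:3), "g01"))
  expect_equal(ops$members[[1]], c("g01", "g02"))
  # a downstream Yes/Yes promoter starts a new operon
  ann <- ann_from(c(0L, 600L, 1200L), 500L, rep("+", 3))
  ops <- predict_operons(ann, flag_table(sprintf("g%02d", 1:3),
                                         c("g01", "g02")))
  expect_equal(nrow(ops), 2L)
  expect_equal(ops$members[[1]], "g01")
  expect_equal(ops$members[[2]], c("g02", "g03"))
  # minus-strand operons run right-to-left from their leader
  ann <- ann_from(c(0L, 600L, 1200L), 500L, rep("-", 3))
  ops <- predict_operons(ann, flag_table(sprintf("g%02d", 1:3), "g03"))
  expect_equal(ops$members[[1]], c("g03", "g02", "g01"))
})

test_that("the planted island architecture yields 11 operons over 52 genes", {
  gen <- tiny_gen()
  scanned <- annotate_promoters(gen$annotation, gen$sequence)
  ops <- predict_operons(gen$annotation, scanned$flags)
  expect_equal(nrow(ops), 11L)
  expect_equal(sum(ops$n_genes), 52L)
  # number of operons equals the number of Yes/Yes promoters
  expect_equal(nrow(ops), sum(scanned$flags$nifa_flag == "Yes" &
                                scanned$flags$rpon_flag == "Yes"))
  # operons are pairwise disjoint and reproduce the planted units exactly
  all_members <- unlist(ops$members)
  expect_equal(anyDuplicated(all_members), 0L)
  met <- evaluate_recovery(list(operons = ops), gen$truth)
  expect_equal(met$operons$exact_match_fraction, 1.0)
})

test_that("island detection equals the run-length oracle", {
  gen <- micro_gen()
  ann <- gen$annotation
  set.seed(31)
  for (rep in 1:40) {
    flags <- runif(nrow(ann$genes)) < runif(1, 0.1, 0.7)
    min_genes <- sample(1:5, 1)
    # exact maximal member runs at gap 0, and the gapped variant too
    for (gap in c(0L, sample(1:4, 1))) {
      got <- detect_islands(ann, flags, island_config(min_genes, gap))
      want <- oracle_runs(flags, min_genes, gap)
      expect_equal(nrow(got), length(want))
      for (k in seq_along(want)) {
        expect_equal(got$members[[k]], ann$genes$locus_id[want[[k]]])
        # boundaries are member genes
        expect_true(flags[match(got$first_locus[k], ann$genes$locus_id)])
        expect_true(flags[match(got$last_locus[k], ann$genes$locus_id)])
      }
      if (nrow(got) > 1) {
        ends <- match(got$last_locus, ann$genes$locus_id)
        starts <- match(got$first_locus, ann$genes$locus_id)
        expect_true(all(starts[-1] > ends[-length(ends)]))  # sorted, disjoint
      }
    }
  }
})

test_that("raising the gap tolerance never shrinks the largest island", {
  gen <- micro_gen()
  set.seed(13)
  for (rep in 1:10) {
    flags <- runif(30) < 0.4
    largest <- 0L
    for (gap in 0:5) {
      isl <- detect_islands(gen$annotation, flags, island_config(1L, gap))
      now <- if (nrow(isl)) max(isl$gene_count) else 0L
      expect_gte(now, largest)
      largest <- now
    }
  }
})

test_that("island edge cases behave", {
  gen <- micro_gen()
  n <- nrow(gen$annotation$genes)
  all_in <- detect_islands(gen$annotation, rep(TRUE, n))
  expect_equal(nrow(all_in), 1L)
  expect_equal(all_in$gene_count, n)
  expect_equal(nrow(detect_islands(gen$annotation, rep(FALSE, n))), 0L)
})

test_that("island span is max(end) - min(start) over members", {
  ann <- ann_from(c(100L, 2000L), c(900L, 500L), c("+", "+"))
  expect_equal(island_span("g01", ann), 900L)
  expect_equal(island_span(c("g01", "g02"), ann), 2400L)
  expect_equal(island_span(c("g02", "g01"), ann), 2400L)  # order-invariant
  expect_error(island_span("nope", ann), "unknown locus")
  # the generator plants the island span exactly
  gen <- tiny_gen()
  expect_equal(island_span(gen$truth$island$member_loci, gen$annotation),
               49000L)
})
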