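test_that("generation is bit-reproducible given a spec", {
  spec <- micro_spec(seed = 99)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$truth$regulon_loci, b$truth$regulon_loci)
  expect_identical(generate_expression(a$truth, spec),
                   generate_expression(b$truth, spec))
  expect_identical(generate_orthologs(a$truth, spec),
                   generate_orthologs(b$truth, spec))
  # a different seed changes the realisation
  expect_false(identical(generate_genome(micro_spec(seed = 100))$sequence,
                         a$sequence))
})

test_that("a zero-gene spec yields an empty annotation and truth", {
  gen <- generate_genome(simulation_spec(n_genes = 0, seed = 1))
  expect_equal(nrow(gen$annotation$genes), 0L)
  expect_length(gen$truth$regulon_loci, 0L)
  expect_length(gen$truth$operons, 0L)
})

test_that("planted truth matches the requested architecture", {
  gen <- tiny_gen()
  truth <- gen$truth
  expect_length(truth$operons, 11L)
  expect_equal(sum(lengths(lapply(truth$operons, `[[`, "members"))), 52L)
  expect_length(truth$regulon_loci, 72L)          # 52 in-island + 20 outside
  expect_equal(truth$island$span_bp, 49000L)
  # island bounds are regulon members; interior gaps at most 2 genes
  expect_true(truth$island$first_locus %in% truth$regulon_loci)
  expect_true(truth$island$last_locus %in% truth$regulon_loci)
  ord <- gen$annotation$genes$locus_id
  isl_idx <- seq(truth$island$first_index, truth$island$last_index)
  memb <- ord[isl_idx] %in% truth$island$member_loci
  gaps <- rle(memb)
  expect_lte(max(gaps$lengths[!gaps$values]), 2L)
  # operon members share a strand and are contiguous in gene order
  for (op in truth$operons) {
    idx <- match(op$members, ord)
    expect_equal(length(unique(gen$annotation$genes$strand[idx])), 1L)
    expect_equal(sort(idx), min(idx):max(idx))
    expect_equal(op$members[1], op$leader)
  }
  expect_error(simulation_spec(island = list(start_index = 1,
                                             n_island_genes = 5,
                                             n_regulon_in_island = 6,
                                             operon_structure = c(6),
                                             span_bp = 5000)),
               "regulon genes than island|sum")
})

test_that("expression folds are exact in the noiseless limit", {
  spec <- micro_spec(noise_sigma = 0)
  gen <- generate_genome(spec)
  expr <- generate_expression(gen$truth, spec)
  fc_nfix <- compute_fold_changes(expr, "nfix", "nexcess")
  fc_shock <- compute_fold_changes(expr, "shock10", "nfix")
  members <- fc_nfix$locus_id %in% gen$truth$regulon_loci
  expect_equal(fc_nfix$ratio[members], rep(20, sum(members)))
  expect_equal(fc_nfix$ratio[!members], rep(1, sum(!members)))
  expect_equal(fc_shock$ratio[members], rep(0.1, sum(members)))
})

test_that("noisy folds concentrate around the planted effects", {
  spec <- simulation_spec(seed = 17)    # 166 regulon genes, sigma 0.2
  gen <- generate_genome(spec)
  expr <- generate_expression(gen$truth, spec)
  fc <- compute_fold_changes(expr, "nfix", "nexcess")
  members <- fc$locus_id %in% gen$truth$regulon_loci
  expect_equal(mean(fc$ratio[members]), 20, tolerance = 0.1)
  expect_gt(median(fc$ratio[!members]), 0.9)
  expect_lt(median(fc$ratio[!members]), 1.1)
})

test_that("ortholog retention drives the core subset as a binomial", {
  gen <- tiny_gen()
  members <- gen$truth$regulon_loci
  refs <- c("Azoarcus_BH72", "Avinelandii_AvoP")
  # retention 1: full regulon survives; retention 0: nothing does
  spec1 <- tiny_spec(ortholog_retention = 1)
  expect_setequal(core_subset(members, generate_orthologs(gen$truth, spec1),
                              refs), members)
  spec0 <- tiny_spec(ortholog_retention = 0)
  expect_length(core_subset(members, generate_orthologs(gen$truth, spec0),
                            refs), 0L)
  # retention 0.6 over two references on 166 members: binomial(166, 0.36)
  spec <- simulation_spec(seed = 23)
  big <- generate_genome(spec)
  orth <- generate_orthologs(big$truth, spec)
  n_core <- length(core_subset(big$truth$regulon_loci, orth, refs))
  bounds <- qbinom(c(0.005, 0.995), 166, 0.36)
  expect_gte(n_core, bounds[1])
  expect_lte(n_core, bounds[2])
})

test_that("recovery metrics match a brute-force confusion matrix", {
  gen <- micro_gen()
  truth <- gen$truth
  # perfect calls
  perfect <- evaluate_recovery(list(regulon = truth$regulon_loci), truth)
  expect_equal(perfect$regulon[c("sensitivity", "specificity", "jaccard")],
               list(sensitivity = 1, specificity = 1, jaccard = 1))
  # complement calls: zero sensitivity
  comp <- evaluate_recovery(
    list(regulon = setdiff(truth$universe, truth$regulon_loci)), truth)
  expect_equal(comp$regulon$sensitivity, 0)
  expect_equal(comp$regulon$precision, 0)
  # random calls vs manual counting
  set.seed(66)
  for (rep in 1:10) {
    called <- sample(truth$universe, sample(5:25, 1))
    met <- evaluate_recovery(list(regulon = called), truth)$regulon
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (g in truth$universe) {
      in_call <- g %in% called
      in_truth <- g %in% truth$regulon_loci
      if (in_call && in_truth) tp <- tp + 1
      if (in_call && !in_truth) fp <- fp + 1
      if (!in_call && in_truth) fn <- fn + 1
      if (!in_call && !in_truth) tn <- tn + 1
    }
    expect_equal(met$sensitivity, tp / (tp + fn))
    expect_equal(met$specificity, tn / (tn + fp))
    expect_equal(met$jaccard, tp / (tp + fp + fn))
  }
  expect_error(evaluate_recovery(list(regulon = "not_a_locus"), truth),
               "universe")
})
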