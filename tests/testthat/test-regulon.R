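table1_labels <- function() {
  t1 <- nif_island_table1()
  list(nfix = setNames(classify_regulation(t1$nfix_fold), t1$locus_id),
       shock = setNames(classify_regulation(t1$shock_ratio), t1$locus_id))
}

test_that("regulon membership is the up-and-shock-down intersection", {
  labs <- table1_labels()
  reg <- infer_regulon(labs$nfix, labs$shock)
  expect_true(reg$member[reg$locus_id == "PST1306"])   # 21.46 up, 0.06 down
  expect_false(reg$member[reg$locus_id == "PST1310"])  # 1.02 / 1.03 unchanged
  expect_false(reg$member[reg$locus_id == "PST1327"])  # up but shock 0.56
  expect_true(all(regulon_members(reg) %in%
                    reg$locus_id[reg$up_in_nfix]))     # members <= up-set
  expect_equal(reg$member, reg$up_in_nfix & reg$down_after_shock)
  # empty universe and mismatched universes
  expect_equal(nrow(infer_regulon(character(), character())), 0L)
  expect_error(infer_regulon(c(a = "up"), c(b = "down")), "universe")
})

test_that("core subsets require presence in every reference genome", {
  members <- c("g1", "g2", "g3", "g4")
  orth <- data.frame(locus_id = c("g1", "g2", "g3"),
                     BH72 = c(TRUE, TRUE, FALSE),
                     AvoP = c(TRUE, FALSE, TRUE))
  expect_equal(core_subset(members, orth, character()), members)
  expect_equal(core_subset(members, orth, c("BH72", "AvoP")), "g1")
  expect_equal(core_subset(members, orth, "BH72"), c("g1", "g2"))
  # g4 absent from the table counts as absent everywhere
  expect_false("g4" %in% core_subset(members, orth, "BH72"))
  expect_error(core_subset(members, orth, "Kpneumoniae"), "unknown reference")
})

test_that("core subsets agree with a brute-force filter on random tables", {
  set.seed(21)
  for (rep in 1:10) {
    loci <- sprintf("g%02d", 1:40)
    members <- sample(loci, 15)
    orth <- data.frame(locus_id = sample(loci, 35),
                       r1 = sample(c(TRUE, FALSE), 35, replace = TRUE),
                       r2 = sample(c(TRUE, FALSE), 35, replace = TRUE))
    manual <- character()
    for (m in members) {
      row <- orth[orth$locus_id == m, ]
      if (nrow(row) == 1 && isTRUE(row$r1) && isTRUE(row$r2))
        manual <- c(manual, m)
    }
    expect_setequal(core_subset(members, orth, c("r1", "r2")), manual)
  }
})

test_that("core-genome overlap is plain set intersection", {
  expect_equal(core_genome_overlap(c("a", "b"), c("c", "d")), character())
  core24 <- pseudomonas_core_regulon()
  expect_length(core_genome_overlap(core24, core24), 24L)
  set.seed(3)
  for (rep in 1:10) {
    a <- sample(letters, 12); b <- sample(letters, 9)
    expect_setequal(core_genome_overlap(a, b), intersect(a, b))
  }
})

test_that("island partition splits members exactly", {
  labs <- table1_labels()
  members <- regulon_members(infer_regulon(labs$nfix, labs$shock))
  part <- island_partition(members, c("PST1302", "PST1359"))
  expect_true("PST1326" %in% part$inside)
  expect_equal(part$outside, character())   # the whole table is the island
  expect_setequal(c(part$inside, part$outside), members)
  expect_length(intersect(part$inside, part$outside), 0L)
})

test_that("bp-interval island partition matches a brute-force overlap test", {
  gen <- tiny_gen()
  ann <- gen$annotation
  set.seed(8)
  for (rep in 1:5) {
    members <- sample(ann$genes$locus_id, 40)
    lo <- sample.int(ann$sequence_length - 60000L, 1L)
    island <- c(lo, lo + 50000L)
    part <- island_partition(members, island, ann)
    g <- ann$genes
    manual <- vapply(members, function(m) {
      row <- g[g$locus_id == m, ]
      row$start < island[2] && row$end > island[1]
    }, logical(1))
    expect_setequal(part$inside, members[manual])
    expect_setequal(part$outside, members[!manual])
  }
  # locus-range partition using the annotation's gene order
  first <- gen$truth$island$first_locus
  last <- gen$truth$island$last_locus
  part <- island_partition(gen$truth$regulon_loci, c(first, last), ann)
  expect_length(part$inside, 52L)
  expect_length(part$outside, 20L)
})

test_that("category summaries count planted proportions exactly", {
  expect_equal(categorize_functions("g1", c(g1 = "nif"))$proportion, 1.0)
  # planted composition of a 95-gene core subset
  planted <- c(nif = 19L, regulation = 7L, transport_metabolism = 37L,
               energy = 15L, unknown = 15L, other = 2L)
  genes <- sprintf("g%02d", 1:95)
  cmap <- setNames(rep(names(planted), planted), genes)
  set.seed(4)
  summ <- categorize_functions(sample(genes), cmap)
  expect_equal(setNames(summ$n, summ$category)[names(planted)], planted)
  expect_equal(sum(summ$proportion), 1, tolerance = 1e-9)
  expect_equal(summ$proportion[summ$category == "nif"], 0.2)
  # empty set: no rows, no division by zero
  expect_equal(nrow(categorize_functions(character(), cmap)), 0L)
  # unmapped genes fall into "unknown"
  summ2 <- categorize_functions(c("g01", "zzz"), cmap)
  expect_equal(summ2$n[summ2$category == "unknown"], 1L)
})
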