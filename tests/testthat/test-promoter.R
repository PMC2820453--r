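test_that("gapped patterns compile to the right geometry", {
  uas <- compile_pattern("TGT-N10-ACA")
  expect_equal(uas$total_length, 16L)           # 3 + 10 + 3
  expect_equal(sum(uas$is_gap), 10L)
  rpon <- compile_pattern("TGGCAC-N5-TTGC", 1)
  expect_equal(rpon$total_length, 15L)          # 6 + 5 + 4
  expect_equal(rpon$max_mismatches, 1L)
  a <- compile_pattern("A")
  expect_equal(scan_sequence("A", a, "+")$position, 0L)
  expect_equal(nrow(scan_sequence("C", a, "+")), 0L)
  expect_error(compile_pattern("TGT-N1O-ACA"), "malformed")
  expect_error(compile_pattern("TGT~ACA"), "malformed")
})

test_that("planted and absent motifs are found and not found", {
  uas <- compile_pattern("TGT-N10-ACA")
  seq <- paste0("TGT", strrep("A", 10), "ACA")
  hit <- scan_sequence(seq, uas, "+")
  expect_equal(hit$position, 0L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(nrow(scan_sequence(strrep("A", 100), uas)), 0L)
  # shorter than the pattern: empty result, not an error
  expect_equal(nrow(scan_sequence("ACGT", uas)), 0L)
})

test_that("subject N is a mismatch at fixed positions, a match in gaps", {
  pat0 <- compile_pattern("TGT-N10-ACA", 0)
  pat1 <- compile_pattern("TGT-N10-ACA", 1)
  with_gap_n <- paste0("TGT", strrep("N", 10), "ACA")
  expect_equal(nrow(scan_sequence(with_gap_n, pat0, "+")), 1L)
  with_fixed_n <- paste0("NGT", strrep("A", 10), "ACA")
  expect_equal(nrow(scan_sequence(with_fixed_n, pat0, "+")), 0L)
  hit <- scan_sequence(with_fixed_n, pat1, "+")
  expect_equal(hit$mismatches, 1L)
})

test_that("the scanner agrees with the sliding-window oracle", {
  set.seed(101)
  patterns <- c("TGT-N10-ACA", "TGGCAC-N5-TTGC", "RRYW-N3-SWG")
  for (rep in 1:60) {
    spec <- sample(patterns, 1)
    budget <- sample(0:2, 1)
    seq <- random_seq(sample(30:150, 1), with_n = rep %% 5 == 0)
    got <- scan_sequence(seq, compile_pattern(spec, budget))
    want <- oracle_scan(seq, spec, budget)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("hits respect reverse-complement and downstream-append symmetry", {
  set.seed(55)
  pat <- compile_pattern("TGGCAC-N5-TTGC", 1)
  for (rep in 1:20) {
    seq <- random_seq(120)
    hits <- scan_sequence(seq, pat)
    # revcomp: positions mirror, strands swap
    rc_hits <- scan_sequence(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))), pat)
    mirrored <- data.frame(position = nchar(seq) - 15L - rc_hits$position,
                           strand = chartr("+-", "-+", rc_hits$strand),
                           mismatches = rc_hits$mismatches)
    mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
    expect_equal(hits$position, mirrored$position)
    expect_equal(hits$strand, mirrored$strand)
    # appending downstream sequence never disturbs existing hits
    longer <- scan_sequence(paste0(seq, random_seq(40)), pat)
    expect_true(all(paste(hits$position, hits$strand) %in%
                      paste(longer$position, longer$strand)))
  }
})

test_that("UAS false positives on random sequence stay near 4^-6 per window", {
  set.seed(77)
  pat <- compile_pattern("TGT-N10-ACA")
  n_windows <- 0; n_hits <- 0
  for (rep in 1:40) {
    seq <- random_seq(2000)
    n_windows <- n_windows + 2 * (2000 - 16 + 1)
    n_hits <- n_hits + nrow(scan_sequence(seq, pat))
  }
  expected <- n_windows * 4^-6
  expect_lt(n_hits, 3 * expected + 5)
})

test_that("upstream extraction honours strand, truncation and wrapping", {
  genome <- random_seq(1000)
  plus <- list(locus_id = "p", start = 400L, end = 700L, strand = "+")
  up <- extract_upstream(plus, genome, 400)
  expect_equal(up$seq, substr(genome, 1, 400))
  # truncation at a linear contig edge
  near <- list(locus_id = "n", start = 50L, end = 300L, strand = "+")
  expect_equal(nchar(extract_upstream(near, genome, 400)$seq), 50L)
  # circular wrap restores the full window
  expect_equal(nchar(extract_upstream(near, genome, 400,
                                      circular = TRUE)$seq), 400L)
  expect_equal(extract_upstream(near, genome, 400, circular = TRUE)$seq,
               paste0(substr(genome, 651, 1000), substr(genome, 1, 50)))
  expect_error(extract_upstream(plus, genome, 0), "positive")
})

test_that("minus-strand extraction mirrors the plus-strand case", {
  set.seed(12)
  genome <- random_seq(600)
  minus <- list(locus_id = "m", start = 100L, end = 250L, strand = "-")
  up_minus <- extract_upstream(minus, genome, 200)
  # mirrored gene on the reverse-complemented genome
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  mirrored <- list(locus_id = "m2", start = 600L - 250L, end = 600L - 100L,
                   strand = "+")
  up_plus <- extract_upstream(mirrored, rc, 200)
  expect_equal(up_minus$seq, up_plus$seq)
})

test_that("promoter flags implement the 100-bp UAS spacing rule", {
  cfg <- scan_config()
  gene <- list(locus_id = "g", strand = "+")
  uas <- paste0("TGT", strrep("A", 10), "ACA")
  rpon <- paste0("TGGCAC", "GGGGG", "TTGC")
  pad <- function(n) strrep("C", n)
  # UAS ends 150 bp before the start; promoter element close in: Yes/Yes
  up1 <- paste0(pad(400 - 16 - 150), uas, pad(150 - 15 - 20), rpon, pad(20))
  ann1 <- annotate_promoter(gene, up1, cfg)
  expect_equal(ann1$nifa_flag, "Yes")
  expect_equal(ann1$rpon_flag, "Yes")
  expect_equal(max(ann1$uas_hits$distance_to_start), 150L)
  # UAS ends only 50 bp before the start: spacing rule fails
  up2 <- paste0(pad(400 - 16 - 50), uas, pad(50 - 15 - 20), rpon, pad(20))
  ann2 <- annotate_promoter(gene, up2, cfg)
  expect_equal(ann2$nifa_flag, "No")
  expect_equal(ann2$rpon_flag, "Yes")
})

test_that("the printed consensus columns flag 11 Yes/Yes island loci", {
  t1 <- nif_island_table1()
  yy <- t1$locus_id[t1$nifa_flag %in% "Yes" & t1$rpon_flag %in% "Yes"]
  expect_length(yy, 11L)
  expect_setequal(yy, c("PST1306", "PST1314", "PST1315", "PST1325",
                        "PST1326", "PST1333", "PST1338", "PST1344",
                        "PST1348", "PST1349", "PST1359"))
})

test_that("every planted promoter is recovered in genome coordinates", {
  gen <- tiny_gen()
  scanned <- annotate_promoters(gen$annotation, gen$sequence)
  planted <- gen$truth$motifs
  found <- paste(scanned$hits$pattern, scanned$hits$genome_start,
                 scanned$hits$strand)
  expect_true(all(paste(planted$pattern, planted$genome_start,
                        planted$strand) %in% found))
  # leaders, and only leaders, are flagged Yes/Yes
  leaders <- vapply(gen$truth$operons, `[[`, character(1), "leader")
  yy <- scanned$flags$locus_id[scanned$flags$nifa_flag == "Yes" &
                                 scanned$flags$rpon_flag == "Yes"]
  expect_setequal(yy, leaders)
})
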