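# Synthetic genomes, expression matrices and ortholog tables with planted
# truth, emulating the design of a two-steady-state (nitrogen fixation vs
# nitrogen excess) plus one ammonium-shock-time-point array study over a
# bacterial genome carrying a contiguous nitrogen-fixation expression
# island: co-regulated operons headed by NifA-UAS + sigma-54 promoters,
# interspersed with a few non-regulated genes, plus regulon members
# scattered outside the island.

derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

#' Simulation settings with planted truth
#'
#' Defaults emulate the architecture of the A1501 study: a 1,000-gene
#' genome with a 58-gene island spanning 49 kb in which 52 regulon genes
#' form 11 operons, 114 further regulon genes outside the island (166 in
#' all), ~20-fold induction under nitrogen fixation, 10-fold repression
#' 10 min after ammonium shock, log-normal multiplicative noise, and an
#' ortholog retention probability of 0.6 per reference genome.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Gene length range (bp) outside the island.
#' @param intergenic_range Gap range (bp) between transcription units.
#' @param operon_intergenic_range Gap range (bp) within operons; stays
#'   below the default operon-joining threshold.
#' @param island List: `start_index` (gene index where the island
#'   starts), `n_island_genes`, `n_regulon_in_island`,
#'   `operon_structure` (operon sizes, summing to
#'   `n_regulon_in_island`), `span_bp` (exact island span planted by
#'   scaling island gene lengths).
#' @param n_regulon_outside Regulon members planted outside the island.
#' @param effect_size_nfix Linear fold induction of regulon genes under
#'   nitrogen fixation vs nitrogen excess (default 20).
#' @param effect_size_shock Linear fold of regulon genes 10 min after
#'   ammonium shock relative to nitrogen fixation (default 0.1).
#' @param noise_sigma SD of log-intensity noise per condition
#'   (default 0.2).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters.
#' @param ortholog_retention Probability a gene has an ortholog in a
#'   reference genome, independent per gene and reference (default 0.6).
#' @param seed Integer seed; all generators are deterministic given the
#'   spec.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 1000,
                            gene_length_range = c(600, 1500),
                            intergenic_range = c(250, 400),
                            operon_intergenic_range = c(20, 150),
                            island = list(start_index = 400,
                                          n_island_genes = 58,
                                          n_regulon_in_island = 52,
                                          operon_structure = c(5, 2, 7, 3, 8,
                                                               2, 5, 6, 1, 4,
                                                               9),
                                          span_bp = 49000),
                            n_regulon_outside = 114,
                            effect_size_nfix = 20,
                            effect_size_shock = 0.1,
                            noise_sigma = 0.2,
                            baseline_meanlog = log(500),
                            baseline_sdlog = 0.5,
                            ortholog_retention = 0.6,
                            seed = 1) {
  spec <- structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = gene_length_range,
    intergenic_range = intergenic_range,
    operon_intergenic_range = operon_intergenic_range,
    island = island, n_regulon_outside = as.integer(n_regulon_outside),
    effect_size_nfix = effect_size_nfix,
    effect_size_shock = effect_size_shock,
    noise_sigma = noise_sigma, baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    ortholog_retention = ortholog_retention, seed = as.integer(seed)),
    class = "simulation_spec")
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  stopifnot(spec$n_genes >= 0,
            spec$effect_size_nfix > 0, spec$effect_size_shock > 0,
            spec$noise_sigma >= 0,
            spec$ortholog_retention >= 0, spec$ortholog_retention <= 1)
  if (spec$n_genes == 0L) return(invisible(spec))
  isl <- spec$island
  if (sum(isl$operon_structure) != isl$n_regulon_in_island)
    stop("operon sizes must sum to n_regulon_in_island")
  if (isl$n_regulon_in_island > isl$n_island_genes)
    stop("more regulon genes than island genes")
  if (isl$start_index < 1L ||
      isl$start_index + isl$n_island_genes - 1L > spec$n_genes)
    stop("island does not fit in the genome")
  n_outside <- spec$n_genes - isl$n_island_genes
  if (spec$n_regulon_outside > max(0L, n_outside - 12L))
    stop("too many outside regulon genes for the genome size")
  invisible(spec)
}

# Island gene roles: a vector over the island's gene slots with entries
# "operon <k>" (integer operon index) or 0 for a non-regulated gap gene.
# Gap genes sit at interior operon junctions (never at the island
# edges), at most 2 per junction so the island never fragments.
plan_island_roles <- function(isl) {
  n_ops <- length(isl$operon_structure)
  n_gap <- isl$n_island_genes - isl$n_regulon_in_island
  n_junction <- n_ops - 1L
  if (n_gap > 0L && n_junction == 0L)
    stop("gap genes need at least two operons")
  repeat {
    alloc <- if (n_gap == 0L) integer(n_junction) else
      tabulate(sample.int(n_junction, n_gap, replace = TRUE), n_junction)
    if (n_gap == 0L || max(alloc) <= 2L) break
  }
  roles <- integer(0)
  for (k in seq_len(n_ops)) {
    roles <- c(roles, rep(k, isl$operon_structure[k]))
    if (k <= n_junction) roles <- c(roles, rep(0L, alloc[k]))
  }
  roles
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# overwrite genome_seq[at, at + nchar(what)) (0-based) with `what`
plant_seq <- function(genome_seq, at, what) {
  paste0(substr(genome_seq, 1L, at),
         what,
         substr(genome_seq, at + nchar(what) + 1L, nchar(genome_seq)))
}

#' Generate a synthetic annotated genome with planted promoters
#'
#' Lays out genes per the spec (island operons with small intra-operon
#' gaps, larger gaps between transcription units), draws a random-base
#' sequence, and plants, upstream of every operon leader, a NifA UAS
#' ending at least 100 bp (plus jitter) before the gene start and a
#' sigma-54 -24/-12 element close to the start. Chance occurrences of
#' the sigma-54 element in upstream windows elsewhere are removed by
#' single-base edits so the planted promoters are the only ones; UAS
#' chance occurrences are left in place (they are inert without the
#' promoter element and their background rate is part of what the
#' scanner's false-positive accounting measures). Deterministic given
#' the spec (including its seed).
#'
#' @param spec A [simulation_spec()].
#' @return List: `annotation` ([genome_annotation()]), `sequence` (DNA
#'   string) and `truth` (planted regulon loci, island bounds and
#'   members, operons, motif coordinates, per-gene true folds).
#' @export
generate_genome <- function(spec) {
  validate_simulation_spec(spec)
  if (spec$n_genes == 0L) {
    ann <- genome_annotation("synthetic_chr", empty_gene_table(), 1000L)
    return(list(annotation = ann, sequence = random_dna_seeded(spec, 1000L),
                truth = empty_truth(spec)))
  }
  set.seed(derive_seed(spec$seed, 1L))
  isl <- spec$island
  n <- spec$n_genes
  isl_idx <- seq(isl$start_index, isl$start_index + isl$n_island_genes - 1L)
  roles <- integer(n)                      # 0 = not in an operon
  roles[isl_idx] <- plan_island_roles(isl)
  in_island <- seq_len(n) %in% isl_idx

  # transcription units: each operon is one TU, every other gene its own
  tu <- integer(n)
  tu_next <- 1L
  for (i in seq_len(n)) {
    if (roles[i] > 0L && i > 1L && roles[i - 1L] == roles[i] &&
        in_island[i - 1L]) {
      tu[i] <- tu[i - 1L]
    } else {
      tu[i] <- tu_next
      tu_next <- tu_next + 1L
    }
  }
  tu_strand <- sample(c("+", "-"), tu_next - 1L, replace = TRUE)
  strand <- tu_strand[tu]

  # lengths; island genes drawn tighter, then scaled to hit span_bp
  len <- integer(n)
  len[!in_island] <- round(runif(sum(!in_island),
                                 spec$gene_length_range[1L],
                                 spec$gene_length_range[2L]))
  raw_isl <- runif(isl$n_island_genes, 600, 900)
  gap_after <- round(ifelse(
    tu[-1L] == tu[-n],
    runif(n - 1L, spec$operon_intergenic_range[1L],
          spec$operon_intergenic_range[2L]),
    runif(n - 1L, spec$intergenic_range[1L], spec$intergenic_range[2L])))
  if (!is.null(isl$span_bp)) {
    gaps_inside <- sum(gap_after[isl_idx[-length(isl_idx)]])
    target <- isl$span_bp - gaps_inside
    scaled <- round(raw_isl * target / sum(raw_isl))
    scaled[length(scaled)] <- target - sum(scaled[-length(scaled)])
    if (any(scaled < 300))
      stop("island span_bp too small for its gene count")
    len[isl_idx] <- scaled
  } else {
    len[isl_idx] <- round(raw_isl)
  }

  margin <- 500L
  start <- integer(n)
  pos <- margin
  for (i in seq_len(n)) {
    start[i] <- pos
    pos <- pos + len[i] + if (i < n) gap_after[i] else 0L
  }
  end <- start + len
  seq_len_total <- pos + margin
  locus <- sprintf("SYN%04d", seq_len(n))

  genome_seq <- random_dna(seq_len_total)

  # plant UAS + sigma-54 element upstream of each operon leader
  n_ops <- length(isl$operon_structure)
  motifs <- list()
  operons <- vector("list", n_ops)
  for (k in seq_len(n_ops)) {
    op_idx <- which(roles == k)
    s <- strand[op_idx[1L]]
    memb_order <- if (s == "+") op_idx else rev(op_idx)
    leader <- memb_order[1L]
    operons[[k]] <- list(leader = locus[leader],
                         members = locus[memb_order], strand = s)
    uas_seq <- paste0("TGT", random_dna(10L), "ACA")
    rpon_seq <- paste0("TGGCAC", random_dna(5L), "TTGC")
    d_uas <- 100L + sample.int(31L, 1L) - 1L     # 100..130 bp spacing
    d_rpon <- sample(12:25, 1L)
    if (s == "+") {
      uas_at <- start[leader] - d_uas - 16L
      rpon_at <- start[leader] - d_rpon - 15L
      genome_seq <- plant_seq(genome_seq, uas_at, uas_seq)
      genome_seq <- plant_seq(genome_seq, rpon_at, rpon_seq)
    } else {
      uas_at <- end[leader] + d_uas
      rpon_at <- end[leader] + d_rpon
      genome_seq <- plant_seq(genome_seq, uas_at, revcomp_dna(uas_seq))
      genome_seq <- plant_seq(genome_seq, rpon_at, revcomp_dna(rpon_seq))
    }
    motifs[[length(motifs) + 1L]] <- data.frame(
      locus_id = locus[leader],
      pattern = c("NifA_UAS", "RpoN_promoter"),
      genome_start = c(uas_at, rpon_at),
      genome_end = c(uas_at + 16L, rpon_at + 15L),
      strand = s, distance_to_start = c(d_uas, d_rpon),
      stringsAsFactors = FALSE)
  }
  motifs <- do.call(rbind, motifs)

  # regulon membership: all operon genes + scattered outside members
  # (kept >= 6 genes clear of the island so its boundaries stay crisp)
  members <- roles > 0L
  buffer <- c(max(1L, isl_idx[1L] - 6L):min(n, isl_idx[length(isl_idx)] + 6L))
  eligible <- setdiff(which(!in_island), buffer)
  outside_members <- sort(sample(eligible, spec$n_regulon_outside))
  members[outside_members] <- TRUE

  categories <- assign_categories(members)
  genes <- data.frame(
    locus_id = locus, name = NA_character_, start = start, end = end,
    strand = strand,
    product = ifelse(roles > 0L, "nitrogen fixation island protein",
                     ifelse(members, "nitrogen fixation-inducible protein",
                            "hypothetical protein")),
    category = categories, stringsAsFactors = FALSE)
  annotation <- genome_annotation("synthetic_chr", genes, seq_len_total)

  truth <- structure(list(
    spec = spec,
    universe = locus,
    regulon_loci = locus[members],
    island = list(first_locus = locus[isl_idx[1L]],
                  last_locus = locus[isl_idx[length(isl_idx)]],
                  first_index = isl_idx[1L],
                  last_index = isl_idx[length(isl_idx)],
                  member_loci = locus[roles > 0L],
                  span_bp = max(end[roles > 0L]) - min(start[roles > 0L])),
    operons = operons,
    motifs = motifs,
    true_folds = data.frame(
      locus_id = locus,
      nfix_fold = ifelse(members, spec$effect_size_nfix, 1),
      shock_fold = ifelse(members, spec$effect_size_shock, 1),
      stringsAsFactors = FALSE)),
    class = "synthetic_truth")

  genome_seq <- scrub_chance_promoters(genome_seq, annotation, motifs)
  list(annotation = annotation, sequence = genome_seq, truth = truth)
}

random_dna_seeded <- function(spec, n) {
  set.seed(derive_seed(spec$seed, 1L))
  random_dna(n)
}

empty_truth <- function(spec) {
  structure(list(spec = spec, universe = character(),
                 regulon_loci = character(), island = NULL,
                 operons = list(), motifs = NULL,
                 true_folds = data.frame(locus_id = character(),
                                         nfix_fold = numeric(),
                                         shock_fold = numeric())),
            class = "synthetic_truth")
}

assign_categories <- function(members) {
  n <- length(members)
  out <- character(n)
  reg_levels <- c("nif", "regulation", "transport_metabolism", "energy",
                  "unknown", "other")
  reg_probs <- c(0.20, 0.07, 0.39, 0.16, 0.16, 0.02)
  out[members] <- sample(reg_levels, sum(members), replace = TRUE,
                         prob = reg_probs)
  out[!members] <- sample(c("transport_metabolism", "energy", "unknown",
                            "other"),
                          sum(!members), replace = TRUE,
                          prob = c(0.25, 0.10, 0.35, 0.30))
  out
}

# Remove chance sigma-54 promoter occurrences from every gene's
# coding-strand upstream window by single-base edits, leaving planted
# motifs untouched; iterates until a full rescan is clean.
scrub_chance_promoters <- function(genome_seq, annotation,
                                   planted, cfg = scan_config()) {
  g <- annotation$genes
  pat <- cfg$rpon_pattern
  planted_at <- function(pos) {
    any(pos >= planted$genome_start & pos < planted$genome_end)
  }
  for (round in 1:8) {
    clean <- TRUE
    for (i in seq_len(nrow(g))) {
      gene <- g[i, ]
      up <- extract_upstream(gene, genome_seq, cfg$upstream_window,
                             circular = annotation$circular)
      hits <- scan_sequence(up$seq, pat, strands = "+")
      if (!nrow(hits)) next
      up_codes <- dna_ints(up$seq)
      for (h in seq_len(nrow(hits))) {
        p0 <- hits$position[h]
        # genome position of each motif offset under the window mapping
        gpos <- if (gene$strand == "+")
          up$genome_start + p0 + seq_len(pat$total_length) - 1L
        else
          up$genome_end - (p0 + seq_len(pat$total_length) - 1L) - 1L
        fixed <- which(!pat$is_gap)
        matched <- fixed[pat$ok[cbind(up_codes[p0 + fixed], fixed)]]
        editable <- matched[!vapply(gpos[matched], planted_at, logical(1L))]
        if (!length(editable)) next      # hit inseparable from a planted motif
        j <- if (length(editable) == 1L) editable else sample(editable, 1L)
        old <- substr(genome_seq, gpos[j] + 1L, gpos[j] + 1L)
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        genome_seq <- plant_seq(genome_seq, gpos[j], new)
        clean <- FALSE
      }
    }
    if (clean) break
  }
  genome_seq
}

#' Generate a synthetic expression matrix
#'
#' Per-gene baseline intensities are log-normal; regulon genes are
#' multiplied by `effect_size_nfix` under `nfix` (vs the `nexcess`
#' baseline) and by `effect_size_shock` under `shock10` relative to
#' `nfix`. Independent multiplicative log-normal noise of SD
#' `noise_sigma` (log scale) is applied per condition. Deterministic
#' given the spec.
#'
#' @param truth Truth object from [generate_genome()].
#' @param spec The same [simulation_spec()].
#' @return Positive matrix, rows = loci, columns `nfix`, `nexcess`,
#'   `shock10`.
#' @export
generate_expression <- function(truth, spec = truth$spec) {
  set.seed(derive_seed(spec$seed, 2L))
  n <- length(truth$universe)
  baseline <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  tf <- truth$true_folds
  mu <- cbind(nfix = baseline * tf$nfix_fold,
              nexcess = baseline,
              shock10 = baseline * tf$nfix_fold * tf$shock_fold)
  noise <- matrix(exp(rnorm(3L * n, 0, spec$noise_sigma)), ncol = 3L)
  m <- mu * noise
  rownames(m) <- truth$universe
  m
}

#' Generate a synthetic ortholog presence table
#'
#' Every gene is present in each reference genome independently with
#' probability `ortholog_retention`. Deterministic given the spec.
#'
#' @param truth Truth object from [generate_genome()].
#' @param spec The same [simulation_spec()].
#' @param references Reference genome names.
#' @return `data.frame`: `locus_id` plus one logical column per
#'   reference.
#' @export
generate_orthologs <- function(truth, spec = truth$spec,
                               references = c("Azoarcus_BH72",
                                              "Avinelandii_AvoP")) {
  set.seed(derive_seed(spec$seed, 3L))
  out <- data.frame(locus_id = truth$universe, stringsAsFactors = FALSE)
  for (ref in references)
    out[[ref]] <- rbinom(length(truth$universe), 1L,
                         spec$ortholog_retention) == 1L
  out
}

#' Score recovery of planted truth
#'
#' Confusion-matrix metrics for the called regulon, boundary offsets (in
#' genes) for the detected island best matching the planted one, and the
#' exact-match fraction over planted operons.
#'
#' @param calls List with any of: `regulon` (character vector of called
#'   member loci), `islands` ([detect_islands()] table), `operons`
#'   ([predict_operons()] table).
#' @param truth Truth object from [generate_genome()].
#' @return List with components `regulon` (`sensitivity`, `specificity`,
#'   `precision`, `jaccard`), `island` (`first_offset`, `last_offset`,
#'   `n_islands`), `operons` (`n_called`, `exact_match_fraction`) —
#'   each `NULL` when the corresponding call set was not supplied.
#' @export
evaluate_recovery <- function(calls, truth) {
  out <- list(regulon = NULL, island = NULL, operons = NULL)
  if (!is.null(calls$regulon)) {
    if (length(setdiff(calls$regulon, truth$universe)))
      stop("called regulon contains loci outside the truth universe")
    pos <- truth$universe %in% truth$regulon_loci
    called <- truth$universe %in% calls$regulon
    tp <- sum(called & pos); fp <- sum(called & !pos)
    fn <- sum(!called & pos); tn <- sum(!called & !pos)
    out$regulon <- list(
      sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
      precision = if (tp + fp) tp / (tp + fp) else NA_real_,
      jaccard = if (tp + fp + fn) tp / (tp + fp + fn) else NA_real_)
  }
  if (!is.null(calls$islands)) {
    isl <- truth$island
    ni <- nrow(calls$islands)
    if (ni == 0L || is.null(isl)) {
      out$island <- list(first_offset = NA_integer_,
                         last_offset = NA_integer_, n_islands = ni)
    } else {
      overlap <- vapply(calls$islands$members, function(m)
        length(intersect(m, isl$member_loci)), integer(1L))
      best <- which.max(overlap)
      out$island <- list(
        first_offset = match(calls$islands$first_locus[best],
                             truth$universe) - isl$first_index,
        last_offset = match(calls$islands$last_locus[best],
                            truth$universe) - isl$last_index,
        n_islands = ni)
    }
  }
  if (!is.null(calls$operons)) {
    planted <- lapply(truth$operons, `[[`, "members")
    called_sets <- calls$operons$members
    exact <- vapply(planted, function(p)
      any(vapply(called_sets, setequal, logical(1L), p)), logical(1L))
    out$operons <- list(
      n_called = nrow(calls$operons),
      exact_match_fraction = if (length(planted)) mean(exact) else NA_real_)
  }
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the exact file formats the pipeline consumes — GFF3 + FASTA
#' annotation, expression TSV, ortholog TSV, category-map TSV — plus the
#' planted truth as JSON.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (and the in-memory `truth`),
#'   invisibly.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_genome(spec)
  expr <- generate_expression(gen$truth, spec)
  orth <- generate_orthologs(gen$truth, spec)
  paths <- list(
    gff3 = file.path(dir, "genome.gff3"),
    fasta = file.path(dir, "genome.fna"),
    expression = file.path(dir, "expression.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    category_map = file.path(dir, "category_map.tsv"),
    truth_json = file.path(dir, "truth.json"))
  write_annotations(gen$annotation, paths$gff3, sequence = gen$sequence,
                    fasta_path = paths$fasta)
  write_expression(expr, paths$expression)
  write_ortholog_table(orth, paths$orthologs)
  write.table(data.frame(locus_id = gen$annotation$genes$locus_id,
                         category = gen$annotation$genes$category),
              paths$category_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- gen$truth
  truth_json$spec <- unclass(truth_json$spec)
  jsonlite::write_json(unclass(truth_json), paths$truth_json,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth = gen$truth)))
}
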