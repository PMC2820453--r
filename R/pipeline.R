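# Orchestration: run the full analysis (expression -> regulon -> scan ->
# operons -> islands -> report) from a YAML/list configuration, writing
# every stage's output and a summary report whose internal consistency
# (partition sums, containments) is asserted at write time.

PIPELINE_CONFIG_KEYS <- c("inputs", "conditions", "thresholds", "scan",
                          "operon", "island_detection", "island",
                          "out_dir", "seed")

#' Run the full analysis pipeline
#'
#' Stages run in order: fold-change classification of the
#' nitrogen-fixation (nfix vs nexcess) and ammonium-shock (shock10 vs
#' nfix) contrasts; regulon inference by condition intersection;
#' ortholog core subset; core-genome overlap; promoter scanning; operon
#' prediction; island detection and regulon partition; functional
#' categories; report. Stages whose optional inputs are absent are
#' skipped with a logged notice.
#'
#' @param config Path to a YAML file or an equivalent nested list.
#'   Recognised top-level keys: `inputs` (paths: `expression`, `gff3`,
#'   `fasta`, `orthologs`, `core_genome`, `category_map`; plus
#'   `required_references`), `conditions` (names of the `nfix`,
#'   `nexcess`, `shock10` columns), `thresholds` (`up_cut`, `down_cut`,
#'   `pseudocount`), `scan` (`upstream_window`, `min_uas_distance`,
#'   `uas_pattern`, `uas_mismatches`, `rpon_pattern`, `rpon_mismatches`,
#'   `uas_strands`), `operon` (`max_intergenic_gap`,
#'   `require_same_strand`), `island_detection` (`min_genes`,
#'   `max_gap_genes`), `island` (locus-ID range `c(first, last)` for the
#'   partition; defaults to the largest detected island), `out_dir`,
#'   `seed`.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#'   `NULL` disables file output.
#' @return The summary report (list of class `summary_report`),
#'   invisibly containing the per-stage objects in attribute `stages`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  bad <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(bad))
    stop("unknown config key: ", paste(bad, collapse = ", "))
  inputs <- config$inputs
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) if (is.null(out_dir)) NULL else
    file.path(out_dir, name)

  conds <- modify_defaults(list(nfix = "nfix", nexcess = "nexcess",
                                shock10 = "shock10"), config$conditions)
  thr <- modify_defaults(list(up_cut = 2, down_cut = 0.5, pseudocount = 0),
                         config$thresholds)
  cfg_de <- de_config(thr$up_cut, thr$down_cut, thr$pseudocount)

  # -- expression ----------------------------------------------------
  if (is.null(inputs$expression))
    stop("config must name an expression matrix under inputs$expression")
  expr <- read_expression(inputs$expression)
  fc_nfix <- classify_contrast(expr, conds$nfix, conds$nexcess, cfg_de)
  fc_shock <- classify_contrast(expr, conds$shock10, conds$nfix, cfg_de)
  stage_log("expression", sprintf(
    "%d genes; nfix contrast %d up / %d down; shock contrast %d up / %d down",
    nrow(expr), sum(fc_nfix$label == "up"), sum(fc_nfix$label == "down"),
    sum(fc_shock$label == "up"), sum(fc_shock$label == "down")))
  if (!is.null(out_dir)) {
    write_tsv_dot(fc_nfix, outfile("folds_nfix.tsv"))
    write_tsv_dot(fc_shock, outfile("folds_shock.tsv"))
  }

  # -- regulon -------------------------------------------------------
  regulon <- infer_regulon(setNames(fc_nfix$label, fc_nfix$locus_id),
                           setNames(fc_shock$label, fc_shock$locus_id))
  members <- regulon_members(regulon)
  stage_log("regulon", sprintf("%d members", length(members)))
  if (!is.null(out_dir)) write_regulon(regulon, outfile("regulon.tsv"))

  # -- ortholog core subset ------------------------------------------
  core <- NULL
  if (!is.null(inputs$orthologs)) {
    orth <- read_ortholog_table(inputs$orthologs)
    required <- inputs$required_references
    if (is.null(required)) required <- setdiff(names(orth), "locus_id")
    core <- core_subset(members, orth, required)
    stage_log("core_subset", sprintf("%d of %d members retained in {%s}",
                                     length(core), length(members),
                                     paste(required, collapse = ", ")))
  } else stage_log("core_subset", "skipped (no ortholog table)")

  # -- core-genome overlap -------------------------------------------
  core_genome <- NULL
  if (!is.null(inputs$core_genome)) {
    ids <- read_locus_list(inputs$core_genome)
    core_genome <- core_genome_overlap(members, ids)
    stage_log("core_genome", sprintf("%d members in the core genome",
                                     length(core_genome)))
  } else stage_log("core_genome", "skipped (no core-genome list)")

  # -- promoter scan / operons / islands -----------------------------
  annotation <- NULL; promoters <- NULL; operons <- NULL; islands <- NULL
  if (!is.null(inputs$gff3) && !is.null(inputs$fasta)) {
    loaded <- read_annotations(inputs$gff3, inputs$fasta)
    annotation <- loaded$annotation
    scfg <- scan_config_from(config$scan)
    scanned <- annotate_promoters(annotation, loaded$sequence, scfg)
    promoters <- scanned$flags
    n_yy <- sum(promoters$nifa_flag == "Yes" & promoters$rpon_flag == "Yes")
    stage_log("scan", sprintf("%d genes scanned; %d NifA/RpoN Yes/Yes",
                              nrow(promoters), n_yy))
    ocfg <- operon_config(
      max_intergenic_gap = config$operon$max_intergenic_gap %||% 200,
      require_same_strand = config$operon$require_same_strand %||% TRUE)
    operons <- predict_operons(annotation, promoters, ocfg)
    stage_log("operons", sprintf("%d operons covering %d genes",
                                 nrow(operons), sum(operons$n_genes)))
    icfg <- island_config(
      min_genes = config$island_detection$min_genes %||% 5,
      max_gap_genes = config$island_detection$max_gap_genes %||% 4)
    islands <- detect_islands(annotation,
                              setNames(regulon$member, regulon$locus_id),
                              icfg)
    stage_log("islands", sprintf("%d island(s)", nrow(islands)))
    if (!is.null(out_dir)) {
      write_tsv_dot(promoters, outfile("promoters.tsv"))
      write_motif_hits_bed(scanned$hits, annotation,
                           outfile("motif_hits.bed"))
      write_operons_gff3(operons, annotation, outfile("operons.gff3"))
      write_islands_bed(islands, annotation, outfile("islands.bed"))
      write_tsv_dot(islands[, setdiff(names(islands), "members")],
                    outfile("islands.tsv"))
      write_tsv_dot(operons[, setdiff(names(operons), "members")],
                    outfile("operons.tsv"))
    }
  } else stage_log("scan", "skipped (no genome annotation/sequence)")

  # -- island partition ----------------------------------------------
  island_range <- config$island
  if (is.null(island_range) && !is.null(islands) && nrow(islands)) {
    biggest <- which.max(islands$gene_count)
    island_range <- c(islands$first_locus[biggest],
                      islands$last_locus[biggest])
  }
  if (!is.null(island_range)) {
    part <- island_partition(members, unlist(island_range), annotation)
  } else {
    part <- list(inside = character(), outside = members)
    stage_log("island_partition", "no island defined; all members outside")
  }

  # -- categories ----------------------------------------------------
  categories <- NULL
  if (!is.null(inputs$category_map)) {
    cmap <- read_category_map(inputs$category_map)
    categories <- categorize_functions(if (is.null(core)) members else core,
                                       cmap)
  } else stage_log("categories", "skipped (no category map)")

  report <- summary_report(
    n_genes = nrow(expr),
    n_up_nfix = sum(fc_nfix$label == "up"),
    n_down_nfix = sum(fc_nfix$label == "down"),
    n_up_shock = sum(fc_shock$label == "up"),
    n_down_shock = sum(fc_shock$label == "down"),
    n_altered_shock = sum(fc_shock$label != "unchanged"),
    n_regulon = length(members),
    n_core_subset = if (is.null(core)) NA_integer_ else length(core),
    n_regulon_in_island = length(part$inside),
    n_regulon_outside = length(part$outside),
    n_core_genome_overlap = if (is.null(core_genome)) NA_integer_ else
      length(core_genome),
    n_yesyes_promoters = if (is.null(promoters)) NA_integer_ else
      sum(promoters$nifa_flag == "Yes" & promoters$rpon_flag == "Yes"),
    n_operons = if (is.null(operons)) NA_integer_ else nrow(operons),
    n_operon_genes = if (is.null(operons)) NA_integer_ else
      sum(operons$n_genes),
    islands = if (is.null(islands)) NULL else
      islands[, setdiff(names(islands), "members")],
    categories = categories)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_as_json(report), outfile("report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_tsv_dot(report_as_table(report), outfile("report.tsv"))
  }
  attr(report, "stages") <- list(
    expr = expr, fc_nfix = fc_nfix, fc_shock = fc_shock, regulon = regulon,
    core_subset = core, core_genome = core_genome, annotation = annotation,
    promoters = promoters, operons = operons, islands = islands,
    partition = part)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

modify_defaults <- function(defaults, override) {
  for (k in names(override)) defaults[[k]] <- override[[k]]
  defaults
}

scan_config_from <- function(scan) {
  scan_config(
    upstream_window = scan$upstream_window %||% 400,
    min_uas_distance = scan$min_uas_distance %||% 100,
    uas_pattern = compile_pattern(scan$uas_pattern %||% "TGT-N10-ACA",
                                  scan$uas_mismatches %||% 0,
                                  name = "NifA_UAS"),
    rpon_pattern = compile_pattern(scan$rpon_pattern %||% "TGGCAC-N5-TTGC",
                                   scan$rpon_mismatches %||% 1,
                                   name = "RpoN_promoter"),
    uas_strands = scan$uas_strands %||% "both")
}

stage_log <- function(stage, what) {
  message(sprintf("[%s] %s", stage, what))
}

read_locus_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("locus_id", first, fixed = TRUE)) {
    read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", ""))$locus_id
  } else {
    trimws(readLines(path))
  }
}

write_tsv_dot <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.character(out[[j]]) || is.factor(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), ".", as.character(out[[j]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Assemble (and validate) the pipeline summary report
#'
#' Invariants asserted: island partition sums to the regulon size, and
#' the regulon is contained in the nitrogen-fixation up-set.
#'
#' @param ... Report fields (see [run_pipeline()]).
#' @return List of class `summary_report`.
#' @keywords internal
summary_report <- function(...) {
  rep <- list(...)
  stopifnot(rep$n_regulon_in_island + rep$n_regulon_outside ==
              rep$n_regulon,
            rep$n_regulon <= rep$n_up_nfix)
  structure(rep, class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v) || is.data.frame(v)) next
    cat(sprintf("  %-24s %s\n", k, v))
  }
  if (!is.null(x$islands) && nrow(x$islands)) {
    cat("  islands:\n")
    print(x$islands, row.names = FALSE)
  }
  invisible(x)
}

report_as_json <- function(report) {
  out <- unclass(report)
  out$islands <- if (is.null(out$islands)) NULL else out$islands
  out
}

report_as_table <- function(report) {
  scalars <- Filter(function(v) !is.null(v) && !is.data.frame(v),
                    unclass(report))
  data.frame(key = names(scalars),
             value = vapply(scalars, function(v) as.character(v)[1L],
                            character(1L)),
             stringsAsFactors = FALSE)
}

#' Render a nif-island-style summary table
#'
#' One row per gene with the worked example's column layout: locus, gene
#' name, functional description, ammonium-shock ratio, nitrogen-fixation
#' fold, and the NifA / RpoN consensus flags. Genes absent from the
#' promoter table get blank flags. Re-reading the written file with
#' [read_table1()] reproduces the numeric and flag content.
#'
#' @param folds_shock,folds_nfix Fold tables (`locus_id`, `ratio`) for
#'   the ammonium-shock and nitrogen-fixation contrasts.
#' @param promoters Optional flag table (`locus_id`, `nifa_flag`,
#'   `rpon_flag`).
#' @param annotation Optional [genome_annotation()] supplying gene names
#'   and products.
#' @param path Optional output TSV (missing values written as ".").
#' @return `data.frame` in table order.
#' @export
report_table1_style <- function(folds_shock, folds_nfix, promoters = NULL,
                                annotation = NULL, path = NULL) {
  loci <- folds_nfix$locus_id
  if (!setequal(loci, folds_shock$locus_id))
    stop("fold tables cover different gene sets")
  out <- data.frame(locus_id = loci, gene_name = NA_character_,
                    description = NA_character_,
                    shock_ratio = folds_shock$ratio[
                      match(loci, folds_shock$locus_id)],
                    nfix_fold = folds_nfix$ratio,
                    nifa_flag = NA_character_, rpon_flag = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    idx <- match(loci, annotation$genes$locus_id)
    out$gene_name <- annotation$genes$name[idx]
    out$description <- annotation$genes$product[idx]
  }
  if (!is.null(promoters)) {
    idx <- match(loci, promoters$locus_id)
    out$nifa_flag <- promoters$nifa_flag[idx]
    out$rpon_flag <- promoters$rpon_flag[idx]
  }
  if (!is.null(path)) write_tsv_dot(out, path)
  out
}
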