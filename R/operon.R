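# Operon prediction from promoter flags + gene adjacency, and detection
# of expression islands (maximal runs of co-regulated genes) over the
# gene order.

#' Operon-joining settings
#'
#' @param max_intergenic_gap Largest intergenic distance (bp) across
#'   which an operon extends (default 200, a standard bacterial operon
#'   heuristic).
#' @param require_same_strand Operons never cross a strand switch
#'   (default `TRUE`).
#' @return List of class `operon_config`.
#' @export
operon_config <- function(max_intergenic_gap = 200,
                          require_same_strand = TRUE) {
  stopifnot(max_intergenic_gap >= 0, is.logical(require_same_strand))
  structure(list(max_intergenic_gap = as.integer(max_intergenic_gap),
                 require_same_strand = require_same_strand),
            class = "operon_config")
}

#' Island-detection settings
#'
#' @param min_genes Minimum number of member genes for a reported island
#'   (default 5).
#' @param max_gap_genes Largest run of consecutive non-member genes
#'   tolerated inside an island (default 4; co-regulated islands can
#'   carry a few interior genes that do not pass the regulon filter).
#' @return List of class `island_config`.
#' @export
island_config <- function(min_genes = 5, max_gap_genes = 4) {
  stopifnot(min_genes >= 1, max_gap_genes >= 0)
  structure(list(min_genes = as.integer(min_genes),
                 max_gap_genes = as.integer(max_gap_genes)),
            class = "island_config")
}

#' Predict NifA-sigma54-dependent operons
#'
#' Every gene flagged `Yes` for both the NifA UAS and the sigma-54
#' promoter seeds an operon. The operon extends gene by gene in the
#' direction of transcription while the strand is unchanged (when
#' required), the intergenic gap stays within `max_intergenic_gap`, and
#' the next gene does not itself carry a Yes/Yes promoter (which starts
#' a new operon). Genes with No or blank flags are absorbed as internal
#' members. The number of operons therefore equals the number of Yes/Yes
#' promoters.
#'
#' @param annotation A [genome_annotation()] (genes sorted by start).
#' @param promoters Flag table with columns `locus_id`, `nifa_flag`,
#'   `rpon_flag` covering every gene (see [annotate_promoters()]).
#' @param cfg An [operon_config()].
#' @return `data.frame` with columns `operon_id`, `leader_locus`,
#'   `strand`, `n_genes` and a list-column `members` (loci in
#'   transcription order, leader first), ordered along the genome.
#' @export
predict_operons <- function(annotation, promoters, cfg = operon_config()) {
  g <- annotation$genes
  if (nrow(g) > 1L && is.unsorted(g$start)) stop("annotation unsorted")
  missing_loci <- setdiff(g$locus_id, promoters$locus_id)
  if (length(missing_loci))
    stop("promoter flags missing for ", length(missing_loci), " gene(s)")
  idx <- match(g$locus_id, promoters$locus_id)
  yy <- promoters$nifa_flag[idx] %in% "Yes" &
    promoters$rpon_flag[idx] %in% "Yes"
  n <- nrow(g)
  leaders <- which(yy)
  ops <- vector("list", length(leaders))
  for (k in seq_along(leaders)) {
    i <- leaders[k]
    memb <- i
    if (g$strand[i] == "+") {
      j <- i + 1L
      while (j <= n && !yy[j] &&
             (!cfg$require_same_strand || g$strand[j] == "+") &&
             g$start[j] - g$end[j - 1L] <= cfg$max_intergenic_gap) {
        memb <- c(memb, j)
        j <- j + 1L
      }
    } else {
      j <- i - 1L
      while (j >= 1L && !yy[j] &&
             (!cfg$require_same_strand || g$strand[j] == "-") &&
             g$start[j + 1L] - g$end[j] <= cfg$max_intergenic_gap) {
        memb <- c(memb, j)
        j <- j - 1L
      }
    }
    ops[[k]] <- list(leader = g$locus_id[i], strand = g$strand[i],
                     members = g$locus_id[memb])
  }
  data.frame(
    operon_id = sprintf("operon_%02d", seq_along(ops)),
    leader_locus = vapply(ops, `[[`, character(1L), "leader"),
    strand = vapply(ops, `[[`, character(1L), "strand"),
    n_genes = vapply(ops, function(o) length(o$members), integer(1L)),
    members = I(lapply(ops, `[[`, "members")),
    stringsAsFactors = FALSE)
}

#' Detect expression islands along the gene order
#'
#' Finds maximal runs of member genes (e.g. regulon members), tolerating
#' up to `max_gap_genes` consecutive non-members inside a run. Island
#' boundaries are always member genes. Runs with at least `min_genes`
#' members are reported in genome order.
#'
#' @param annotation A [genome_annotation()].
#' @param member_flags Logical vector of membership, either aligned to
#'   the annotation's gene order or named by locus.
#' @param cfg An [island_config()].
#' @return `data.frame` with columns `island_id`, `first_locus`,
#'   `last_locus`, `gene_count` (member genes), `n_genes_spanned` (all
#'   genes between the bounds inclusive), `span_bp` (`max(end) -
#'   min(start)` over members) and a list-column `members`.
#' @export
detect_islands <- function(annotation, member_flags, cfg = island_config()) {
  g <- annotation$genes
  if (!is.null(names(member_flags))) {
    member_flags <- unname(member_flags[g$locus_id]) %in% TRUE
  } else if (length(member_flags) != nrow(g)) {
    stop("member_flags must align with the annotation's genes")
  }
  idx <- which(member_flags %in% TRUE)
  empty <- data.frame(island_id = character(), first_locus = character(),
                      last_locus = character(), gene_count = integer(),
                      n_genes_spanned = integer(), span_bp = integer(),
                      members = I(list()), stringsAsFactors = FALSE)
  if (length(idx) == 0L) return(empty)
  run_id <- cumsum(c(1L, diff(idx) - 1L > cfg$max_gap_genes))
  runs <- split(idx, run_id)
  runs <- runs[vapply(runs, length, integer(1L)) >= cfg$min_genes]
  if (length(runs) == 0L) return(empty)
  out <- data.frame(
    island_id = sprintf("island_%02d", seq_along(runs)),
    first_locus = vapply(runs, function(r) g$locus_id[r[1L]], character(1L)),
    last_locus = vapply(runs, function(r) g$locus_id[r[length(r)]],
                        character(1L)),
    gene_count = vapply(runs, length, integer(1L)),
    n_genes_spanned = vapply(runs, function(r) r[length(r)] - r[1L] + 1L,
                             integer(1L)),
    span_bp = vapply(runs, function(r)
      max(g$end[r]) - min(g$start[r]), integer(1L)),
    members = I(lapply(runs, function(r) g$locus_id[r])),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genomic span of an island
#'
#' `max(end) - min(start)` in bp over the island's member genes.
#'
#' @param island Either a character vector of member loci or a one-row
#'   slice of the [detect_islands()] table (its `members` entry is
#'   used).
#' @param annotation A [genome_annotation()].
#' @return Span in bp.
#' @export
island_span <- function(island, annotation) {
  members <- if (is.character(island)) island else unlist(island$members)
  idx <- match(members, annotation$genes$locus_id)
  if (anyNA(idx)) stop("unknown locus in island")
  max(annotation$genes$end[idx]) - min(annotation$genes$start[idx])
}

#' Write islands as BED6
#'
#' @param islands [detect_islands()] table.
#' @param annotation The underlying [genome_annotation()].
#' @param path Output path.
#' @export
write_islands_bed <- function(islands, annotation, path) {
  g <- annotation$genes
  starts <- vapply(islands$members, function(m)
    min(g$start[match(m, g$locus_id)]), integer(1L))
  ends <- vapply(islands$members, function(m)
    max(g$end[match(m, g$locus_id)]), integer(1L))
  write_bed(data.frame(chrom = rep(annotation$genome_id, nrow(islands)),
                       start = starts, end = ends, name = islands$island_id,
                       score = islands$gene_count,
                       strand = rep("+", nrow(islands)),
                       stringsAsFactors = FALSE),
            path)
}

#' Write predicted operons as GFF3
#'
#' Emits one `operon` feature per operon with its genes as `gene`
#' children (`Parent` attributes).
#'
#' @param operons [predict_operons()] table.
#' @param annotation The underlying [genome_annotation()].
#' @param path Output path.
#' @export
write_operons_gff3 <- function(operons, annotation, path) {
  g <- annotation$genes
  feats <- list()
  for (k in seq_len(nrow(operons))) {
    memb <- operons$members[[k]]
    idx <- match(memb, g$locus_id)
    feats[[length(feats) + 1L]] <- data.frame(
      start = min(g$start[idx]) + 1L, end = max(g$end[idx]),
      strand = operons$strand[k], type = "operon",
      ID = operons$operon_id[k], Parent = NA_character_,
      stringsAsFactors = FALSE)
    feats[[length(feats) + 1L]] <- data.frame(
      start = g$start[idx] + 1L, end = g$end[idx],
      strand = g$strand[idx], type = "gene", ID = memb,
      Parent = operons$operon_id[k], stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, feats)
  if (is.null(tab)) tab <- data.frame(start = integer(), end = integer(),
                                      strand = character(),
                                      type = character(), ID = character(),
                                      Parent = character())
  gr <- GenomicRanges::GRanges(
    seqnames = rep(annotation$genome_id, nrow(tab)),
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
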