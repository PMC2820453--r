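# Regulon inference by condition intersection and the set operations
# downstream of it: ortholog core subsets, core-genome overlap, island
# partition and functional-category summaries.

#' Infer the nitrogen-fixation-inducible regulon
#'
#' A gene belongs to the regulon iff it is `up` in the nitrogen-fixation
#' vs nitrogen-excess contrast AND `down` in the ammonium-shock (10 min)
#' vs nitrogen-fixation contrast — induced while fixing nitrogen and
#' rapidly repressed by ammonium.
#'
#' @param labels_nfix,labels_shock Character vectors of labels
#'   (`"up"/"down"/"unchanged"`) named by locus; both must cover the same
#'   gene universe.
#' @return `data.frame` with columns `locus_id`, `up_in_nfix`,
#'   `down_after_shock`, `member` (logical), one row per gene in the
#'   universe, in the order of `labels_nfix`.
#' @export
infer_regulon <- function(labels_nfix, labels_shock) {
  if (length(labels_nfix) == 0L && length(labels_shock) == 0L)
    return(data.frame(locus_id = character(), up_in_nfix = logical(),
                      down_after_shock = logical(), member = logical(),
                      stringsAsFactors = FALSE))
  if (is.null(names(labels_nfix)) || is.null(names(labels_shock)))
    stop("label vectors must be named by locus")
  if (!setequal(names(labels_nfix), names(labels_shock)) ||
      length(labels_nfix) != length(labels_shock))
    stop("label maps cover different gene universes")
  loci <- names(labels_nfix)
  up <- unname(labels_nfix[loci] == "up")
  down <- unname(labels_shock[loci] == "down")
  data.frame(locus_id = loci, up_in_nfix = up, down_after_shock = down,
             member = up & down, stringsAsFactors = FALSE)
}

#' Regulon members
#'
#' @param regulon Output of [infer_regulon()].
#' @return Character vector of member loci.
#' @export
regulon_members <- function(regulon) {
  regulon$locus_id[regulon$member]
}

#' Ortholog-conserved core subset of a regulon
#'
#' Restricts a regulon to the genes with an ortholog in every required
#' reference genome (e.g. the two most closely related diazotrophs).
#' A locus absent from the ortholog table counts as absent everywhere.
#'
#' @param members Character vector of regulon member loci.
#' @param orthologs Presence table from [read_ortholog_table()] /
#'   [generate_orthologs()]: `locus_id` plus one logical column per
#'   reference.
#' @param required Character vector of reference-genome column names that
#'   must all be present; empty means no restriction.
#' @return Character vector, a subset of `members`, in `members` order.
#' @export
core_subset <- function(members, orthologs, required) {
  if (length(required) == 0L) return(members)
  unknown <- setdiff(required, setdiff(names(orthologs), "locus_id"))
  if (length(unknown))
    stop("unknown reference genome(s): ", paste(unknown, collapse = ", "))
  idx <- match(members, orthologs$locus_id)
  keep <- !is.na(idx)
  for (ref in required)
    keep <- keep & orthologs[[ref]][idx] %in% TRUE
  members[keep]
}

#' Overlap of a regulon with a core-genome gene list
#'
#' @param members Character vector of regulon member loci.
#' @param core_genome_ids Character vector of core-genome locus IDs.
#' @return Intersection, in `members` order.
#' @export
core_genome_overlap <- function(members, core_genome_ids) {
  members[members %in% core_genome_ids]
}

#' Partition regulon members into island vs non-island genes
#'
#' The island may be given as a locus-ID range `c(first, last)` (closed;
#' membership follows gene order in `annotation` when supplied, else the
#' lexicographic order of the IDs, which is correct for zero-padded tags
#' like `PST1302`), or as a bp interval `c(start, end)` (0-based
#' half-open; a gene is inside if its body overlaps the interval, which
#' requires `annotation`).
#'
#' @param members Character vector of regulon member loci.
#' @param island Length-2 character (locus range) or numeric (bp
#'   interval) vector.
#' @param annotation Optional [genome_annotation()].
#' @return List with character vectors `inside` and `outside`; the two
#'   partition `members`.
#' @export
island_partition <- function(members, island, annotation = NULL) {
  stopifnot(length(island) == 2L)
  if (is.character(island)) {
    if (!is.null(annotation)) {
      ord <- annotation$genes$locus_id
      i <- match(island, ord)
      if (anyNA(i)) stop("island bounds not in annotation")
      in_island <- members %in% ord[seq(min(i), max(i))]
    } else {
      lo <- min(island); hi <- max(island)
      in_island <- members >= lo & members <= hi
    }
  } else {
    if (is.null(annotation))
      stop("bp-interval islands require an annotation")
    g <- annotation$genes
    idx <- match(members, g$locus_id)
    if (anyNA(idx)) stop("member loci missing from annotation")
    # overlap of [start, end) with the island interval
    in_island <- g$start[idx] < max(island) & g$end[idx] > min(island)
  }
  list(inside = members[in_island], outside = members[!in_island])
}

#' Functional-category summary of a gene set
#'
#' @param gene_set Character vector of loci.
#' @param category_map Named character vector (names = loci); unmapped
#'   genes fall into `"unknown"`.
#' @return `data.frame` with columns `category`, `n`, `proportion`
#'   (proportions sum to 1; zero rows for an empty set), sorted by
#'   decreasing count.
#' @export
categorize_functions <- function(gene_set, category_map) {
  if (length(gene_set) == 0L)
    return(data.frame(category = character(), n = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  cats <- unname(category_map[gene_set])
  cats[is.na(cats)] <- "unknown"
  tab <- sort(table(cats), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             proportion = as.integer(tab) / length(gene_set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write regulon calls as TSV
#'
#' @param regulon Output of [infer_regulon()].
#' @param path Output path.
#' @export
write_regulon <- function(regulon, path) {
  write.table(regulon, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
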