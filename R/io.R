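# Readers/writers for the external formats used by the pipeline, and the
# single home for the coordinate convention: internally genes live on a
# 0-based half-open interval [start, end); GFF3 is 1-based inclusive and
# is converted exactly at this boundary.

#' Construct a genome annotation
#'
#' Container for an annotated bacterial genome (or replicon): an ordered
#' gene table plus the sequence length. Gene coordinates are 0-based
#' half-open; genes are stored sorted by `start`.
#'
#' @param genome_id Single string naming the replicon.
#' @param genes `data.frame` with columns `locus_id`, `name`, `start`,
#'   `end`, `strand`, `product`, `category`. `name`, `product` and
#'   `category` may be `NA`. Coordinates 0-based half-open.
#' @param sequence_length Length of the underlying sequence in bp.
#' @param circular Is the replicon circular? Affects upstream-region
#'   extraction only.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id`, `genes` (sorted by `start`), `sequence_length`,
#'   `circular`.
#' @examples
#' g <- data.frame(locus_id = "g1", name = NA, start = 0L, end = 300L,
#'                 strand = "+", product = NA, category = NA)
#' genome_annotation("chr", g, 1000L)
#' @export
genome_annotation <- function(genome_id, genes, sequence_length,
                              circular = FALSE) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.data.frame(genes), length(sequence_length) == 1L,
            is.logical(circular), length(circular) == 1L)
  needed <- c("locus_id", "name", "start", "end", "strand", "product",
              "category")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols))
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "))
  genes <- genes[, needed, drop = FALSE]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (anyDuplicated(genes$locus_id))
      stop("duplicate locus_id in annotation")
    if (any(genes$start < 0L) || any(genes$end <= genes$start))
      stop("gene coordinates must satisfy 0 <= start < end")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (any(genes$end > sequence_length))
      stop("gene end beyond sequence length")
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  }
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, genes = genes,
                 sequence_length = as.integer(sequence_length),
                 circular = circular),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d genes, %s bp%s\n",
              x$genome_id, nrow(x$genes),
              format(x$sequence_length, big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read a genome annotation from GFF3 + FASTA
#'
#' Reads gene features (`type` gene, or CDS where no gene features are
#' present) carrying a `locus_tag` attribute, converts GFF3 1-based
#' inclusive coordinates to the internal 0-based half-open convention,
#' and bounds-checks every feature against the FASTA sequence.
#'
#' @param path GFF3 file.
#' @param fasta_path FASTA file with the single genome sequence.
#' @param circular Treat the replicon as circular (default linear).
#' @return A list with elements `annotation` (a [genome_annotation()])
#'   and `sequence` (uppercase DNA string).
#' @export
read_annotations <- function(path, fasta_path, circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("expected exactly one sequence in ", fasta_path)
  genome_id <- sub("\\s.*$", "", names(seqs)[1L])
  seq_len <- Biostrings::width(seqs)[1L]
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr)) {
    keep <- as.character(gr$type) %in% "gene"
    if (!any(keep)) keep <- as.character(gr$type) %in% "CDS"
    gr <- gr[keep]
  }
  if (length(gr)) {
    if (is.null(gr$locus_tag) || anyNA(gr$locus_tag))
      stop("every gene feature needs a locus_tag attribute")
    if (anyDuplicated(gr$locus_tag))
      stop("duplicate locus_tag in ", path)
    if (any(GenomicRanges::end(gr) > seq_len))
      stop("feature beyond sequence end in ", path)
    grab <- function(field) {
      v <- S4Vectors::mcols(gr)[[field]]
      if (is.null(v)) rep(NA_character_, length(gr)) else as.character(v)
    }
    genes <- data.frame(
      locus_id = as.character(gr$locus_tag),
      name = grab("gene"),
      start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      product = grab("product"),
      category = grab("category"),
      stringsAsFactors = FALSE)
  } else {
    genes <- empty_gene_table()
  }
  ann <- genome_annotation(genome_id, genes, seq_len, circular = circular)
  list(annotation = ann,
       sequence = toupper(as.character(seqs[[1L]])))
}

empty_gene_table <- function() {
  data.frame(locus_id = character(), name = character(), start = integer(),
             end = integer(), strand = character(), product = character(),
             category = character(), stringsAsFactors = FALSE)
}

#' Write a genome annotation to GFF3 (and optionally FASTA)
#'
#' Inverse of [read_annotations()]: emits one `gene` feature per row with
#' `locus_tag`, `gene`, `product` and `category` attributes, converting
#' back to GFF3 1-based inclusive coordinates.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output GFF3 path.
#' @param sequence Optional DNA string; when given with `fasta_path`, the
#'   sequence is written as FASTA under the annotation's `genome_id`.
#' @param fasta_path Optional FASTA output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path, sequence = NULL,
                              fasta_path = NULL) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$genome_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- rep("gene", nrow(g))
  gr$ID <- g$locus_id
  gr$locus_tag <- g$locus_id
  gr$gene <- g$name
  gr$product <- g$product
  gr$category <- g$category
  rtracklayer::export(gr, path, format = "gff3")
  if (!is.null(sequence) && !is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(sequence)
    names(ss) <- annotation$genome_id
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(path)
}

#' Write intervals as 6-column BED
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  needed <- c("chrom", "start", "end", "name", "score", "strand")
  missing_cols <- setdiff(needed, names(intervals))
  if (length(missing_cols))
    stop("intervals table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (any(intervals$start >= intervals$end))
    stop("BED intervals must satisfy start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = intervals$strand)
  gr$name <- as.character(intervals$name)
  gr$score <- as.numeric(intervals$score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read the nif-island worked-example table
#'
#' Parses the transcriptional summary of the A1501 nitrogen-fixation
#' island (one row per island gene): linear expression ratios for the
#' ammonium-shock and nitrogen-fixation contrasts plus the printed
#' NifA-UAS and RpoN (sigma-54) consensus flags. Blank consensus cells
#' are a distinct third state ("not evaluated / operon-internal"), kept
#' as `NA`, never coerced to `"No"`.
#'
#' @param path TSV with columns `locus_id`, `gene_name`, `shock_ratio`,
#'   `nfix_fold`, `nifa_flag`, `rpon_flag` ("." or empty = missing).
#'   Extra columns (e.g. a functional description) are ignored.
#' @return `data.frame` with those six columns; flags are `"Yes"`,
#'   `"No"` or `NA`.
#' @seealso [nif_island_table1()] for the packaged fixture.
#' @export
read_table1 <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c(".", "", "NA"))
  needed <- c("locus_id", "gene_name", "shock_ratio", "nfix_fold",
              "nifa_flag", "rpon_flag")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("table lacks columns: ", paste(missing_cols, collapse = ", "))
  tab <- tab[, needed, drop = FALSE]
  tab$shock_ratio <- as.numeric(tab$shock_ratio)
  tab$nfix_fold <- as.numeric(tab$nfix_fold)
  if (anyNA(tab$shock_ratio) || anyNA(tab$nfix_fold) ||
      any(tab$shock_ratio <= 0) || any(tab$nfix_fold <= 0))
    stop("expression ratios must be positive")
  for (fl in c("nifa_flag", "rpon_flag")) {
    bad <- !(tab[[fl]] %in% c("Yes", "No") | is.na(tab[[fl]]))
    if (any(bad))
      stop("consensus flags must be Yes, No or blank; got: ",
           paste(unique(tab[[fl]][bad]), collapse = ", "))
  }
  tab
}

#' Packaged A1501 nif-island worked example
#'
#' The 58-gene PST1302..PST1359 island summary shipped with the package.
#' @return See [read_table1()].
#' @export
nif_island_table1 <- function() {
  read_table1(system.file("extdata", "table1_nif_island.tsv",
                          package = "nifregulon", mustWork = TRUE))
}

#' Packaged Pseudomonas core-genome membership of the regulon
#'
#' The printed list of nitrogen-fixation-inducible genes that belong to
#' the Pseudomonas core genome (24 loci, mostly ntr/gln nitrogen
#' regulation genes).
#' @return Character vector of locus IDs.
#' @export
pseudomonas_core_regulon <- function() {
  tab <- read.delim(system.file("extdata", "table3_core_genome.tsv",
                                package = "nifregulon", mustWork = TRUE),
                    stringsAsFactors = FALSE, na.strings = c(".", ""))
  tab$locus_id
}

#' Read / write a per-gene expression matrix
#'
#' TSV dialect: a `locus_id` column plus one positive numeric column per
#' condition (canonically `nfix`, `nexcess`, `shock10`).
#'
#' @param path TSV path.
#' @return Numeric matrix, rows named by locus, columns by condition.
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"locus_id" %in% names(tab)) stop("expected a locus_id column")
  if (anyDuplicated(tab$locus_id)) stop("duplicate locus_id")
  m <- as.matrix(tab[, setdiff(names(tab), "locus_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab$locus_id
  if (ncol(m) && nrow(m) && (anyNA(m) || any(m <= 0)))
    stop("intensities must be positive and complete")
  m
}

#' @rdname read_expression
#' @param matrix Numeric matrix as returned by [read_expression()].
#' @export
write_expression <- function(matrix, path) {
  out <- data.frame(locus_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an ortholog presence table
#'
#' TSV with a `locus_id` column and one logical (`TRUE`/`FALSE`) column
#' per reference genome. A locus absent from the table counts as absent
#' from every reference.
#'
#' @param path TSV path.
#' @return `data.frame` with `locus_id` plus logical reference columns.
#' @export
read_ortholog_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"locus_id" %in% names(tab)) stop("expected a locus_id column")
  for (ref in setdiff(names(tab), "locus_id"))
    tab[[ref]] <- as.logical(tab[[ref]])
  tab
}

#' @rdname read_ortholog_table
#' @param orthologs Table as returned by [read_ortholog_table()].
#' @export
write_ortholog_table <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a functional category map
#'
#' @param path TSV with columns `locus_id`, `category`.
#' @return Named character vector: categories named by locus.
#' @export
read_category_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "category") %in% names(tab)))
  setNames(tab$category, tab$locus_id)
}
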