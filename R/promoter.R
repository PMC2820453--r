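# Gapped IUPAC motif compilation and scanning for the NifA upstream
# activator sequence (UAS, TGT-N10-ACA) and the sigma-54 (RpoN) -24/-12
# promoter element, plus the per-gene Yes/No promoter annotation with the
# >= 100 bp UAS spacing rule.
#
# Matching semantics: pattern letters are IUPAC sets; "Nk" tokens are
# fixed-length gaps that match anything and never count as mismatches;
# an N in the *subject* sequence matches nothing (always a mismatch at a
# non-gap position).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Map bytes A,C,G,T -> 1..4, anything else (incl. N) -> 5.
.dna_code <- local({
  tab <- rep(5L, 256L)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("T")] <- 4L
  tab
})

dna_ints <- function(seq) .dna_code[utf8ToInt(seq)]

revcomp_dna <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Compile a gapped IUPAC motif pattern
#'
#' Pattern strings are dash-separated blocks; a block is either an IUPAC
#' string (e.g. `"TGT"`) or a gap token `"Nk"` (k wildcard positions,
#' e.g. `"N10"`). Gap positions match any base — including an `N` in the
#' subject — and never count as mismatches; at every other position a
#' subject base outside the IUPAC set (or a subject `N`) counts as one
#' mismatch.
#'
#' @param spec Pattern string such as `"TGT-N10-ACA"`.
#' @param max_mismatches Mismatch budget for hits (default 0).
#' @param name Pattern name (defaults to `spec`).
#' @return Object of class `motif_pattern`: list with `name`, `spec`,
#'   `blocks`, `total_length`, `max_mismatches`, `is_gap` (logical per
#'   position) and `allowed` (per-position lists of permitted bases;
#'   `NULL` at gaps).
#' @examples
#' compile_pattern("TGT-N10-ACA")           # NifA UAS, 16 bp
#' compile_pattern("TGGCAC-N5-TTGC", 1)     # sigma-54 -24/-12 element
#' @export
compile_pattern <- function(spec, max_mismatches = 0, name = spec) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec),
            is.numeric(max_mismatches), max_mismatches >= 0)
  blocks <- strsplit(toupper(spec), "-", fixed = TRUE)[[1L]]
  allowed <- list()
  is_gap <- logical()
  for (b in blocks) {
    if (grepl("^N[0-9]+$", b)) {
      k <- as.integer(sub("^N", "", b))
      if (k < 1L) stop("malformed gap token: ", b)
      allowed <- c(allowed, rep(list(NULL), k))
      is_gap <- c(is_gap, rep(TRUE, k))
    } else if (grepl("^[ACGTRYSWKMBDHVN]+$", b)) {
      chars <- strsplit(b, "", fixed = TRUE)[[1L]]
      allowed <- c(allowed, IUPAC_SETS[chars])
      is_gap <- c(is_gap, rep(FALSE, length(chars)))
    } else {
      stop("malformed pattern token: ", b)
    }
  }
  m <- length(allowed)
  # 5 x m lookup: ok[code, j] says whether base code is a match at j
  ok <- matrix(FALSE, nrow = 5L, ncol = m)
  for (j in seq_len(m)) {
    if (is_gap[j]) {
      ok[, j] <- TRUE
    } else {
      ok[match(allowed[[j]], c("A", "C", "G", "T")), j] <- TRUE
    }
  }
  structure(list(name = name, spec = spec, blocks = blocks,
                 total_length = m, max_mismatches = as.integer(max_mismatches),
                 is_gap = is_gap, allowed = allowed, ok = ok),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (%d bp, <= %d mismatches)\n",
              x$spec, x$total_length, x$max_mismatches))
  invisible(x)
}

# Mismatch count for every window of `codes` (integer-coded sequence);
# returns a vector of length length(codes) - m + 1.
window_mismatches <- function(codes, pattern) {
  n_win <- length(codes) - pattern$total_length + 1L
  if (n_win < 1L) return(integer())
  mism <- integer(n_win)
  for (j in which(!pattern$is_gap)) {
    okj <- pattern$ok[, j]
    mism <- mism + !okj[codes[j:(j + n_win - 1L)]]
  }
  mism
}

#' Scan a sequence for a motif pattern
#'
#' Reports every window whose mismatch count is within the pattern's
#' budget. Minus-strand hits are found on the reverse complement but
#' reported with their position on the given sequence.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @param pattern A [compile_pattern()] object.
#' @param strands `"+"`, `"-"`, or both (default).
#' @return `data.frame` with columns `pattern`, `position` (0-based
#'   offset of the window on `seq`), `strand`, `mismatches`, sorted by
#'   position. A sequence shorter than the pattern yields zero rows.
#' @export
scan_sequence <- function(seq, pattern, strands = c("+", "-")) {
  stopifnot(inherits(pattern, "motif_pattern"),
            all(strands %in% c("+", "-")))
  seq <- toupper(seq)
  m <- pattern$total_length
  res <- list()
  if ("+" %in% strands) {
    mism <- window_mismatches(dna_ints(seq), pattern)
    hit <- which(mism <= pattern$max_mismatches)
    if (length(hit))
      res[["+"]] <- data.frame(pattern = pattern$name,
                               position = hit - 1L, strand = "+",
                               mismatches = mism[hit],
                               stringsAsFactors = FALSE)
  }
  if ("-" %in% strands && nchar(seq) >= m) {
    mism <- window_mismatches(dna_ints(revcomp_dna(seq)), pattern)
    hit <- which(mism <= pattern$max_mismatches)
    if (length(hit))
      res[["-"]] <- data.frame(pattern = pattern$name,
                               position = nchar(seq) - m - (hit - 1L),
                               strand = "-",
                               mismatches = mism[hit],
                               stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pattern = character(), position = integer(),
               strand = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter-scan settings
#'
#' @param upstream_window Length of the upstream region scanned per gene,
#'   in bp (default 400); must exceed `min_uas_distance` plus the UAS
#'   length so the spacing rule can ever be satisfied.
#' @param min_uas_distance Minimum distance from the UAS 3' edge to the
#'   gene start for a NifA call, in bp (default 100).
#' @param uas_pattern NifA UAS pattern (default `TGT-N10-ACA`, exact).
#' @param rpon_pattern sigma-54 -24/-12 pattern (default
#'   `TGGCAC-N5-TTGC`, up to 1 mismatch).
#' @param uas_strands Strands scanned for the UAS: `"both"` (default;
#'   enhancer-like elements act orientation-independently) or
#'   `"coding"`.
#' @param rpon_strands Strands for the promoter element; coding only.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(upstream_window = 400,
                        min_uas_distance = 100,
                        uas_pattern = compile_pattern("TGT-N10-ACA", 0,
                                                      name = "NifA_UAS"),
                        rpon_pattern = compile_pattern("TGGCAC-N5-TTGC", 1,
                                                       name = "RpoN_promoter"),
                        uas_strands = c("both", "coding"),
                        rpon_strands = "coding") {
  uas_strands <- match.arg(uas_strands)
  rpon_strands <- match.arg(rpon_strands)
  if (upstream_window <= min_uas_distance + uas_pattern$total_length)
    stop("upstream_window must exceed min_uas_distance + UAS length")
  structure(list(upstream_window = as.integer(upstream_window),
                 min_uas_distance = as.integer(min_uas_distance),
                 uas_pattern = uas_pattern, rpon_pattern = rpon_pattern,
                 uas_strands = uas_strands, rpon_strands = rpon_strands),
            class = "scan_config")
}

#' Extract the upstream region of a gene
#'
#' For a plus-strand gene, the `window` bp ending at the gene start; for
#' a minus-strand gene, the reverse complement of the `window` bp
#' starting at the gene end. Either way the returned sequence reads
#' 5'->3' toward the gene, its last base abutting the gene start.
#' Truncated at contig edges unless the genome is circular, in which
#' case it wraps across the origin.
#'
#' @param gene One-row `data.frame` (or list) with `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param genome_seq Genome DNA string.
#' @param window Window length in bp (> 0).
#' @param circular Wrap around the origin?
#' @return List: `seq` (the upstream sequence), `genome_start`,
#'   `genome_end` (0-based half-open footprint on the genome; may exceed
#'   the sequence length by wrapping when circular) and `strand`.
#' @export
extract_upstream <- function(gene, genome_seq, window, circular = FALSE) {
  if (!is.numeric(window) || window <= 0) stop("window must be positive")
  window <- as.integer(window)
  len <- nchar(genome_seq)
  if (gene$start < 0L || gene$end > len) stop("gene outside genome")
  if (gene$strand == "+") {
    from <- gene$start - window
    to <- gene$start                    # [from, to) 0-based
    if (!circular) from <- max(0L, from)
  } else {
    from <- gene$end
    to <- gene$end + window
    if (!circular) to <- min(len, to)
  }
  seq <- if (to <= from) "" else substr_wrapped(genome_seq, from, to, len)
  if (gene$strand == "-" && nzchar(seq)) seq <- revcomp_dna(seq)
  list(seq = seq, genome_start = from, genome_end = to,
       strand = gene$strand)
}

# substring of [from, to) 0-based, wrapping modulo len (from may be
# negative, to may exceed len; the span is at most len)
substr_wrapped <- function(seq, from, to, len) {
  if (from >= 0L && to <= len) return(substr(seq, from + 1L, to))
  lo <- ((from %% len) + len) %% len
  hi <- ((to - 1L) %% len + len) %% len + 1L   # wrapped end, 1-based
  paste0(substr(seq, lo + 1L, len), substr(seq, 1L, hi))
}

#' Annotate the promoter region of one gene
#'
#' Scans an upstream region (from [extract_upstream()] with the
#' config's window) for the NifA UAS and the sigma-54 element. The NifA
#' flag is `"Yes"` iff some UAS hit ends at least `min_uas_distance` bp
#' before the gene start; the RpoN flag is `"Yes"` iff any promoter
#' element hit exists on the coding strand.
#'
#' @param gene One-row gene record (needs `locus_id`, `strand`).
#' @param upstream_seq The upstream sequence (already oriented 5'->3'
#'   toward the gene).
#' @param cfg A [scan_config()].
#' @return List of class `promoter_annotation`: `locus_id`, `uas_hits`
#'   and `rpon_hits` (hit tables with a `distance_to_start` column, bp
#'   from the motif 3' edge to the gene start), `nifa_flag`,
#'   `rpon_flag`.
#' @export
annotate_promoter <- function(gene, upstream_seq, cfg = scan_config()) {
  uas_strands <- if (cfg$uas_strands == "both") c("+", "-") else "+"
  uas <- scan_sequence(upstream_seq, cfg$uas_pattern, strands = uas_strands)
  uas$distance_to_start <- nchar(upstream_seq) -
    (uas$position + cfg$uas_pattern$total_length)
  rpon <- scan_sequence(upstream_seq, cfg$rpon_pattern, strands = "+")
  rpon$distance_to_start <- nchar(upstream_seq) -
    (rpon$position + cfg$rpon_pattern$total_length)
  structure(list(
    locus_id = gene$locus_id,
    uas_hits = uas, rpon_hits = rpon,
    nifa_flag = if (any(uas$distance_to_start >= cfg$min_uas_distance))
      "Yes" else "No",
    rpon_flag = if (nrow(rpon)) "Yes" else "No"),
    class = "promoter_annotation")
}

#' Promoter annotation across a genome
#'
#' Runs [extract_upstream()] + [annotate_promoter()] for each gene (or a
#' subset) and maps motif hits back to genome coordinates.
#'
#' @param annotation A [genome_annotation()].
#' @param genome_seq Genome DNA string.
#' @param cfg A [scan_config()].
#' @param loci Optional character vector restricting the scan.
#' @return List with `flags` (`data.frame`: `locus_id`, `nifa_flag`,
#'   `rpon_flag`, `n_uas_hits`, `n_rpon_hits`, `best_uas_distance`) and
#'   `hits` (`data.frame` of all motif hits in genome coordinates:
#'   `locus_id`, `pattern`, `genome_start`, `genome_end` 0-based
#'   half-open, `strand` on the genome, `mismatches`,
#'   `distance_to_start`).
#' @export
annotate_promoters <- function(annotation, genome_seq, cfg = scan_config(),
                               loci = NULL) {
  g <- annotation$genes
  if (!is.null(loci)) g <- g[g$locus_id %in% loci, , drop = FALSE]
  n <- nrow(g)
  flags <- data.frame(locus_id = g$locus_id,
                      nifa_flag = character(n), rpon_flag = character(n),
                      n_uas_hits = integer(n), n_rpon_hits = integer(n),
                      best_uas_distance = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
  hits <- vector("list", n)
  len <- annotation$sequence_length
  for (i in seq_len(n)) {
    gene <- g[i, ]
    up <- extract_upstream(gene, genome_seq, cfg$upstream_window,
                           circular = annotation$circular)
    ann <- annotate_promoter(gene, up$seq, cfg)
    flags$nifa_flag[i] <- ann$nifa_flag
    flags$rpon_flag[i] <- ann$rpon_flag
    flags$n_uas_hits[i] <- nrow(ann$uas_hits)
    flags$n_rpon_hits[i] <- nrow(ann$rpon_hits)
    ok_dist <- ann$uas_hits$distance_to_start[
      ann$uas_hits$distance_to_start >= cfg$min_uas_distance]
    if (length(ok_dist)) flags$best_uas_distance[i] <- max(ok_dist)
    ua <- ann$uas_hits
    ua$motif_len <- rep(cfg$uas_pattern$total_length, nrow(ua))
    rp <- ann$rpon_hits
    rp$motif_len <- rep(cfg$rpon_pattern$total_length, nrow(rp))
    both <- rbind(ua, rp)
    if (nrow(both)) {
      hits[[i]] <- data.frame(
        locus_id = gene$locus_id,
        pattern = both$pattern,
        genome_start = upstream_to_genome(both$position, both$motif_len,
                                          up, len),
        strand = genome_hit_strand(both$strand, gene$strand),
        mismatches = both$mismatches,
        distance_to_start = both$distance_to_start,
        stringsAsFactors = FALSE)
      hits[[i]]$genome_end <- hits[[i]]$genome_start + both$motif_len
    }
  }
  hits <- do.call(rbind, c(hits[!vapply(hits, is.null, logical(1L))],
                           list(data.frame(
    locus_id = character(), pattern = character(), genome_start = integer(),
    strand = character(), mismatches = integer(),
    distance_to_start = integer(), genome_end = integer(),
    stringsAsFactors = FALSE))))
  rownames(hits) <- NULL
  list(flags = flags,
       hits = hits[, c("locus_id", "pattern", "genome_start", "genome_end",
                       "strand", "mismatches", "distance_to_start")])
}

# genome 0-based start of a hit found at `position` on an upstream
# sequence described by `up` (from extract_upstream); modulo wrap
upstream_to_genome <- function(position, motif_len, up, seq_len) {
  raw <- if (up$strand == "+")
    up$genome_start + position
  else
    up$genome_end - (position + motif_len)
  ((raw %% seq_len) + seq_len) %% seq_len
}

# strand of a hit on the genome given its strand on the oriented
# upstream sequence and the gene's strand
genome_hit_strand <- function(hit_strand, gene_strand) {
  ifelse(hit_strand == "+", gene_strand,
         ifelse(gene_strand == "+", "-", "+"))
}

#' Write motif hits as BED6
#'
#' @param hits Hit table from [annotate_promoters()].
#' @param annotation The [genome_annotation()] scanned.
#' @param path Output path.
#' @export
write_motif_hits_bed <- function(hits, annotation, path) {
  write_bed(data.frame(chrom = rep(annotation$genome_id, nrow(hits)),
                       start = hits$genome_start, end = hits$genome_end,
                       name = paste0(hits$pattern, "@", hits$locus_id),
                       score = hits$mismatches, strand = hits$strand,
                       stringsAsFactors = FALSE),
            path)
}
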