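# Independent brute-force oracles. These deliberately share no code with
# the package: their own IUPAC table, their own gap parsing, plain loops,
# and Biostrings for reverse complements.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# spec string -> list of per-position allowed characters (NULL = gap)
oracle_compile <- function(spec) {
  out <- list()
  for (tok in strsplit(spec, "-", fixed = TRUE)[[1L]]) {
    if (grepl("^N[0-9]+$", tok)) {
      out <- c(out, rep(list(NULL), as.integer(sub("N", "", tok))))
    } else {
      for (ch in strsplit(tok, "")[[1L]])
        out <- c(out, list(oracle_iupac[[ch]]))
    }
  }
  out
}

# every window of one strand, plain double loop over windows x positions
oracle_scan_strand <- function(chars, allowed, max_mm) {
  m <- length(allowed)
  hits <- list()
  if (length(chars) < m) return(hits)
  for (p in 0:(length(chars) - m)) {
    mm <- 0L
    for (j in seq_len(m)) {
      a <- allowed[[j]]
      if (!is.null(a) && !(chars[p + j] %in% a)) mm <- mm + 1L
    }
    if (mm <= max_mm) hits[[length(hits) + 1L]] <- c(pos = p, mm = mm)
  }
  hits
}

oracle_scan <- function(seq, spec, max_mm, strands = c("+", "-")) {
  allowed <- oracle_compile(spec)
  m <- length(allowed)
  rows <- list()
  if ("+" %in% strands) {
    for (h in oracle_scan_strand(strsplit(seq, "")[[1L]], allowed, max_mm))
      rows[[length(rows) + 1L]] <-
        data.frame(position = unname(h["pos"]), strand = "+",
                   mismatches = unname(h["mm"]))
  }
  if ("-" %in% strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (h in oracle_scan_strand(strsplit(rc, "")[[1L]], allowed, max_mm))
      rows[[length(rows) + 1L]] <-
        data.frame(position = nchar(seq) - m - unname(h["pos"]),
                   strand = "-", mismatches = unname(h["mm"]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), strand = character(),
               mismatches = integer())
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal runs of TRUE tolerating <= max_gap interior FALSEs, >= min_genes
# members; returns list of integer index vectors (members only)
oracle_runs <- function(flags, min_genes, max_gap) {
  idx <- which(flags)
  runs <- list()
  cur <- integer()
  for (i in idx) {
    if (length(cur) == 0L || i - cur[length(cur)] - 1L <= max_gap) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- i
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  Filter(function(r) length(r) >= min_genes, runs)
}

random_seq <- function(len, with_n = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alph, len, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else NULL),
        collapse = "")
}
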