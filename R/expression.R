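# Fold-change computation and threshold classification. All ratios are
# linear scale (the dialect of the island worked example); log2 only ever
# appears in reporting, never internally.

#' Differential-expression classification settings
#'
#' @param up_cut Linear fold at or above which a gene is called `up`
#'   (default 2, the classic two-fold rule).
#' @param down_cut Linear fold at or below which a gene is called `down`
#'   (default `1 / up_cut`). Both boundaries are inclusive.
#' @param pseudocount Added to numerator and denominator intensities
#'   before forming ratios (default 0).
#' @return List of class `de_config`.
#' @export
de_config <- function(up_cut = 2, down_cut = 1 / up_cut, pseudocount = 0) {
  stopifnot(is.numeric(up_cut), is.numeric(down_cut),
            is.numeric(pseudocount), pseudocount >= 0)
  if (!(down_cut < 1 && 1 < up_cut))
    stop("need down_cut < 1 < up_cut")
  structure(list(up_cut = up_cut, down_cut = down_cut,
                 pseudocount = pseudocount),
            class = "de_config")
}

#' Per-gene fold changes between two conditions
#'
#' Forms the linear ratio `(numerator + pseudocount) /
#' (denominator + pseudocount)` per gene from an intensity matrix.
#'
#' @param matrix Positive intensity matrix, rows = loci, columns =
#'   conditions (see [read_expression()]).
#' @param numerator,denominator Condition (column) names.
#' @param pseudocount See [de_config()].
#' @return `data.frame` with columns `locus_id`, `ratio`; attribute
#'   `contrast` records `c(numerator, denominator)`.
#' @examples
#' m <- matrix(c(50, 10, 25, 10), 2, dimnames = list(c("a", "b"),
#'             c("nfix", "nexcess")))
#' compute_fold_changes(m, "nfix", "nexcess")
#' @export
compute_fold_changes <- function(matrix, numerator, denominator,
                                 pseudocount = 0) {
  if (!all(c(numerator, denominator) %in% colnames(matrix)))
    stop("contrast conditions missing from matrix: ",
         paste(setdiff(c(numerator, denominator), colnames(matrix)),
               collapse = ", "))
  num <- matrix[, numerator] + pseudocount
  den <- matrix[, denominator] + pseudocount
  if (any(den == 0))
    stop("zero denominator with pseudocount 0")
  out <- data.frame(locus_id = rownames(matrix), ratio = num / den,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- c(numerator = numerator,
                             denominator = denominator)
  out
}

#' Classify fold changes as up / down / unchanged
#'
#' Inclusive thresholding: `up` iff `fold >= up_cut`, `down` iff
#' `fold <= down_cut`, else `unchanged`.
#'
#' @param fold Positive linear fold change(s); vectorized.
#' @param cfg A [de_config()].
#' @return Character vector in `{"up","down","unchanged"}`, named after
#'   `fold` if it has names.
#' @export
classify_regulation <- function(fold, cfg = de_config()) {
  if (!is.numeric(fold) || anyNA(fold) || any(fold <= 0))
    stop("fold changes must be positive numbers")
  out <- rep("unchanged", length(fold))
  out[fold >= cfg$up_cut] <- "up"
  out[fold <= cfg$down_cut] <- "down"
  names(out) <- names(fold)
  out
}

#' Count up / down / unchanged calls
#'
#' @param labels Character vector from [classify_regulation()].
#' @return Named integer vector `c(up=, down=, unchanged=)`; the three
#'   counts always sum to `length(labels)`.
#' @export
summarize_contrast <- function(labels) {
  bad <- setdiff(unique(labels), c("up", "down", "unchanged"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "))
  c(up = sum(labels == "up"),
    down = sum(labels == "down"),
    unchanged = sum(labels == "unchanged"))
}

#' Fold-change classification of a whole contrast
#'
#' Convenience wrapper: fold changes, labels and an optional external
#' significance mask in one call. The mask exists because array studies
#' often pair the fold threshold with a significance call computed
#' elsewhere; genes with `include_mask` `FALSE` are forced to
#' `unchanged`.
#'
#' @inheritParams compute_fold_changes
#' @param cfg A [de_config()].
#' @param include_mask Optional logical vector named by locus.
#' @return `data.frame`: `locus_id`, `ratio`, `label`.
#' @export
classify_contrast <- function(matrix, numerator, denominator,
                              cfg = de_config(), include_mask = NULL) {
  fc <- compute_fold_changes(matrix, numerator, denominator,
                             pseudocount = cfg$pseudocount)
  fc$label <- classify_regulation(fc$ratio, cfg)
  if (!is.null(include_mask)) {
    drop <- fc$locus_id[!include_mask[fc$locus_id] %in% TRUE]
    fc$label[fc$locus_id %in% drop] <- "unchanged"
  }
  attr(fc, "contrast") <- c(numerator = numerator,
                            denominator = denominator)
  fc
}
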