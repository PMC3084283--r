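#' Collapse identical sequences
#'
#' Merges records with the same sequence, summing counts per library. Total
#' reads are conserved. The id of the most abundant constituent is kept.
#'
#' @param reads a [read_set()].
#' @return collapsed [read_set()].
#' @export
collapse_identical <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  libs <- libraries(reads)
  key <- reads$sequence
  grp <- match(key, unique(key))
  cm <- count_matrix(reads)
  agg <- rowsum(cm, grp, reorder = TRUE)
  tot <- total_counts(reads)
  best <- vapply(split(seq_len(nrow(reads)), grp),
                 function(i) i[which.max(tot[i])], 1L)
  read_set(reads$id[best], unique(key), agg)
}

#' Filtering parameters
#'
#' Defaults encode the library pre-processing rules: drop sequences shorter
#' than 19 nt, any ambiguous base disqualifies, and only sequences with more
#' than 5 reads (i.e. >= 6) in the library under study are retained.
#'
#' @param min_length minimum sequence length in nt.
#' @param min_count minimum total read count (strictly-more-than-5 reads
#'   means `min_count = 6`).
#' @param max_ambiguous maximum number of `N` residues tolerated.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_length = 19, min_count = 6, max_ambiguous = 0) {
  if (min_length < 1 || min_count < 1) fail("min_length and min_count must be >= 1")
  structure(list(min_length = min_length, min_count = min_count,
                 max_ambiguous = max_ambiguous), class = "filter_params")
}

#' Quality / length / abundance filtering
#'
#' Applies, in order: the length floor, the ambiguous-base limit, and the
#' read-count floor (on the total across the read set's libraries; filter
#' libraries separately for per-library thresholds). Input should already be
#' collapsed. The report accounts for every removed read.
#'
#' @param reads collapsed [read_set()].
#' @param params a [filter_params()].
#' @return list with `kept` (read_set) and `report` (data frame of removed
#'   sequence/read counts per criterion).
#' @export
filter_reads <- function(reads, params = filter_params()) {
  tot <- total_counts(reads)
  too_short <- nchar(reads$sequence) < params$min_length
  ambig <- !too_short &
    (nchar(reads$sequence) - nchar(gsub("N", "", reads$sequence, fixed = TRUE))) >
      params$max_ambiguous
  low <- !too_short & !ambig & tot < params$min_count
  keep <- !(too_short | ambig | low)
  report <- data.frame(
    criterion = c("too_short", "ambiguous", "low_count", "kept"),
    sequences = c(sum(too_short), sum(ambig), sum(low), sum(keep)),
    reads = c(sum(tot[too_short]), sum(tot[ambig]), sum(tot[low]),
              sum(tot[keep])))
  kept <- as_read_set(as.data.frame(reads)[keep, , drop = FALSE],
                      libraries(reads))
  list(kept = kept, report = report)
}

#' Read-length distribution of a library
#'
#' Fractions are weighted by read counts, not by unique sequences.
#'
#' @param reads a [read_set()].
#' @param library optional library label; default uses totals across
#'   libraries.
#' @return a `length_histogram` data frame (`length`, `reads`, `fraction`).
#' @export
length_distribution <- function(reads, library = NULL) {
  if (nrow(reads) == 0) fail("length_distribution on empty read set")
  n <- if (is.null(library)) total_counts(reads) else {
    if (!library %in% libraries(reads)) fail("unknown library: %s", library)
    reads[[library]]
  }
  if (sum(n) <= 0) fail("no reads in library")
  len <- nchar(reads$sequence)
  agg <- rowsum(n, len)
  out <- data.frame(length = as.integer(rownames(agg)), reads = agg[, 1])
  out <- out[out$reads > 0, , drop = FALSE]
  out$fraction <- out$reads / sum(out$reads)
  rownames(out) <- NULL
  attr(out, "library") <- library
  class(out) <- c("length_histogram", "data.frame")
  out
}

#' Fraction of reads in a length range
#'
#' Convenience on top of [length_distribution()], e.g. the 21-23-nt miRNA
#' band of a library.
#'
#' @param reads a [read_set()].
#' @param from,to inclusive length bounds in nt.
#' @inheritParams length_distribution
#' @return numeric fraction in [0, 1].
#' @export
length_fraction <- function(reads, from = 21, to = 23, library = NULL) {
  h <- length_distribution(reads, library)
  sum(h$fraction[h$length >= from & h$length <= to])
}

#' Flag reads with U-rich low-complexity 3' tails
#'
#' The 36-nt artefact reads carry a low-complexity 3'-terminal window mainly
#' made of uracil; a read is flagged when the T fraction in its 3'-terminal
#' window reaches `u_fraction` (inclusive). Reads shorter than the window are
#' assessed over their full length and noted.
#'
#' @param reads a [read_set()].
#' @param window 3'-terminal window size in nt.
#' @param u_fraction minimum T (U) fraction in the window.
#' @return data frame (`id`, `flag`, `short`): `flag` marks U-rich tails,
#'   `short` marks reads shorter than the window.
#' @export
flag_low_complexity_tail <- function(reads, window = 10, u_fraction = 0.5) {
  len <- nchar(reads$sequence)
  w <- pmin(window, len)
  tail_seq <- substr(reads$sequence, len - w + 1, len)
  tfrac <- (nchar(tail_seq) - nchar(gsub("T", "", tail_seq, fixed = TRUE))) / w
  data.frame(id = reads$id, flag = tfrac >= u_fraction, short = len < window)
}
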