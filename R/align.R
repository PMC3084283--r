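# Pairwise local alignment with a fixed scoring scheme (match +1, mismatch -1,
# gap -2, linear). N matches nothing, including another N, so masked hairpin
# positions always count as mismatches.

.mirfree_env <- new.env(parent = emptyenv())

sub_matrix <- function() {
  if (is.null(.mirfree_env$submat)) {
    letters <- c(DNA_BASES, "N")
    m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
    diag(m) <- 1
    m["N", "N"] <- -1
    .mirfree_env$submat <- m
  }
  .mirfree_env$submat
}

# Batch local alignment of many patterns against one subject.
# Returns identity (matches / aligned columns), coverage (fraction of the
# shorter sequence covered by the aligned span), span columns, score, and the
# aligned ranges on both sequences (0-based half-open).
align_stats <- function(patterns, subject, type = "local") {
  if (any(!nzchar(patterns)) || !nzchar(subject)) fail("empty sequence in alignment")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), subject, type = type,
    substitutionMatrix = sub_matrix(), gapOpening = 0, gapExtension = 2)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  cols <- nchar(as.character(pat))
  matches <- Biostrings::nmatch(aln)
  pw <- width(pat); sw <- width(sub)
  lp <- nchar(patterns); ls <- nchar(subject)
  # span on the shorter sequence; at equal lengths take the larger span so
  # the measure is symmetric in the two sequences
  span_short <- ifelse(lp < ls, pw, ifelse(lp > ls, sw, pmax(pw, sw)))
  len_short <- pmin(lp, ls)
  data.frame(
    identity = ifelse(cols > 0, matches / cols, 0),
    coverage = span_short / len_short,
    columns = cols,
    score = score(aln),
    a_start = start(pat) - 1L, a_end = end(pat),
    b_start = start(sub) - 1L, b_end = end(sub))
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman-style local alignment under a fixed scoring scheme (match
#' +1, mismatch -1, gap -2). Identity is matches over aligned columns
#' (gap columns included); coverage is the fraction of the *shorter* sequence
#' covered by the aligned span, matching the intent of clustering 5'/3'
#' length variants of one miRNA. `N` never matches, not even another `N`.
#'
#' @param a,b DNA sequences (character scalars).
#' @return a `pair_alignment` list: `identity`, `coverage`, `columns`,
#'   `score`, `span_a`, `span_b` (0-based half-open).
#' @export
align_pair <- function(a, b) {
  a <- as_dna(a); b <- as_dna(b)
  # canonical orientation (shorter, then lexicographically smaller sequence
  # as pattern): the optimal local alignment need not be unique, and a fixed
  # orientation makes identity and coverage exactly symmetric
  swap <- nchar(b) < nchar(a) || (nchar(b) == nchar(a) && b < a)
  st <- if (swap) align_stats(b, a) else align_stats(a, b)
  span_pat <- c(st$a_start, st$a_end); span_sub <- c(st$b_start, st$b_end)
  structure(list(identity = st$identity, coverage = st$coverage,
                 columns = st$columns, score = st$score,
                 span_a = if (swap) span_sub else span_pat,
                 span_b = if (swap) span_pat else span_sub),
            class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("pair_alignment: identity %.3f, coverage %.3f over %d columns (score %g)\n",
              x$identity, x$coverage, x$columns, x$score))
  invisible(x)
}

# Candidate pair pre-filter: pairs of sequences sharing an exact k-mer. At
# identity >= 0.9 with aligned span >= 16 columns, matched runs of >= 8
# columns are guaranteed, so k = 8 loses nothing.
kmer_candidate_pairs <- function(seqs, k = 8) {
  n <- length(seqs)
  if (n < 2) return(matrix(integer(), ncol = 2))
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(s)
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  idx <- rep(seq_len(n), lengths(km))
  groups <- split(idx, unlist(km))
  pairs <- lapply(groups, function(g) {
    g <- unique(g)
    if (length(g) < 2) return(NULL)
    t(combn(sort(g), 2))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(), ncol = 2))
  unique(pairs)
}

# Evaluate identity/coverage for an index-pair matrix, batched by subject.
# Pairs are aligned in the same canonical orientation as align_pair, so the
# result does not depend on index order.
evaluate_pairs <- function(seqs, pairs) {
  if (nrow(pairs) == 0)
    return(data.frame(i = integer(), j = integer(), identity = numeric(),
                      coverage = numeric(), columns = integer()))
  si <- seqs[pairs[, 1]]; sj <- seqs[pairs[, 2]]
  swap <- nchar(sj) < nchar(si) | (nchar(sj) == nchar(si) & sj < si)
  pat <- ifelse(swap, pairs[, 2], pairs[, 1])
  sub <- ifelse(swap, pairs[, 1], pairs[, 2])
  out <- vector("list", 0)
  for (j in unique(sub)) {
    sel <- sub == j
    st <- align_stats(seqs[pat[sel]], seqs[j])
    out[[length(out) + 1]] <- data.frame(i = pairs[sel, 1], j = pairs[sel, 2],
                                         identity = st$identity,
                                         coverage = st$coverage,
                                         columns = st$columns)
  }
  do.call(rbind, out)
}
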