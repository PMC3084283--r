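# Precursor discovery on assembled contigs: mapping candidate sequences,
# the two-distinct-regions screen, folding, and miRNA:miRNA* duplex calling.

#' Read assembled contigs from FASTA
#'
#' Contigs shorter than 40 nt cannot host a miRNA:miRNA* duplex and are
#' skipped with a warning.
#'
#' @param path FASTA path.
#' @param min_len minimum usable contig length.
#' @return data frame `id`, `sequence`.
#' @export
read_contigs <- function(path, min_len = 40) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1)
  seqs <- as_dna(as.character(ss))
  short <- nchar(seqs) < min_len
  if (any(short)) warn("skipping %d contig(s) shorter than %d nt", sum(short),
                       min_len)
  data.frame(id = ids[!short], sequence = seqs[!short],
             stringsAsFactors = FALSE)
}

#' Map candidate sequences onto contigs
#'
#' Default mode reports every exact placement of each candidate on each
#' contig, on both strands (the minus strand matches the candidate's reverse
#' complement). An `min_identity < 1` mode locates the best local alignment
#' per strand instead, for noisy contigs.
#'
#' @param candidates a [candidate_table()] or [read_set()] (needs
#'   `sequence` plus `candidate_id`/`id`).
#' @param contigs data frame `id`, `sequence` (see [read_contigs()]).
#' @param min_identity,min_coverage placement thresholds (defaults: exact,
#'   full-length).
#' @return data frame of hits: `candidate_id`, `contig_id`, `start`, `end`
#'   (0-based half-open on the contig), `strand`, `identity`.
#' @export
map_candidates_to_contigs <- function(candidates, contigs, min_identity = 1.00,
                                      min_coverage = 1.00) {
  ids <- if ("candidate_id" %in% names(candidates)) candidates$candidate_id else candidates$id
  seqs <- candidates$sequence
  hits <- list()
  add <- function(cand, contig, starts, width, strand) {
    starts <- starts[starts > 0]
    if (length(starts))
      hits[[length(hits) + 1]] <<- data.frame(
        candidate_id = cand, contig_id = contig, start = starts - 1L,
        end = starts - 1L + width, strand = strand, identity = 1)
  }
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$sequence[ci]
    for (k in seq_along(seqs)) {
      if (min_identity >= 1) {
        fw <- gregexpr(seqs[k], cseq, fixed = TRUE)[[1]]
        add(ids[k], contigs$id[ci], as.integer(fw), nchar(seqs[k]), "+")
        rv <- gregexpr(revcomp(seqs[k]), cseq, fixed = TRUE)[[1]]
        add(ids[k], contigs$id[ci], as.integer(rv), nchar(seqs[k]), "-")
      } else {
        for (strand in c("+", "-")) {
          qs <- if (strand == "+") seqs[k] else revcomp(seqs[k])
          st <- align_stats(qs, cseq)
          cov <- (st$a_end - st$a_start) / nchar(qs)
          if (st$identity >= min_identity && cov >= min_coverage)
            hits[[length(hits) + 1]] <- data.frame(
              candidate_id = ids[k], contig_id = contigs$id[ci],
              start = st$b_start, end = st$b_end, strand = strand,
              identity = st$identity)
        }
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(candidate_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), identity = numeric()))
  do.call(rbind, hits)
}

#' Screen contigs for precursor potential
#'
#' A contig passes when it carries hits from at least two *distinct*
#' candidate sequences whose intervals do not overlap (strictly: sharing
#' even one position disqualifies the pair).
#'
#' @param hits output of [map_candidates_to_contigs()].
#' @return character vector of passing contig ids.
#' @export
screen_precursor_contigs <- function(hits) {
  pass <- vapply(split(hits, hits$contig_id), function(h) {
    n <- nrow(h)
    if (n < 2) return(FALSE)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (h$candidate_id[a] != h$candidate_id[b] &&
          (h$end[a] <= h$start[b] || h$end[b] <= h$start[a]))
        return(TRUE)
    }
    FALSE
  }, TRUE)
  names(pass)[pass]
}

# fraction of a hit interval (0-based half-open) inside an arm interval
interval_overlap_frac <- function(hit, arm) {
  if (is.null(arm)) return(0)
  ov <- max(0, min(hit[2], arm[2]) - max(hit[1], arm[1]))
  ov / (hit[2] - hit[1])
}

#' Call a miRNA:miRNA* duplex on a folded contig
#'
#' A duplex verdict requires one hit lying at least `min_arm_frac` of its
#' length within the 5' arm and another within the 3' arm (distinct
#' candidates, non-overlapping), with at least `min_pairing` of each hit's
#' positions base-paired to positions of the other hit's interval.
#'
#' @param fold a [fold_hairpin()] result for the contig (or folded window).
#' @param hits hits on that contig, coordinates matching `fold`.
#' @param min_arm_frac minimum fraction of a hit inside an arm.
#' @param min_pairing minimum inter-hit pairedness.
#' @return a `duplex_call`: `verdict` (`"duplex"`/`"rejected"`), `reason`,
#'   `mirna_interval`, `star_interval`, `n_pairs_between`, plus the hit ids.
#' @export
call_duplex <- function(fold, hits, min_arm_frac = 0.8, min_pairing = 0.6) {
  res <- function(verdict, reason, a = NULL, b = NULL, np = 0) {
    structure(list(verdict = verdict, reason = reason,
                   mirna_interval = if (!is.null(a)) c(a$start, a$end),
                   star_interval = if (!is.null(b)) c(b$start, b$end),
                   mirna_id = if (!is.null(a)) a$candidate_id,
                   star_id = if (!is.null(b)) b$candidate_id,
                   n_pairs_between = np),
              class = "duplex_call")
  }
  if (is.null(fold$arm5)) return(res("rejected", "no arms"))
  on5 <- vapply(seq_len(nrow(hits)), function(r)
    interval_overlap_frac(c(hits$start[r], hits$end[r]), fold$arm5), 0) >= min_arm_frac
  on3 <- vapply(seq_len(nrow(hits)), function(r)
    interval_overlap_frac(c(hits$start[r], hits$end[r]), fold$arm3), 0) >= min_arm_frac
  if (!any(on5) || !any(on3)) {
    reason <- if (sum(on5) >= 2 || sum(on3) >= 2) "same arm" else "arm placement"
    return(res("rejected", reason))
  }
  pairs <- fold$pairs            # 1-based
  partner <- integer(nchar(fold$sequence))
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  best <- NULL
  for (a in which(on5)) for (b in which(on3)) {
    if (hits$candidate_id[a] == hits$candidate_id[b]) next
    if (!(hits$end[a] <= hits$start[b] || hits$end[b] <= hits$start[a])) next
    pos_a <- (hits$start[a] + 1):hits$end[a]        # 1-based positions
    pos_b <- (hits$start[b] + 1):hits$end[b]
    a_to_b <- sum(partner[pos_a] %in% pos_b)
    b_to_a <- sum(partner[pos_b] %in% pos_a)
    frac_a <- a_to_b / length(pos_a)
    frac_b <- b_to_a / length(pos_b)
    if (frac_a >= min_pairing && frac_b >= min_pairing) {
      ha <- hits[a, ]; hb <- hits[b, ]
      return(res("duplex", "opposite arms paired", ha, hb, a_to_b))
    }
    best <- max(best, min(frac_a, frac_b))
  }
  res("rejected", "insufficient pairing")
}

#' @export
print.duplex_call <- function(x, ...) {
  cat(sprintf("duplex_call: %s (%s)\n", x$verdict, x$reason))
  if (x$verdict == "duplex")
    cat(sprintf("  miRNA %s [%d,%d) / star %s [%d,%d), %d inter-arm pairs\n",
                x$mirna_id, x$mirna_interval[1], x$mirna_interval[2],
                x$star_id, x$star_interval[1], x$star_interval[2],
                x$n_pairs_between))
  invisible(x)
}

#' Discover precursors and duplexes across contigs
#'
#' Runs the full precursor stage: map candidates, screen for contigs with
#' two distinct non-overlapping hits, fold each passing contig (windows
#' around the hits are folded when a contig exceeds `max_fold_len`), and
#' call duplexes.
#'
#' @param candidates candidates to map (see [map_candidates_to_contigs()]).
#' @param contigs data frame `id`, `sequence`.
#' @param min_identity mapping identity.
#' @param max_fold_len maximum length folded at once.
#' @param flank window padding when a contig is longer than `max_fold_len`.
#' @return list with `hits`, `screened` (contig ids), and `duplexes` (data
#'   frame: contig, verdict, reason, miRNA/star ids and intervals).
#' @export
find_precursors <- function(candidates, contigs, min_identity = 1.00,
                            max_fold_len = 200, flank = 15) {
  hits <- map_candidates_to_contigs(candidates, contigs,
                                    min_identity = min_identity)
  screened <- screen_precursor_contigs(hits)
  rows <- list()
  for (cid in screened) {
    h <- hits[hits$contig_id == cid, , drop = FALSE]
    seq <- contigs$sequence[match(cid, contigs$id)]
    off <- 0L
    if (nchar(seq) > max_fold_len) {
      lo <- max(0L, min(h$start) - flank)
      hi <- min(nchar(seq), max(h$end) + flank)
      if (hi - lo > max_fold_len) hi <- lo + max_fold_len
      seq <- substr(seq, lo + 1, hi)
      off <- lo
      h <- h[h$start >= lo & h$end <= hi, , drop = FALSE]
      h$start <- h$start - lo; h$end <- h$end - lo
    }
    if (nchar(seq) < 40 || nrow(h) < 2) next
    fold <- fold_hairpin(seq)
    call <- call_duplex(fold, h)
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = cid, verdict = call$verdict, reason = call$reason,
      mirna_id = call$mirna_id %||% NA_character_,
      star_id = call$star_id %||% NA_character_,
      mirna_start = (call$mirna_interval[1] %||% NA_integer_) + off,
      mirna_end = (call$mirna_interval[2] %||% NA_integer_) + off,
      star_start = (call$star_interval[1] %||% NA_integer_) + off,
      star_end = (call$star_interval[2] %||% NA_integer_) + off,
      stringsAsFactors = FALSE)
  }
  duplexes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), verdict = character(),
               reason = character())
  list(hits = hits, screened = screened, duplexes = duplexes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
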