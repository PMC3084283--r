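# Hairpin folding by base-pair maximization (Nussinov-style dynamic
# programming) with a minimum loop of 3 nt and G-T wobble pairs, plus arm
# detection around the largest hairpin loop. Deterministic traceback.

can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

# maximal nested pairing; returns list(pairs = 2-col matrix of 1-based index
# pairs, n = matrix of subproblem scores)
nussinov <- function(chars, min_loop = 3) {
  L <- length(chars)
  N <- matrix(0L, L, L)
  if (L >= min_loop + 2) {
    for (span in (min_loop + 1):(L - 1)) {
      for (i in seq_len(L - span)) {
        j <- i + span
        best <- N[i + 1, j]
        ks <- (i + min_loop + 1):j
        ks <- ks[can_pair(chars[i], chars[ks])]
        if (length(ks)) {
          left <- ifelse(ks - 1 >= i + 1, N[cbind(rep(i + 1, length(ks)), ks - 1)], 0L)
          right <- ifelse(ks + 1 <= j, N[cbind(pmin(ks + 1, j), rep(j, length(ks)))], 0L)
          right[ks == j] <- 0L
          best <- max(best, max(1L + left + right))
        }
        N[i, j] <- best
      }
    }
  }
  # iterative traceback; prefer pairing i with the smallest admissible k
  pairs <- matrix(integer(), ncol = 2)
  stack <- list(c(1L, L))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= min_loop) next
    if (N[i, j] == 0L) next
    ks <- (i + min_loop + 1):j
    ks <- ks[can_pair(chars[i], chars[ks])]
    paired <- FALSE
    for (k in ks) {
      left <- if (k - 1 >= i + 1) N[i + 1, k - 1] else 0L
      right <- if (k + 1 <= j) N[k + 1, j] else 0L
      if (N[i, j] == 1L + left + right) {
        pairs <- rbind(pairs, c(i, k))
        if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1L, j)
        if (i + 1 <= k - 1) stack[[length(stack) + 1]] <- c(i + 1L, k - 1L)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1]] <- c(i + 1L, j)
  }
  list(pairs = pairs, score = N[1, L])
}

dot_bracket <- function(L, pairs) {
  s <- rep(".", L)
  if (nrow(pairs)) { s[pairs[, 1]] <- "("; s[pairs[, 2]] <- ")" }
  paste(s, collapse = "")
}

#' Fold a putative precursor into a hairpin
#'
#' Computes the maximal nested base pairing (A-T, G-C and G-T wobble; minimum
#' loop 3 nt) by dynamic programming, then locates the hairpin arms as the
#' stem flanking the largest hairpin loop (following the stem outward through
#' bulges until it branches or ends). Traceback is deterministic: position i
#' pairs with the smallest admissible partner. Base-pair maximization stands
#' in for a thermodynamic folder, keeping the decision structure (paired
#' arms, loop, pairedness thresholds) while staying dependency-free; a
#' pre-computed dot-bracket string from an external folder can be supplied
#' instead via `structure`.
#'
#' @param sequence DNA/RNA sequence.
#' @param min_len,max_len admissible sequence length range.
#' @param min_loop minimum unpaired loop length.
#' @param structure optional dot-bracket string overriding the internal
#'   folder.
#' @return a `hairpin_fold`: `sequence`, `pairs` (1-based index pairs),
#'   `n_pairs`, `dot_bracket`, `arm5`, `loop`, `arm3` (0-based half-open
#'   intervals or `NULL`), `pairedness` (fraction of arm positions paired).
#' @export
fold_hairpin <- function(sequence, min_len = 40, max_len = 200, min_loop = 3,
                         structure = NULL) {
  sequence <- as_dna(sequence)
  L <- nchar(sequence)
  if (L < min_len || L > max_len)
    fail("sequence length %d outside [%d, %d]", L, min_len, max_len)
  chars <- strsplit(sequence, "")[[1]]
  if (is.null(structure)) {
    ns <- nussinov(chars, min_loop)
    pairs <- ns$pairs
  } else {
    if (nchar(structure) != L) fail("dot-bracket length mismatch")
    op <- integer(0); pairs <- matrix(integer(), ncol = 2)
    sc <- strsplit(structure, "")[[1]]
    for (p in seq_len(L)) {
      if (sc[p] == "(") op <- c(op, p)
      else if (sc[p] == ")") {
        pairs <- rbind(pairs, c(op[length(op)], p))
        op <- op[-length(op)]
      }
    }
  }
  fold <- list(sequence = sequence, pairs = pairs, n_pairs = nrow(pairs),
               dot_bracket = dot_bracket(L, pairs),
               arm5 = NULL, loop = NULL, arm3 = NULL,
               pairedness = c(arm5 = NA_real_, arm3 = NA_real_))
  class(fold) <- "hairpin_fold"
  if (nrow(pairs) == 0) return(fold)
  # The main stem is the longest chain of nested pairs in which every pair
  # has exactly one child pair (bulges allowed, branching ends a chain).
  # Its outer pair bounds the arms; its inner pair closes the loop (which
  # may itself contain short sub-hairpins).
  np <- nrow(pairs)
  parent <- vapply(seq_len(np), function(r) {
    enc <- which(pairs[, 1] < pairs[r, 1] & pairs[, 2] > pairs[r, 2])
    if (length(enc) == 0) NA_integer_ else enc[which.max(pairs[enc, 1])]
  }, 1L)
  n_children <- tabulate(parent[!is.na(parent)], nbins = np)
  child_of <- rep(NA_integer_, np)
  kids <- which(!is.na(parent))
  child_of[parent[kids][n_children[parent[kids]] == 1]] <-
    kids[n_children[parent[kids]] == 1]
  heads <- which(is.na(parent) | n_children[parent] != 1)
  best_len <- 0L; best_head <- NA_integer_; best_tail <- NA_integer_
  for (h in heads) {
    len <- 1L; cur <- h
    while (!is.na(child_of[cur])) { cur <- child_of[cur]; len <- len + 1L }
    loop_len <- pairs[cur, 2] - pairs[cur, 1] - 1L
    better <- len > best_len ||
      (len == best_len && !is.na(best_tail) &&
         loop_len > pairs[best_tail, 2] - pairs[best_tail, 1] - 1L)
    if (better) { best_len <- len; best_head <- h; best_tail <- cur }
  }
  hp <- pairs[best_head, ]; tp <- pairs[best_tail, ]
  arm5 <- c(hp[1] - 1L, tp[1])       # 0-based half-open
  arm3 <- c(tp[2] - 1L, hp[2])
  paired_pos <- c(pairs)
  pness <- function(iv) {
    pos <- (iv[1] + 1):iv[2]
    mean(pos %in% paired_pos)
  }
  fold$arm5 <- arm5
  fold$loop <- c(tp[1], tp[2] - 1L)
  fold$arm3 <- arm3
  fold$pairedness <- c(arm5 = pness(arm5), arm3 = pness(arm3))
  fold
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(sprintf("hairpin_fold: %d nt, %d pairs\n%s\n%s\n",
              nchar(x$sequence), x$n_pairs, x$sequence, x$dot_bracket))
  if (!is.null(x$arm5))
    cat(sprintf("arms: 5' [%d,%d) / 3' [%d,%d), pairedness %.2f / %.2f\n",
                x$arm5[1], x$arm5[2], x$arm3[1], x$arm3[2],
                x$pairedness["arm5"], x$pairedness["arm3"]))
  invisible(x)
}
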