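# Per-family position-specific scoring matrices for known-miRNA annotation.

#' Build a PSSM profile from an aligned miRNA family
#'
#' Column scores are log2 odds of the observed base frequency (with a
#' pseudocount of 0.25 per base) against a uniform background of 0.25:
#' `score(b) = log2(((n_b + 0.25) / (N + 1)) / 0.25)`, where `N` counts
#' non-gap bases in the column. The consensus takes each column's
#' highest-scoring base (ties resolved in A,C,G,T order).
#'
#' @param family_sequences character vector of aligned sequences, all the
#'   same length; `-` marks gaps.
#' @param family family name.
#' @param pseudocount per-base pseudocount.
#' @return a `pssm_profile`: list with `family`, `matrix` (columns x ACGT),
#'   `consensus`, `n_sequences`.
#' @export
build_pssm <- function(family_sequences, family = "family", pseudocount = 0.25) {
  if (length(family_sequences) < 1) fail("empty family: %s", family)
  seqs <- toupper(as_dna(gsub("\\.", "-", family_sequences)))
  L <- unique(nchar(seqs))
  if (length(L) != 1) fail("ragged alignment in family %s", family)
  chars <- do.call(rbind, strsplit(seqs, ""))
  mat <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(L)) {
    col <- chars[, j]
    counts <- vapply(DNA_BASES, function(b) sum(col == b), 0)
    total <- sum(counts)
    mat[j, ] <- log2(((counts + pseudocount) / (total + 4 * pseudocount)) / 0.25)
  }
  consensus <- paste(DNA_BASES[apply(mat, 1, which.max)], collapse = "")
  structure(list(family = family, matrix = mat, consensus = consensus,
                 n_sequences = length(seqs)),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("pssm_profile '%s': %d columns from %d sequences\n  consensus %s\n",
              x$family, nrow(x$matrix), x$n_sequences, x$consensus))
  invisible(x)
}

#' Build profiles for a list of families
#'
#' @param families named list of aligned sequence vectors.
#' @return named list of `pssm_profile` objects.
#' @export
build_pssm_set <- function(families) {
  out <- lapply(names(families), function(f) build_pssm(families[[f]], f))
  names(out) <- names(families)
  out
}

#' Scan reads against PSSM profiles for known miRNAs
#'
#' Each read is slid ungapped against every profile consensus over start
#' offsets -3..+3 nt (absorbing the 5'/3' end heterogeneity of miRNA
#' processing). Identity is matching positions over compared (overlapping)
#' positions; untemplated 3' additions falling outside the consensus are not
#' compared. A read is labeled `known:<family>` when its best identity
#' reaches `min_identity`; identity ties between families are broken by the
#' higher summed PSSM score.
#'
#' @param reads a [read_set()].
#' @param profiles list of [build_pssm()] profiles.
#' @param min_identity identity threshold.
#' @param offsets integer offsets of the read start on the consensus.
#' @param min_overlap minimum compared positions.
#' @return data frame: `id`, `category`, `family`, `identity`, `coverage`
#'   (compared positions over read length), `score`.
#' @export
scan_profiles <- function(reads, profiles, min_identity = 0.90,
                          offsets = -3:3, min_overlap = 16) {
  n <- nrow(reads)
  res <- data.frame(id = reads$id, category = rep("unassigned", n),
                    family = NA_character_, identity = 0, coverage = 0,
                    score = -Inf, stringsAsFactors = FALSE)
  if (n == 0 || length(profiles) == 0) return(res)
  read_chars <- strsplit(reads$sequence, "")
  cons_chars <- lapply(profiles, function(p) strsplit(p$consensus, "")[[1]])
  for (r in seq_len(n)) {
    rc <- read_chars[[r]]
    Lr <- length(rc)
    best <- c(identity = -1, score = -Inf)
    best_fam <- NA_character_
    best_overlap <- 0
    for (f in seq_along(profiles)) {
      cc <- cons_chars[[f]]
      Lc <- length(cc)
      pm <- profiles[[f]]$matrix
      for (o in offsets) {
        k <- seq_len(Lr)
        pos <- k + o                      # consensus positions
        keep <- pos >= 1 & pos <= Lc
        if (sum(keep) < min_overlap) next
        k <- k[keep]; pos <- pos[keep]
        ident <- sum(rc[k] == cc[pos]) / length(k)
        sc <- sum(pm[cbind(pos, match(rc[k], DNA_BASES))], na.rm = TRUE)
        if (ident > best["identity"] + 1e-12 ||
            (abs(ident - best["identity"]) <= 1e-12 && sc > best["score"])) {
          best <- c(identity = ident, score = sc)
          best_fam <- profiles[[f]]$family
          best_overlap <- length(k)
        }
      }
    }
    if (best["identity"] >= min_identity) {
      res$category[r] <- paste0("known:", best_fam)
      res$family[r] <- best_fam
      res$identity[r] <- best[["identity"]]
      res$coverage[r] <- best_overlap / Lr
      res$score[r] <- best[["score"]]
    }
  }
  res
}

#' Write / read a PSSM profile store as TSV
#'
#' Columns: `family`, `column`, `A`, `C`, `G`, `T`, `consensus_base`,
#' `n_sequences`.
#'
#' @param profiles list of profiles.
#' @param path TSV path.
#' @export
write_pssm_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(family = p$family, column = seq_len(nrow(p$matrix)),
               A = p$matrix[, "A"], C = p$matrix[, "C"],
               G = p$matrix[, "G"], T = p$matrix[, "T"],
               consensus_base = strsplit(p$consensus, "")[[1]],
               n_sequences = p$n_sequences)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm_profiles
#' @export
read_pssm_profiles <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(split(df, df$family), function(d) {
    d <- d[order(d$column), ]
    mat <- as.matrix(d[, DNA_BASES])
    dimnames(mat) <- list(NULL, DNA_BASES)
    structure(list(family = d$family[1], matrix = mat,
                   consensus = paste(d$consensus_base, collapse = ""),
                   n_sequences = d$n_sequences[1]),
              class = "pssm_profile")
  })
  out[unique(df$family)]
}
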