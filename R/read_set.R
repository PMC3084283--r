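#' Read sets: unique small-RNA sequences with per-library counts
#'
#' A `read_set` is the atom of the pipeline: a data frame with columns `id`
#' and `sequence` plus one numeric count column per sequencing library.
#' Sequences are uppercase DNA (`U` is normalized to `T` on input); every row
#' must have at least one positive library count.
#'
#' @param id character vector of record labels.
#' @param sequence character vector of sequences over {A,C,G,T,N}.
#' @param counts numeric matrix (rows = records) with one named column per
#'   library, or a named numeric vector for a single library.
#' @param library single library label used when `counts` is an unnamed vector.
#' @return a `read_set` (data frame subclass).
#' @export
read_set <- function(id, sequence, counts, library = "library1") {
  sequence <- as_dna(sequence)
  if (is.null(dim(counts))) {
    counts <- matrix(as.numeric(counts), ncol = 1,
                     dimnames = list(NULL, library))
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) fail("count columns must be named by library")
  x <- data.frame(id = as.character(id), sequence = sequence,
                  stringsAsFactors = FALSE)
  for (lib in colnames(counts)) x[[lib]] <- as.numeric(counts[, lib])
  attr(x, "libraries") <- colnames(counts)
  class(x) <- c("read_set", "data.frame")
  validate_read_set(x)
  x
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d unique sequences, %s reads across %d library(ies) [%s]\n",
              nrow(x), format(sum(total_counts(x)), big.mark = ","),
              length(libraries(x)), paste(libraries(x), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Library labels of a read set
#' @param x a `read_set`.
#' @export
libraries <- function(x) attr(x, "libraries")

#' Per-record total read counts (summed over libraries)
#' @param x a `read_set`.
#' @return numeric vector, one total per record.
#' @export
total_counts <- function(x) {
  libs <- libraries(x)
  if (length(libs) == 1L) return(x[[libs]])
  rowSums(as.matrix(as.data.frame(x)[, libs, drop = FALSE]))
}

count_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, libraries(x), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Validate read-set invariants
#' @param x a `read_set`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_read_set <- function(x) {
  if (nrow(x) > 0) {
    if (any(nchar(x$sequence) < 1)) fail("empty sequence in read_set")
    check_alphabet(x$sequence)
    cm <- count_matrix(x)
    if (any(cm < 0)) fail("negative read counts")
    if (any(rowSums(cm) <= 0)) fail("record with no positive library count")
  }
  invisible(x)
}

# rebuild a read_set from a plain data.frame slice, keeping library attr
as_read_set <- function(df, libs) {
  rownames(df) <- NULL
  attr(df, "libraries") <- libs
  class(df) <- c("read_set", "data.frame")
  df
}

#' Merge two read sets over distinct libraries
#'
#' Records with identical sequences are aligned; counts absent from a library
#' are zero.
#'
#' @param a,b `read_set` objects with disjoint library labels.
#' @return combined `read_set`.
#' @export
merge_read_sets <- function(a, b) {
  la <- libraries(a); lb <- libraries(b)
  if (length(intersect(la, lb)) > 0) fail("library labels overlap")
  seqs <- union(a$sequence, b$sequence)
  ia <- match(seqs, a$sequence); ib <- match(seqs, b$sequence)
  cm <- matrix(0, nrow = length(seqs), ncol = length(la) + length(lb),
               dimnames = list(NULL, c(la, lb)))
  cma <- count_matrix(a); cmb <- count_matrix(b)
  cm[!is.na(ia), la] <- cma[ia[!is.na(ia)], , drop = FALSE]
  cm[!is.na(ib), lb] <- cmb[ib[!is.na(ib)], , drop = FALSE]
  id <- ifelse(is.na(ia), b$id[ib], a$id[ia])
  read_set(id, seqs, cm)
}
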