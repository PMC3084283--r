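#' @importFrom stats aggregate cor pt runif rnorm setNames
#' @importFrom utils read.delim write.table combn head
#' @importFrom BiocGenerics start end width score
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' Sequences are stored internally in the DNA alphabet; `as_rna()` renders the
#' RNA form (T to U) for display or export, `as_dna()` normalizes input the
#' other way (U to T, uppercased).
#'
#' @param x character vector of sequences.
#' @return character vector.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# stop() with call.=FALSE and sprintf formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# check sequences are uppercase A/C/G/T/N
check_alphabet <- function(seqs, where = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    fail("%d %s(s) contain characters outside {A,C,G,T,N}; first offender: %s",
         sum(bad), where, seqs[which(bad)[1]])
  }
  invisible(TRUE)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, salt) {
  (as.numeric(seed) * 7919 + salt) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
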