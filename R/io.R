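#' Read small-RNA sequences from FASTA or FASTQ
#'
#' Reads are returned un-collapsed (identical sequences stay on separate rows;
#' see [collapse_identical()]). `U` is normalized to `T` and sequences are
#' uppercased; nothing else is altered. Two collapsed-FASTA header dialects
#' encode a read count: a trailing `-N` or `_xN` (e.g. `>c1-7`, `>s12_x532`).
#' `_xN` takes precedence when both could apply; otherwise the count is 1.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @param library library label attached to the counts.
#' @return a [read_set()].
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           library = "library1") {
  format <- match.arg(format)
  if (!file.exists(path)) fail("input file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) fail("malformed %s file %s: %s", format, path,
                             conditionMessage(e)))
  if (length(set) == 0) {
    warn("no sequences in %s", path)
    return(read_set(character(), character(),
                    matrix(numeric(), ncol = 1, dimnames = list(NULL, library))))
  }
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1)
  seqs <- as_dna(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warn("rejected %d record(s) with non-IUPAC residues (first: %s)",
         sum(bad), ids[which(bad)[1]])
    ids <- ids[!bad]; seqs <- seqs[!bad]
  }
  counts <- rep(1, length(ids))
  mx <- regmatches(ids, regexpr("_x[0-9]+$", ids))
  has_x <- lengths(regmatches(ids, gregexpr("_x[0-9]+$", ids))) > 0
  counts[has_x] <- as.numeric(sub("^_x", "", regmatches(ids, regexpr("_x[0-9]+$", ids))))
  dash <- !has_x & grepl("-[0-9]+$", ids)
  counts[dash] <- as.numeric(sub("^.*-", "", ids[dash]))
  read_set(ids, seqs, matrix(counts, ncol = 1, dimnames = list(NULL, library)))
}

#' Construct a reference sequence set
#'
#' @param name set label, e.g. `"rRNA"`, `"hairpin"`, `"species:Lmi"`.
#' @param ids,sequences parallel character vectors.
#' @param mature_coords optional data frame (`hairpin_id`, `start`, `end`),
#'   0-based half-open mature-arm coordinates on the hairpins.
#' @return a `reference_set`.
#' @export
reference_set <- function(name, ids, sequences, mature_coords = NULL) {
  sequences <- as_dna(sequences)
  if (anyDuplicated(ids)) fail("duplicate ids in reference set '%s'", name)
  if (length(sequences)) check_alphabet(sequences, name)
  if (!is.null(mature_coords) && nrow(mature_coords) > 0) {
    j <- match(mature_coords$hairpin_id, ids)
    if (anyNA(j)) fail("mature_coords refer to unknown hairpin id: %s",
                       mature_coords$hairpin_id[which(is.na(j))[1]])
    len <- nchar(sequences)[j]
    ok <- mature_coords$start >= 0 & mature_coords$end <= len &
      mature_coords$start < mature_coords$end
    if (!all(ok)) fail("mature_coords out of bounds for hairpin %s",
                       mature_coords$hairpin_id[which(!ok)[1]])
  }
  structure(list(name = name,
                 sequences = data.frame(id = as.character(ids),
                                        sequence = sequences,
                                        stringsAsFactors = FALSE),
                 mature_coords = mature_coords),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set '%s': %d sequences%s\n", x$name,
              nrow(x$sequences),
              if (!is.null(x$mature_coords))
                sprintf(", %d mature intervals", nrow(x$mature_coords)) else ""))
  invisible(x)
}

STANDARD_REFSETS <- c("rRNA", "tRNA", "snRNA", "piRNA_transposon",
                      "endosymbiont", "known_mature", "hairpin")

#' Load reference bundles from a key = value config
#'
#' The config is a flat `key = value` text file mapping set names to FASTA
#' paths. Recognized keys: the contaminant sets (`rRNA`, `tRNA`, `snRNA`,
#' `piRNA_transposon`, `endosymbiont`), `known_mature`, `hairpin`,
#' `hairpin_coords` (TSV of 0-based half-open mature coordinates on the
#' hairpins) and any number of `species:<tag>` small-RNA sets used for
#' conservation calls. Standard sets left unconfigured come back empty, with
#' a warning.
#'
#' @param config path to the config file.
#' @return named list of `reference_set` objects.
#' @export
load_reference_sets <- function(config) {
  conf <- read_config(config)
  base <- dirname(normalizePath(config))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  coords <- NULL
  if (!is.null(conf$hairpin_coords)) {
    p <- resolve(conf$hairpin_coords)
    if (!file.exists(p)) fail("hairpin_coords file not found: %s", p)
    coords <- read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
  }
  keys <- setdiff(names(conf), "hairpin_coords")
  keys <- keys[keys %in% STANDARD_REFSETS | startsWith(keys, "species:")]
  out <- list()
  for (k in keys) {
    p <- resolve(conf[[k]])
    if (!file.exists(p)) fail("reference file for set '%s' not found: %s", k, p)
    ss <- Biostrings::readBStringSet(p)
    ids <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1)
    out[[k]] <- reference_set(k, ids, as.character(ss),
                              mature_coords = if (k == "hairpin") coords else NULL)
  }
  missing <- setdiff(STANDARD_REFSETS, names(out))
  if (length(missing)) {
    warn("unconfigured reference sets left empty: %s",
         paste(missing, collapse = ", "))
    for (k in missing) out[[k]] <- reference_set(k, character(), character())
  }
  out
}

CANDIDATE_STATUS <- c("known", "star", "conserved_candidate",
                      "specific_candidate", "contaminant", "artefact",
                      "unassigned")

#' Candidate tables
#'
#' One row per non-redundant representative sequence: `candidate_id`,
#' `sequence`, `status`, `cluster_id`, then one count column per library
#' (counts are summed over the cluster the representative stands for).
#'
#' @param candidate_id,sequence,status,cluster_id row fields.
#' @param counts numeric matrix with one named column per library.
#' @return a `candidate_table` (data frame subclass).
#' @export
candidate_table <- function(candidate_id, sequence, status, cluster_id, counts) {
  if (!all(status %in% CANDIDATE_STATUS))
    fail("unknown status value(s): %s",
         paste(setdiff(status, CANDIDATE_STATUS), collapse = ", "))
  counts <- as.matrix(counts)
  x <- data.frame(candidate_id = as.character(candidate_id),
                  sequence = as_dna(sequence),
                  status = as.character(status),
                  cluster_id = as.character(cluster_id),
                  stringsAsFactors = FALSE)
  for (lib in colnames(counts)) x[[lib]] <- as.numeric(counts[, lib])
  attr(x, "libraries") <- colnames(counts)
  class(x) <- c("candidate_table", "data.frame")
  x
}

table_totals <- function(tab) {
  rowSums(as.matrix(as.data.frame(tab)[, attr(tab, "libraries"), drop = FALSE]))
}

#' Write / read a candidate table as TSV
#'
#' Rows are written in a deterministic order: descending total read count,
#' ties broken by lexicographic sequence. Comment lines starting with `#`
#' (e.g. a recorded seed) are skipped on read. An `rna = TRUE` flag renders
#' sequences in the RNA alphabet on output; they are normalized back to DNA
#' on read.
#'
#' @param table a [candidate_table()].
#' @param path output TSV path.
#' @param header_comments optional character vector written as leading
#'   `#`-prefixed lines.
#' @param rna render sequences with U instead of T.
#' @export
write_candidate_table <- function(table, path, header_comments = NULL,
                                  rna = FALSE) {
  ord <- order(-table_totals(table), table$sequence)
  out <- as.data.frame(table)[ord, , drop = FALSE]
  if (rna) out$sequence <- as_rna(out$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidate_table
#' @export
read_candidate_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  fixed <- c("candidate_id", "sequence", "status", "cluster_id")
  if (!all(fixed %in% names(df)))
    fail("not a candidate table (missing columns): %s", path)
  libs <- setdiff(names(df), c(fixed, "species"))
  out <- candidate_table(df$candidate_id, df$sequence, df$status,
                         df$cluster_id, as.matrix(df[, libs, drop = FALSE]))
  if ("species" %in% names(df)) out$species <- df$species
  out
}

#' Write sequences as FASTA
#'
#' @param ids,sequences parallel vectors.
#' @param path output path.
#' @param counts optional numeric vector appended to ids as `_xN`.
#' @param rna render in RNA alphabet.
#' @export
write_fasta <- function(ids, sequences, path, counts = NULL, rna = FALSE) {
  if (!is.null(counts)) ids <- sprintf("%s_x%d", ids, as.integer(counts))
  if (rna) sequences <- as_rna(sequences)
  writeLines(paste0(">", ids, "\n", sequences), path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `gene`, `group` (control/treated), `replicate`, `Ct` and
#' optionally `efficiency`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_qpcr_table <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "group", "replicate", "Ct")
  if (!all(need %in% names(df))) fail("not a qPCR Ct table: %s", path)
  if (!all(df$group %in% c("control", "treated")))
    fail("qPCR group must be 'control' or 'treated'")
  if (any(df$Ct <= 0)) fail("non-positive Ct values")
  df
}

#' Flat key = value config files
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers are converted.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) fail("malformed config line: %s", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) paste(format(v, scientific = FALSE),
                                                      collapse = ","), "")),
             path)
  invisible(path)
}
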