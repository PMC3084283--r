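# shared fixtures and independent oracles

.shared <- new.env(parent = emptyenv())

# one full pipeline run on the default synthetic libraries (fixed seed),
# shared across test files to keep the suite fast
get_shared_run <- function(seed = 3) {
  if (is.null(.shared$outdir)) {
    outdir <- file.path(tempdir(), sprintf("mirfree_shared_run_%d", seed))
    if (!file.exists(file.path(outdir, "report.json")))
      run_pipeline(pipeline_config(outdir = outdir, seed = seed))
    .shared$outdir <- outdir
    .shared$config <- pipeline_config(outdir = outdir, seed = seed)
  }
  list(outdir = .shared$outdir, config = .shared$config)
}

# a similarity_graph from an explicit edge list (indices)
make_graph <- function(n, edges, counts = seq_len(n)) {
  edges <- if (length(edges)) matrix(as.integer(edges), ncol = 2, byrow = TRUE)
           else matrix(integer(), ncol = 2)
  structure(list(nodes = data.frame(id = sprintf("n%02d", seq_len(n)),
                                    sequence = sprintf("s%02d", seq_len(n)),
                                    total = counts,
                                    L1 = counts, stringsAsFactors = FALSE),
                 edges = cbind(from = pmin(edges[, 1], edges[, 2]),
                               to = pmax(edges[, 1], edges[, 2])),
                 libraries = "L1"),
            class = "similarity_graph")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# rebuild a read_set from a plain data-frame slice (slicing drops attributes)
as_read_set_for_test <- function(df, lib = "WB") {
  read_set(df$id, df$sequence,
           matrix(df[[lib]], ncol = 1, dimnames = list(NULL, lib)))
}

# read_set of end-variants of a few random cores (clustering fixture)
make_variant_reads <- function(n_cores = 8, n_variants = 12, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (k in seq_len(n_cores)) {
      core <- random_dna(30)
      for (v in seq_len(n_variants)) {
        s5 <- sample(0:3, 1); s3 <- sample(0:3, 1)
        seq <- substr(core, 1 + s5, 30 - s3)
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("c%d_v%d", k, v), sequence = seq,
          count = sample(1:500, 1))
      }
    }
    df <- do.call(rbind, rows)
    df <- df[!duplicated(df$sequence), ]
    read_set(df$id, df$sequence, matrix(df$count, ncol = 1,
                                        dimnames = list(NULL, "L1")))
  })
}

# independent single-linkage oracle: all-pairs align_pair + plain union-find
brute_force_partition <- function(reads, min_identity = 0.9,
                                  min_coverage = 0.8) {
  n <- nrow(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      al <- align_pair(reads$sequence[i], reads$sequence[j])
      if (al$identity >= min_identity && al$coverage >= min_coverage) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

# canonical form of a partition over sequences, for comparison
partition_signature <- function(labels, keys) {
  groups <- split(keys, labels)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, "", collapse = ",")), collapse = ";")
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, mx) {
    k <- length(labels) + 1
    if (k > n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (v in seq_len(mx + 1)) grow(c(labels, v), max(mx, v))
  }
  grow(integer(), 0L)
  out
}

# exhaustive maximum nested-pairing count (independent of the DP folder)
max_pairs_exhaustive <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (ok(chars[i], chars[k]))
        best <- max(best, 1L + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  if (length(chars) < min_loop + 2) return(0L)
  rec(1L, length(chars))
}
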