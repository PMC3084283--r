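# Single-linkage clustering of sequence variants at identity/coverage
# thresholds, with the most abundant member as cluster representative.

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, as.integer(i)); rj <- uf_find(parent, as.integer(j))
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' Cluster reads by sequence similarity
#'
#' Single-linkage transitive closure over all pairs whose optimal local
#' alignment reaches both thresholds (defaults: 90% identity, 80% coverage
#' of the shorter sequence), clustering the 5'/3' end variants of one miRNA
#' into one cluster. Every read lands in exactly one cluster; the
#' representative is the member with the largest total count (ties broken by
#' lexicographically smallest sequence). The partition does not depend on
#' input order.
#'
#' @param reads collapsed, filtered [read_set()].
#' @param min_identity minimum alignment identity.
#' @param min_coverage minimum coverage of the shorter sequence.
#' @return a `sequence_clusters` object: list with `membership` (data frame
#'   `cluster_id`, `member_id`, `is_representative`) and `clusters` (list of
#'   `members`, `representative`, `representative_sequence`, `counts`,
#'   `total`), ordered by descending total count.
#' @export
cluster_reads <- function(reads, min_identity = 0.90, min_coverage = 0.80) {
  n <- nrow(reads)
  if (n == 0) return(structure(list(membership = data.frame(), clusters = list()),
                               class = "sequence_clusters"))
  seqs <- reads$sequence
  parent <- uf_new(n)
  pairs <- kmer_candidate_pairs(seqs)
  if (nrow(pairs) > 0) {
    ev <- evaluate_pairs(seqs, pairs)
    hit <- ev$identity >= min_identity & ev$coverage >= min_coverage
    for (r in which(hit)) parent <- uf_union(parent, ev$i[r], ev$j[r])
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  groups <- split(seq_len(n), root)
  tot <- total_counts(reads)
  cm <- count_matrix(reads)
  clusters <- lapply(groups, function(idx) {
    best <- idx[order(-tot[idx], seqs[idx])][1]
    list(members = reads$id[idx],
         representative = reads$id[best],
         representative_sequence = seqs[best],
         counts = colSums(cm[idx, , drop = FALSE]),
         total = sum(tot[idx]),
         member_rows = idx, representative_row = best)
  })
  ord <- order(-vapply(clusters, `[[`, 0, "total"),
               vapply(clusters, `[[`, "", "representative_sequence"))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("cluster%d", seq_along(clusters))
  membership <- do.call(rbind, lapply(names(clusters), function(cid) {
    cl <- clusters[[cid]]
    data.frame(cluster_id = cid, member_id = cl$members,
               is_representative = cl$members == cl$representative)
  }))
  structure(list(membership = membership, clusters = clusters,
                 libraries = libraries(reads)),
            class = "sequence_clusters")
}

#' @export
print.sequence_clusters <- function(x, ...) {
  cat(sprintf("sequence_clusters: %d clusters over %d reads\n",
              length(x$clusters), nrow(x$membership)))
  invisible(x)
}

#' Representative read set of a clustering
#'
#' One record per cluster: the predominant member's sequence carrying the
#' cluster's summed per-library counts.
#'
#' @param clusters a `sequence_clusters` from [cluster_reads()].
#' @return a [read_set()].
#' @export
cluster_representatives <- function(clusters) {
  cl <- clusters$clusters
  cm <- do.call(rbind, lapply(cl, `[[`, "counts"))
  read_set(vapply(cl, `[[`, "", "representative"),
           vapply(cl, `[[`, "", "representative_sequence"),
           matrix(cm, nrow = length(cl),
                  dimnames = list(NULL, clusters$libraries)))
}

#' Write cluster membership as TSV
#'
#' @param clusters a `sequence_clusters`.
#' @param path output path.
#' @param header_comments optional `#`-prefixed header lines.
#' @export
write_cluster_table <- function(clusters, path, header_comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comments)) writeLines(paste0("# ", header_comments), con)
  write.table(clusters$membership, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
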