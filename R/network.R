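# Novel-candidate definition: abundance threshold, similarity graph,
# connected components, fast-greedy modularity communities, representatives,
# and conserved/specific classification.

#' Select abundant unannotated reads as candidate input
#'
#' Keeps reads with total count at least `min_reads` (inclusive) whose
#' annotation category is `unassigned` (known miRNAs, stars, contaminants
#' and artefacts are excluded).
#'
#' @param reads a [read_set()].
#' @param annotations optional [annotate_reads()] output aligned to `reads`
#'   by `id`; when `NULL` all reads are treated as unassigned.
#' @param min_reads inclusive total-count threshold.
#' @return a [read_set()] of candidate reads.
#' @export
select_abundant <- function(reads, annotations = NULL, min_reads = 100) {
  keep <- total_counts(reads) >= min_reads
  if (!is.null(annotations)) {
    cat_by_id <- setNames(annotations$category, annotations$id)
    keep <- keep & cat_by_id[reads$id] == "unassigned"
  }
  as_read_set(as.data.frame(reads)[which(keep), , drop = FALSE], libraries(reads))
}

#' Build the candidate similarity graph
#'
#' Nodes are candidate sequences; an (unweighted) edge joins two candidates
#' whose optimal local alignment reaches `min_identity`, covers
#' `min_coverage` of the shorter sequence, and spans at least `min_span`
#' aligned columns (the span floor stands in for a database-size-dependent
#' e-value cutoff).
#'
#' @param candidates a [read_set()] of candidate reads.
#' @param min_identity,min_coverage alignment thresholds.
#' @param min_span minimum aligned columns per edge.
#' @return a `similarity_graph`: list with `nodes` (data frame `id`,
#'   `sequence`, `total`, per-library counts) and `edges` (two-column matrix
#'   of node indices, `from < to`).
#' @export
build_similarity_graph <- function(candidates, min_identity = 0.90,
                                   min_coverage = 0.95, min_span = 16) {
  if (nrow(candidates) < 1) fail("no candidate sequences")
  seqs <- candidates$sequence
  pairs <- kmer_candidate_pairs(seqs)
  edges <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  if (nrow(pairs) > 0) {
    ev <- evaluate_pairs(seqs, pairs)
    hit <- ev$identity >= min_identity & ev$coverage >= min_coverage &
      ev$columns >= min_span
    if (any(hit))
      edges <- cbind(from = pmin(ev$i[hit], ev$j[hit]),
                     to = pmax(ev$i[hit], ev$j[hit]))
  }
  edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
  nodes <- data.frame(id = candidates$id, sequence = seqs,
                      total = total_counts(candidates),
                      stringsAsFactors = FALSE)
  for (lib in libraries(candidates)) nodes[[lib]] <- candidates[[lib]]
  structure(list(nodes = nodes, edges = edges,
                 libraries = libraries(candidates)),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Connected components of a similarity graph
#'
#' @param graph a `similarity_graph`.
#' @return list of integer node-index vectors, sorted by decreasing size
#'   (ties: smallest member index first).
#' @export
connected_components <- function(graph) {
  n <- nrow(graph$nodes)
  parent <- uf_new(n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) parent <- uf_union(parent, e[r, 1], e[r, 2])
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  comps <- split(seq_len(n), root)
  comps <- comps[order(-lengths(comps), vapply(comps, min, 1L))]
  names(comps) <- NULL
  comps
}

#' Modularity of a partition
#'
#' `Q = sum_i (e_ii - a_i^2)` on the unweighted graph, where `e_ii` is the
#' fraction of edges inside community `i` and `a_i` the fraction of edge
#' endpoints in community `i`.
#'
#' @param graph a `similarity_graph`.
#' @param assignment community label per node (any vector).
#' @return modularity Q in [-1, 1].
#' @export
partition_modularity <- function(graph, assignment) {
  m <- nrow(graph$edges)
  if (m == 0) fail("modularity undefined on an edgeless graph")
  if (length(assignment) != nrow(graph$nodes))
    fail("assignment must cover all nodes")
  comm <- as.character(assignment)
  cf <- comm[graph$edges[, 1]]
  ct <- comm[graph$edges[, 2]]
  within <- tapply(cf == ct, cf, sum)
  e_ii <- setNames(rep(0, length(unique(comm))), unique(comm))
  e_ii[names(within)] <- within / m
  ends <- table(c(cf, ct)) / (2 * m)
  a_i <- setNames(rep(0, length(unique(comm))), unique(comm))
  a_i[names(ends)] <- as.numeric(ends)
  sum(e_ii - a_i^2)
}

# CNM greedy merging on one component (node indices `nodes`), using
# whole-graph edge count m for the Q bookkeeping. Returns the component's
# assignment (community id = smallest member node index) at its best-Q point
# along the merge path.
cnm_component <- function(graph, nodes, m) {
  sub_e <- graph$edges[graph$edges[, 1] %in% nodes, , drop = FALSE]
  comm_of <- setNames(nodes, nodes)         # node -> community id
  if (nrow(sub_e) == 0) return(setNames(rep(min(nodes), length(nodes)),
                                        nodes))
  ids <- sort(nodes)
  # e_cnt[i, j]: edges between communities; a_deg: summed degrees
  key <- function(i) as.character(i)
  e_cnt <- new.env(parent = emptyenv())
  ek <- function(i, j) paste(min(i, j), max(i, j))
  inc <- function(i, j, by = 1) {
    k <- ek(i, j)
    assign(k, (if (exists(k, e_cnt)) get(k, e_cnt) else 0) + by, e_cnt)
  }
  for (r in seq_len(nrow(sub_e))) inc(sub_e[r, 1], sub_e[r, 2])
  deg <- setNames(rep(0, length(ids)), ids)
  dt <- table(c(sub_e[, 1], sub_e[, 2]))
  deg[names(dt)] <- as.numeric(dt)
  a_i <- deg / (2 * m)
  e_in <- setNames(rep(0, length(ids)), ids)  # within-community edges / m
  alive <- as.character(ids)
  q_now <- sum(e_in[alive] - a_i[alive]^2)
  best_q <- q_now
  best_assign <- comm_of
  while (length(alive) > 1) {
    # connected community pairs and their dQ
    keys <- ls(e_cnt)
    if (length(keys) == 0) break
    parts <- do.call(rbind, strsplit(keys, " "))
    ci <- as.numeric(parts[, 1]); cj <- as.numeric(parts[, 2])
    eij <- vapply(keys, get, 0, envir = e_cnt)
    live <- as.character(ci) %in% alive & as.character(cj) %in% alive & eij > 0
    if (!any(live)) break
    ci <- ci[live]; cj <- cj[live]; eij <- eij[live]
    # dQ of merging ci, cj: e_ij enters Q once (per-edge fraction), the
    # degree penalty twice
    dq <- eij / m - 2 * a_i[as.character(ci)] * a_i[as.character(cj)]
    ord <- order(-dq, pmin(ci, cj), pmax(ci, cj))
    b <- ord[1]
    i <- min(ci[b], cj[b]); j <- max(ci[b], cj[b])
    # merge j into i
    comm_of[comm_of == j] <- i
    e_in[key(i)] <- e_in[key(i)] + e_in[key(j)] + eij[b] / m
    # rewire inter-community counts of j onto i
    for (k in ls(e_cnt)) {
      pq <- as.numeric(strsplit(k, " ")[[1]])
      if (j %in% pq) {
        other <- setdiff(pq, j)
        cnt <- get(k, e_cnt)
        rm(list = k, envir = e_cnt)
        if (length(other) == 1 && other != i && as.character(other) %in% alive)
          inc(i, other, cnt)
      }
    }
    rm(list = ek(i, j)[exists(ek(i, j), e_cnt)], envir = e_cnt)
    a_i[key(i)] <- a_i[key(i)] + a_i[key(j)]
    alive <- setdiff(alive, key(j))
    q_now <- sum(e_in[alive] - a_i[alive]^2)
    if (q_now > best_q + 1e-12) {
      best_q <- q_now
      best_assign <- comm_of
    }
  }
  best_assign
}

#' Fast-greedy modularity communities
#'
#' Agglomerative (Clauset-Newman-Moore style) community detection: starting
#' from singletons, repeatedly merge the connected pair of communities with
#' the largest modularity gain (ties broken by the smallest community-id
#' pair), and return the partition with maximal Q along the merge path.
#' Disconnected graphs are processed per connected component with Q
#' bookkeeping over the whole graph; an edgeless component becomes a single
#' community with a warning.
#'
#' @param graph a `similarity_graph`.
#' @return a `community_partition`: list with `assignment` (community label
#'   per node), `Q`, and `n_communities`.
#' @export
fast_greedy_communities <- function(graph) {
  n <- nrow(graph$nodes)
  m <- nrow(graph$edges)
  comps <- connected_components(graph)
  assignment <- integer(n)
  if (m == 0) {
    warn("edgeless graph: every node its own community, Q contribution 0")
    assignment <- seq_len(n)
    return(structure(list(assignment = assignment, Q = 0,
                          n_communities = n),
                     class = "community_partition"))
  }
  for (comp in comps) {
    if (length(comp) == 1) {
      assignment[comp] <- comp
    } else {
      a <- cnm_component(graph, comp, m)
      assignment[as.integer(names(a))] <- a
    }
  }
  structure(list(assignment = assignment,
                 Q = partition_modularity(graph, assignment),
                 n_communities = length(unique(assignment))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, Q = %.4f\n",
              x$n_communities, x$Q))
  invisible(x)
}

# subgraph restricted to a node subset, with reindexed nodes
subgraph <- function(graph, nodes) {
  nodes <- sort(nodes)
  idx <- match(seq_len(nrow(graph$nodes)), nodes)
  e <- graph$edges[graph$edges[, 1] %in% nodes & graph$edges[, 2] %in% nodes, ,
                   drop = FALSE]
  e2 <- cbind(from = idx[e[, 1]], to = idx[e[, 2]])
  structure(list(nodes = graph$nodes[nodes, , drop = FALSE],
                 edges = e2, libraries = graph$libraries),
            class = "similarity_graph")
}

#' Representatives of a community partition
#'
#' One representative per community: the member with the maximal total read
#' count (ties: lexicographically smallest sequence); community counts are
#' summed over members.
#'
#' @param graph a `similarity_graph`.
#' @param partition a `community_partition` (or a bare assignment vector).
#' @return a [candidate_table()] with one row per community, status
#'   `unassigned` (conservation is classified separately) and `cluster_id`
#'   naming the community.
#' @export
select_representatives <- function(graph, partition) {
  assignment <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  nd <- graph$nodes
  libs <- graph$libraries
  groups <- split(seq_len(nrow(nd)), assignment)
  rows <- lapply(groups, function(idx) {
    best <- idx[order(-nd$total[idx], nd$sequence[idx])][1]
    counts <- colSums(as.matrix(nd[idx, libs, drop = FALSE]))
    list(id = nd$id[best], sequence = nd$sequence[best], counts = counts)
  })
  cm <- do.call(rbind, lapply(rows, `[[`, "counts"))
  candidate_table(vapply(rows, `[[`, "", "id"),
                  vapply(rows, `[[`, "", "sequence"),
                  rep("unassigned", length(rows)),
                  paste0("community", names(groups)),
                  matrix(cm, nrow = length(rows), dimnames = list(NULL, libs)))
}

#' Define non-redundant candidates from a similarity graph
#'
#' The largest component is partitioned by [fast_greedy_communities()]; each
#' smaller component is kept as a single cluster unless its own greedy
#' partition exceeds `q_threshold`, in which case its communities are used.
#'
#' @param graph a `similarity_graph`.
#' @param q_threshold modularity needed before a minor component is split.
#' @return list with `table` (a [candidate_table()]), `assignment`,
#'   `n_components`, `major_component_size`, `Q_major` (modularity of the
#'   greedy partition of the largest component, over that component's
#'   subgraph), and `n_modules_major`.
#' @export
define_candidates <- function(graph, q_threshold = 0.3) {
  comps <- connected_components(graph)
  n <- nrow(graph$nodes)
  assignment <- integer(n)
  q_major <- NA_real_
  n_modules_major <- NA_integer_
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    if (length(comp) == 1) { assignment[comp] <- comp; next }
    sg <- subgraph(graph, comp)
    if (nrow(sg$edges) == 0) { assignment[comp] <- min(comp); next }
    part <- fast_greedy_communities(sg)
    if (ci == 1) {
      q_major <- part$Q
      n_modules_major <- part$n_communities
      assignment[comp] <- comp[part$assignment]
    } else if (part$Q > q_threshold) {
      assignment[comp] <- comp[part$assignment]
    } else {
      assignment[comp] <- min(comp)
    }
  }
  list(table = select_representatives(graph, assignment),
       assignment = assignment,
       n_components = length(comps),
       major_component_size = length(comps[[1]]),
       Q_major = q_major,
       n_modules_major = n_modules_major)
}

#' Classify candidate conservation against other-species small RNAs
#'
#' A candidate is `conserved` when it matches at least one species set at
#' 100% identity over at least 95% of its length (either strand); matching
#' species tags are recorded. With no species sets (or all empty) every
#' candidate is `specific`.
#'
#' @param table a [candidate_table()].
#' @param species_sets named list of `reference_set`s (names like
#'   `species:Lmi`).
#' @param min_identity,min_coverage match thresholds.
#' @return the table with `status` updated to `conserved_candidate` /
#'   `specific_candidate` and a `species` column of comma-joined tags.
#' @export
classify_conservation <- function(table, species_sets, min_identity = 1.00,
                                  min_coverage = 0.95) {
  tags <- rep("", nrow(table))
  for (nm in names(species_sets)) {
    refs <- species_sets[[nm]]$sequences$sequence
    if (length(refs) == 0) next
    if (min_identity < 1)
      fail("classify_conservation implements exact matching (identity 1.0)")
    cov <- exact_coverage(table$sequence, refs, min_coverage)
    hit <- cov >= min_coverage
    tags[hit] <- ifelse(nzchar(tags[hit]), paste(tags[hit], nm, sep = ","), nm)
  }
  upd <- table$status %in% c("unassigned", "conserved_candidate",
                             "specific_candidate")
  table$status[upd] <- ifelse(nzchar(tags[upd]), "conserved_candidate",
                              "specific_candidate")
  table$species <- tags
  table
}

#' Export a similarity graph as an edge-list TSV
#'
#' @param graph a `similarity_graph`.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(from = graph$nodes$id[graph$edges[, 1]],
                   to = graph$nodes$id[graph$edges[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
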