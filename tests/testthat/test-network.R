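test_that("select_abundant applies the inclusive threshold and annotation filter", {
  rs <- read_set(c("a", "b", "c"),
                 c("ACGTACGTACGTACGTACGTAA", "CCGTACGTACGTACGTACGTAA",
                   "GCGTACGTACGTACGTACGTAA"),
                 matrix(c(99, 100, 1e6), ncol = 1, dimnames = list(NULL, "L1")))
  ann <- data.frame(id = c("a", "b", "c"),
                    category = c("unassigned", "unassigned", "known:miR-1"))
  out <- select_abundant(rs, ann)
  expect_equal(out$id, "b")                      # 99 excluded, 100 included,
                                                 # known excluded at any count
})

test_that("similarity-graph edges match an all-pairs alignment oracle", {
  reads <- make_variant_reads(n_cores = 4, n_variants = 5, seed = 13)
  g <- build_similarity_graph(reads, 0.90, 0.95)
  n <- nrow(reads)
  oracle <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- align_pair(reads$sequence[i], reads$sequence[j])
    oracle[i, j] <- al$identity >= 0.90 && al$coverage >= 0.95 &&
      al$columns >= 16
  }
  got <- matrix(FALSE, n, n)
  if (nrow(g$edges)) got[g$edges] <- TRUE
  expect_equal(got, oracle)
  # no self or duplicate edges
  expect_true(all(g$edges[, 1] < g$edges[, 2]))
  expect_equal(anyDuplicated(g$edges), 0L)

  # two identical sequences -> one edge; two unrelated 22-mers -> none
  rs2 <- read_set(c("x", "y"), rep("ACGTACGTACGTACGTACGTAC", 2),
                  matrix(c(1, 1), ncol = 1, dimnames = list(NULL, "L1")))
  expect_equal(nrow(build_similarity_graph(rs2)$edges), 1)
  withr::with_seed(14, rs3 <- read_set(c("x", "y"),
                                       c(random_dna(22), random_dna(22)),
                                       matrix(c(1, 1), ncol = 1,
                                              dimnames = list(NULL, "L1"))))
  expect_equal(nrow(build_similarity_graph(rs3)$edges), 0)
})

test_that("connected_components matches a union-find oracle on random graphs", {
  g0 <- make_graph(5, c())
  expect_length(connected_components(g0), 5)
  gp <- make_graph(3, c(1, 2, 2, 3))
  expect_equal(connected_components(gp), list(1:3))

  withr::with_seed(15, {
    n <- 50
    pairs <- t(combn(n, 2))
    pairs <- pairs[runif(nrow(pairs)) < 0.02, , drop = FALSE]
    g <- make_graph(n, t(pairs))
    comps <- connected_components(g)
    # oracle: plain union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pairs))) {
      ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    roots <- vapply(seq_len(n), find, 1L)
    expect_equal(partition_signature(unlist(Map(rep, seq_along(comps),
                                                lengths(comps)))[order(unlist(comps))],
                                     seq_len(n)),
                 partition_signature(roots, seq_len(n)))
    # disjoint cover, sorted by size
    expect_setequal(unlist(comps), seq_len(n))
    expect_true(all(diff(lengths(comps)) <= 0))
  })
})

test_that("partition_modularity reproduces hand-computed values", {
  two_tri <- make_graph(6, c(1, 2, 1, 3, 2, 3, 4, 5, 4, 6, 5, 6))
  expect_equal(partition_modularity(two_tri, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(partition_modularity(two_tri, rep(1, 6)), 0)
  tri <- make_graph(3, c(1, 2, 1, 3, 2, 3))
  expect_equal(partition_modularity(tri, 1:3), -1 / 3)
  expect_error(partition_modularity(make_graph(3, c()), 1:3), "edgeless")
  expect_error(partition_modularity(tri, 1:2), "cover")
})

test_that("fast-greedy matches exhaustive search on small bridged-clique graphs", {
  skip_if_not_installed("igraph")
  clique_edges <- function(nodes) t(combn(nodes, 2))
  cases <- list(
    rbind(clique_edges(1:3), clique_edges(4:6), c(3, 4)),
    rbind(clique_edges(1:4), clique_edges(5:8), c(4, 5)),
    rbind(clique_edges(1:5), clique_edges(6:10), c(5, 6)),
    rbind(clique_edges(1:3), clique_edges(4:7), c(1, 7)),
    clique_edges(1:4))                           # K4 -> one community
  for (e in cases) {
    n <- max(e)
    g <- make_graph(n, t(e))
    got <- fast_greedy_communities(g)
    best <- -Inf
    for (p in all_partitions(n))
      best <- max(best, partition_modularity(g, p))
    expect_equal(got$Q, best, tolerance = 1e-12)
    # cross-check the Q value itself with igraph on the same assignment
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    expect_equal(igraph::modularity(ig, got$assignment[seq_len(n)]), got$Q,
                 tolerance = 1e-12)
  }
  # two bridged triangles: the triangles, Q = 2*(3/7 - (7/14)^2)
  gb <- make_graph(6, c(1, 2, 1, 3, 2, 3, 4, 5, 4, 6, 5, 6, 3, 4))
  pb <- fast_greedy_communities(gb)
  expect_equal(pb$Q, 2 * (3 / 7 - (7 / 14)^2))
  expect_equal(length(unique(pb$assignment)), 2)
})

test_that("greedy communities handle disjoint components and edgeless graphs", {
  two_cliques <- rbind(t(combn(1:5, 2)), t(combn(6:10, 2)))
  g <- make_graph(10, t(two_cliques))
  p <- fast_greedy_communities(g)
  expect_equal(length(unique(p$assignment)), 2)
  expect_equal(p$Q, 0.5)
  expect_warning(p0 <- fast_greedy_communities(make_graph(4, c())), "edgeless")
  expect_equal(p0$Q, 0)
  # never below the all-in-one partition when edges exist
  expect_gte(p$Q, 0)
})

test_that("representatives take the most abundant member with lexicographic ties", {
  g <- make_graph(3, c(1, 2, 1, 3), counts = c(4585181, 12, 12))
  g$nodes$sequence <- c("TTT", "CCC", "AAA")
  tab <- select_representatives(g, rep(1, 3))
  expect_equal(tab$candidate_id, "n01")          # most abundant wins
  expect_equal(tab$L1, 4585181 + 24)             # community counts summed
  g2 <- make_graph(2, c(1, 2), counts = c(5, 5))
  g2$nodes$sequence <- c("TTT", "AAA")
  expect_equal(select_representatives(g2, c(1, 1))$sequence, "AAA")
})

test_that("conservation requires an exact hit in a species set", {
  withr::with_seed(16, {
    cand <- random_dna(22)
    other <- random_dna(22)
    tab <- candidate_table(c("a", "b"), c(cand, other),
                           c("unassigned", "unassigned"), c("c1", "c2"),
                           matrix(c(500, 500), ncol = 1,
                                  dimnames = list(NULL, "L1")))
    mid <- if (substr(other, 11, 11) == "A") "C" else "A"   # internal mismatch
    mm <- paste0(substr(other, 1, 10), mid, substr(other, 12, 22))
    sets <- list(`species:Lmi` = reference_set("species:Lmi", "s1",
                                               paste0(random_dna(50), cand)),
                 `species:Bmo` = reference_set("species:Bmo", "s2", mm))
    out <- classify_conservation(tab, sets)
    expect_equal(out$status, c("conserved_candidate", "specific_candidate"))
    expect_equal(out$species, c("species:Lmi", ""))
    # empty species sets -> all specific
    empty <- list(`species:X` = reference_set("species:X", character(),
                                              character()))
    expect_true(all(classify_conservation(tab, empty)$status ==
                      "specific_candidate"))
  })
})
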