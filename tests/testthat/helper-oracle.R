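# Independent brute-force oracles. These deliberately avoid the package's
# counting path (adjacency-matrix lookups into the catalog index): pair states
# are re-derived by scanning the induced edge list of every node triple, and
# matching is by explicit edge-set comparison / igraph isomorphism.

# explicit rank-labelled edge set ("lo hi" strings) for each catalog entry
oracle_edge_sets <- function() {
  cat54 <- build_catalog()
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  lapply(seq_len(nrow(cat54)), function(i) {
    sts <- c(cat54$s_bm[i], cat54$s_bt[i], cat54$s_mt[i])
    edges <- character(0)
    for (k in 1:3) {
      lo <- pairs[[k]][1]; hi <- pairs[[k]][2]
      if (sts[k] %in% c("up", "bidir")) edges <- c(edges, paste(lo, hi))
      if (sts[k] %in% c("down", "bidir")) edges <- c(edges, paste(hi, lo))
    }
    sort(edges)
  })
}

# ordered spectrum by exhaustive induced-subgraph matching
oracle_spectrum <- function(net) {
  rk <- stats::setNames(net$nodes$rank, net$nodes$node)
  ef <- unname(rk[net$edges$from])
  et <- unname(rk[net$edges$to])
  keep <- ef != et
  ef <- ef[keep]; et <- et[keep]
  sets <- oracle_edge_sets()
  eta <- integer(54)
  n <- nrow(net$nodes)
  if (n < 3) return(eta)
  for (combo in utils::combn(n, 3, simplify = FALSE)) {
    sel <- ef %in% combo & et %in% combo
    key <- sort(paste(match(ef[sel], combo), match(et[sel], combo)))
    hit <- which(vapply(sets, identical, logical(1), y = key))
    if (length(hit) == 1) eta[hit] <- eta[hit] + 1L
  }
  eta
}

# igraph digraph for one catalog row (vertices 1..3 always present)
oracle_igraph <- function(row) {
  sets <- strsplit(oracle_edge_sets()[[row]], " ")
  el <- do.call(rbind, lapply(sets, as.integer))
  igraph::graph_from_edgelist(el, directed = TRUE) |>
    (\(g) if (igraph::vcount(g) < 3) igraph::add_vertices(g, 3 - igraph::vcount(g)) else g)()
}

# unordered census: counts of connected induced 3-node subgraphs per class_id,
# by igraph weak-connectivity + directed isomorphism against one reference
# digraph per class
oracle_unordered_census <- function(net) {
  cat54 <- build_catalog()
  class_rows <- vapply(split(seq_len(54), cat54$class_id), `[`, integer(1), 1)
  refs <- lapply(class_rows, oracle_igraph)

  rk <- stats::setNames(net$nodes$rank, net$nodes$node)
  ef <- unname(rk[net$edges$from]); et <- unname(rk[net$edges$to])
  keep <- ef != et
  g <- igraph::graph_from_edgelist(cbind(ef, et)[keep, , drop = FALSE],
                                   directed = TRUE)
  n <- nrow(net$nodes)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))

  counts <- stats::setNames(integer(length(refs)), names(class_rows))
  for (combo in utils::combn(n, 3, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(g, combo)
    if (!igraph::is_connected(sub, mode = "weak")) next
    hit <- which(vapply(refs, function(r) igraph::isomorphic(sub, r),
                        logical(1)))
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# collapse a 54-vector of counts to the 13 classes (catalog row order)
collapse_eta <- function(eta) {
  as.numeric(rowsum(eta, build_catalog()$class_id))
}

expect_spectrum_equals_oracle <- function(net) {
  sp <- count_spectrum(net)
  expect_equal(sp$eta, as.numeric(oracle_spectrum(net)))
}
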