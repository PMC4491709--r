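#' Construct a directed ordered network
#'
#' An ordered network is a directed graph whose nodes form a strict total
#' order, e.g. species in a food web ordered by adult body mass. Edges follow
#' the energy-flow convention: an edge from A to B means B eats A, so an
#' "upward" link points from a lower-rank (smaller) node to a higher-rank
#' (larger) one.
#'
#' Ranks are assigned by ascending `niche_value` when the node table supplies
#' one; ties are broken by node-table order (with a warning, since the theory
#' assumes a strict order). Without niche values, node-table order itself
#' defines the ranks. Duplicate edges are collapsed with a warning.
#' Self-loops (cannibalism) are kept on the edge list but never participate
#' in 3-node substructures.
#'
#' @param edges Data frame whose first two columns are edge source and target
#'   (node ids, coerced to character).
#' @param nodes Optional: a character vector of node ids, or a data frame
#'   whose first column is the node id and whose second column (if present) is
#'   a numeric niche value (e.g. body mass). Defaults to the nodes in order of
#'   first appearance in `edges`. Every edge endpoint must appear.
#' @return An object of class `ordered_network`: a list with `nodes` (tibble:
#'   `node`, `rank`, `niche_value`) and `edges` (tibble: `from`, `to`).
#' @examples
#' net <- ordered_network(
#'   data.frame(from = c("a", "b"), to = c("b", "c")),
#'   data.frame(node = c("a", "b", "c"), mass = c(1, 10, 100))
#' )
#' net
#' @export
ordered_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("`edges` needs at least two columns (from, to)")
  ed <- tibble::tibble(from = as.character(edges[[1]]),
                       to = as.character(edges[[2]]))
  if (anyNA(ed$from) || anyNA(ed$to)) stop("edge endpoints must not be NA")

  dup <- duplicated(paste(ed$from, ed$to, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed")
    ed <- ed[!dup, ]
  }

  niche <- NULL
  if (is.null(nodes)) {
    ids <- unique(c(rbind(ed$from, ed$to)))
  } else if (is.data.frame(nodes)) {
    ids <- as.character(nodes[[1]])
    if (ncol(nodes) >= 2) {
      niche <- as.numeric(nodes[[2]])
      if (anyNA(niche)) {
        stop("unparseable niche value for node(s): ",
             paste(ids[is.na(niche)], collapse = ", "))
      }
    }
  } else {
    ids <- as.character(nodes)
  }
  if (anyDuplicated(ids)) stop("duplicate node id(s) in node table")

  missing <- setdiff(unique(c(ed$from, ed$to)), ids)
  if (length(missing) > 0) {
    stop("edge endpoint(s) not in node table: ",
         paste(missing, collapse = ", "))
  }

  if (!is.null(niche)) {
    if (anyDuplicated(niche)) {
      warning("ties in niche value broken by node-table order")
    }
    ord <- order(niche) # stable: ties keep input order
  } else {
    ord <- seq_along(ids)
  }
  node_tbl <- tibble::tibble(
    node = ids[ord],
    rank = seq_along(ids),
    niche_value = if (is.null(niche)) NA_real_ else niche[ord]
  )

  structure(
    list(nodes = node_tbl, edges = ed),
    class = "ordered_network"
  )
}

#' @export
print.ordered_network <- function(x, ...) {
  n_self <- sum(x$edges$from == x$edges$to)
  cat("<ordered_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges", if (n_self > 0) paste0(" (", n_self, " self-loops)"),
      "\n", sep = "")
  ranked <- !all(is.na(x$nodes$niche_value))
  cat("  ranks from ", if (ranked) "ascending niche value" else "node order",
      "\n", sep = "")
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)

n_self_loops <- function(net) sum(net$edges$from == net$edges$to)

# logical adjacency matrix indexed by rank (1..N), self-loops dropped
rank_adjacency <- function(net) {
  n <- n_nodes(net)
  a <- matrix(FALSE, n, n)
  fr <- net$nodes$rank[match(net$edges$from, net$nodes$node)]
  to <- net$nodes$rank[match(net$edges$to, net$nodes$node)]
  keep <- fr != to
  a[cbind(fr[keep], to[keep])] <- TRUE
  a
}

#' Permute the ranks of an ordered network
#'
#' Keeps the directed topology fixed and reassigns node ranks by a
#' permutation; the mechanism behind the rank-reordering null model.
#'
#' @param net An [ordered_network()].
#' @param perm Integer permutation of `1:N`; node with current rank `r` gets
#'   new rank `perm[r]`.
#' @return A new `ordered_network` (niche values are dropped, since the
#'   permuted order no longer derives from them).
#' @export
permute_ranks <- function(net, perm) {
  n <- n_nodes(net)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  new_nodes <- net$nodes
  new_nodes$rank <- perm[net$nodes$rank]
  new_nodes$niche_value <- NA_real_
  new_nodes <- new_nodes[order(new_nodes$rank), ]
  structure(list(nodes = new_nodes, edges = net$edges),
            class = "ordered_network")
}
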