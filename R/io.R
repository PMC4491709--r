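#' Read a directed ordered network from delimited files
#'
#' Reads an edge list (two columns: source, target) and an optional node table
#' (node id, optional numeric niche value such as average adult body mass).
#' Lines starting with `#` are comments. Ranks are assigned by ascending niche
#' value (ties broken by file order, with a warning); without a node table,
#' ranks follow first appearance in the edge list.
#'
#' Edge direction follows the energy-flow convention used throughout: an edge
#' from A to B means B eats A. Files recorded the other way around
#' (predator -> prey) can be flipped on read with `direction = "eats"`.
#'
#' @param edge_path Path to the edge list.
#' @param node_path Optional path to the node table.
#' @param delim Field delimiter (default tab).
#' @param direction `"energy"` (prey -> predator, kept as read) or `"eats"`
#'   (predator -> prey in the file; reversed on read).
#' @param col_names Do the files have a header line? Default `TRUE`
#'   (files written by [write_ordered_network()] do).
#' @return An [ordered_network()].
#' @export
read_ordered_network <- function(edge_path, node_path = NULL, delim = "\t",
                                 direction = c("energy", "eats"),
                                 col_names = TRUE) {
  direction <- match.arg(direction)
  edges <- readr::read_delim(edge_path, delim = delim, comment = "#",
                             col_names = col_names,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  if (nrow(edges) == 0) stop("edge file is empty: ", edge_path)
  if (direction == "eats") edges <- edges[, c(2, 1)]

  nodes <- NULL
  if (!is.null(node_path)) {
    nodes <- readr::read_delim(node_path, delim = delim, comment = "#",
                               col_names = col_names,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
    if (nrow(nodes) == 0) stop("node file is empty: ", node_path)
    if (ncol(nodes) >= 2) {
      niche <- suppressWarnings(as.numeric(nodes[[2]]))
      if (anyNA(niche)) {
        stop("unparseable niche value for node(s): ",
             paste(nodes[[1]][is.na(niche)], collapse = ", "))
      }
      nodes <- data.frame(node = nodes[[1]], niche_value = niche)
    } else {
      nodes <- nodes[[1]]
    }
  }
  ordered_network(edges, nodes)
}

#' Write a directed ordered network to delimited files
#'
#' Writes the edge list (energy-flow convention) and a node table in rank
#' order, so that reading the files back reproduces nodes, ranks and edges
#' exactly. The niche column is included only when niche values are present.
#'
#' @param net An [ordered_network()].
#' @param edge_path,node_path Output paths (node table skipped if
#'   `node_path` is `NULL`).
#' @param delim Field delimiter.
#' @return `edge_path`, invisibly.
#' @export
write_ordered_network <- function(net, edge_path, node_path = NULL,
                                  delim = "\t") {
  stopifnot(inherits(net, "ordered_network"))
  readr::write_delim(net$edges, edge_path, delim = delim)
  if (!is.null(node_path)) {
    tbl <- net$nodes[order(net$nodes$rank), c("node", "niche_value")]
    if (all(is.na(tbl$niche_value))) tbl <- tbl["node"]
    readr::write_delim(tbl, node_path, delim = delim)
  }
  invisible(edge_path)
}

#' Built-in toy ordered networks
#'
#' Deterministic small fixtures for examples and testing. `chain3` is the
#' upward chain a -> b -> c; `fan_in3` has both lower nodes feeding the top
#' node; `fan_out3` has the bottom node feeding both others; `triangle3` is
#' the transitive (omnivory) triangle a -> b -> c plus a -> c. `random6` and
#' `random10` are draws from the ordered random model (6 nodes at
#' p_up = 0.4, p_down = 0.15; 10 nodes at p_up = 0.35, p_down = 0.1),
#' deterministic given `seed`.
#'
#' @param name One of `"chain3"`, `"fan_in3"`, `"fan_out3"`, `"triangle3"`,
#'   `"random6"`, `"random10"`.
#' @param seed Seed for the random fixtures (default 1).
#' @return An [ordered_network()].
#' @export
make_fixture <- function(name, seed = 1) {
  abc <- c("a", "b", "c")
  ed <- function(from, to) data.frame(from = from, to = to)
  switch(name,
    chain3 = ordered_network(ed(c("a", "b"), c("b", "c")), abc),
    fan_in3 = ordered_network(ed(c("a", "b"), c("c", "c")), abc),
    fan_out3 = ordered_network(ed(c("a", "a"), c("b", "c")), abc),
    triangle3 = ordered_network(ed(c("a", "b", "a"), c("b", "c", "c")), abc),
    random6 = generate_random_network(6, 0.4, 0.15, seed = seed),
    random10 = generate_random_network(10, 0.35, 0.1, seed = seed),
    stop("unknown fixture: ", name)
  )
}
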