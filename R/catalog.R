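#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## Pair states between two rank-ordered nodes (lower, higher):
##   none  - no link
##   down  - link from the higher-rank node to the lower-rank node
##   up    - link from the lower-rank node to the higher-rank node
##   bidir - both links present
PAIR_STATES <- c("none", "down", "up", "bidir")

## Pairs of a rank-ordered triple (bottom < middle < top), in the fixed
## convention used throughout: (bottom,middle), (bottom,top), (middle,top).
PAIR_NAMES <- c("bm", "bt", "mt")

# integer encoding of a pair state, 0..3 in PAIR_STATES order
state_int <- function(state) match(state, PAIR_STATES) - 1L

# code index in 1..64 from the three pair-state integers
code_index_from_ints <- function(s_bm, s_bt, s_mt) {
  1L + s_bm + 4L * s_bt + 16L * s_mt
}

# 3x3 logical adjacency of the rank-labelled triple (1=bottom,2=middle,3=top)
code_adjacency <- function(s_bm, s_bt, s_mt) {
  a <- matrix(FALSE, 3L, 3L)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  states <- c(s_bm, s_bt, s_mt)
  for (k in 1:3) {
    lo <- pairs[[k]][1]; hi <- pairs[[k]][2]
    if (states[k] == 2L || states[k] == 3L) a[lo, hi] <- TRUE # up
    if (states[k] == 1L || states[k] == 3L) a[hi, lo] <- TRUE # down
  }
  a
}

# pack the six off-diagonal adjacency bits into one integer (row-major order)
pack_adjacency <- function(a) {
  bits <- c(a[1, 2], a[1, 3], a[2, 1], a[2, 3], a[3, 1], a[3, 2])
  as.integer(sum(as.integer(bits) * 2L^(0:5)))
}

PERMS3 <- list(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)

# canonical form of the unordered digraph: minimum packed adjacency over all
# node permutations; also returns the automorphism count
canonical_digraph <- function(a) {
  packed <- vapply(PERMS3, function(p) pack_adjacency(a[p, p]), integer(1))
  list(canon = min(packed),
       n_aut = sum(vapply(PERMS3, function(p) identical(a[p, p], a),
                          logical(1))))
}

#' Enumerate all ordered 3-node configurations
#'
#' Three rank-ordered nodes (bottom < middle < top) define three node pairs,
#' each in one of four pair states (`none`, `down`, `up`, `bidir`), giving
#' \eqn{4^3 = 64} configurations. The pair order is fixed as
#' (bottom,middle), (bottom,top), (middle,top).
#'
#' @return A tibble with 64 rows and columns `code_index` (1..64, the
#'   deterministic enumeration order), `s_bm`, `s_bt`, `s_mt` (pair states),
#'   `code` (the states pasted with `-`), and `connected` (see
#'   [is_connected_code()]).
#' @examples
#' codes <- enumerate_codes()
#' nrow(codes)          # 64
#' sum(codes$connected) # 54
#' @export
enumerate_codes <- function() {
  grid <- expand.grid(s_bm = 0:3, s_bt = 0:3, s_mt = 0:3,
                      KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    code_index = code_index_from_ints(grid$s_bm, grid$s_bt, grid$s_mt),
    s_bm = PAIR_STATES[grid$s_bm + 1L],
    s_bt = PAIR_STATES[grid$s_bt + 1L],
    s_mt = PAIR_STATES[grid$s_mt + 1L],
    code = paste(PAIR_STATES[grid$s_bm + 1L],
                 PAIR_STATES[grid$s_bt + 1L],
                 PAIR_STATES[grid$s_mt + 1L], sep = "-"),
    connected = is_connected_code(PAIR_STATES[grid$s_bm + 1L],
                                  PAIR_STATES[grid$s_bt + 1L],
                                  PAIR_STATES[grid$s_mt + 1L])
  )
}

#' Is an ordered 3-node configuration a connected substructure?
#'
#' A configuration is a connected substructure when every one of the three
#' nodes has at least one incident link (in either direction). Exactly 10 of
#' the 64 configurations contain an isolated node and fail this test.
#'
#' @param s_bm,s_bt,s_mt Pair states (`"none"`, `"down"`, `"up"`, `"bidir"`)
#'   for the (bottom,middle), (bottom,top) and (middle,top) pairs. Vectorised.
#' @return Logical vector.
#' @examples
#' is_connected_code("none", "none", "none") # FALSE
#' is_connected_code("up", "none", "up")     # TRUE (upward chain)
#' @export
is_connected_code <- function(s_bm, s_bt, s_mt) {
  ok <- function(s) s != "none"
  # bottom touches pairs bm, bt; middle bm, mt; top bt, mt
  (ok(s_bm) | ok(s_bt)) & (ok(s_bm) | ok(s_mt)) & (ok(s_bt) | ok(s_mt))
}

catalog_cache <- new.env(parent = emptyenv())

#' Catalog of the 54 connected ordered 3-node substructures
#'
#' Enumerates all 64 ordered 3-node configurations, drops the 10 that contain
#' an isolated node, and labels the remaining 54 connected substructures. Each
#' substructure gets a class ID `q` in 1..13 (its unordered directed-graph
#' isomorphism class, found by minimising the packed adjacency matrix over all
#' node permutations) and a member ID `s` numbering the ordered members within
#' the class.
#'
#' Class IDs are assigned by sorting the 13 classes by link count `links` and
#' then by canonical adjacency form; member IDs by lexicographic order of the
#' pair-state triple within each class (with `none < down < up < bidir`). This
#' numbering is deterministic but is this package's own convention, so the
#' three substructures commonly referenced by their shape carry stable
#' aliases: `fan_in_up` (both lower nodes link up into the top node),
#' `up_chain` (bottom to middle to top), and `fan_out_up` (bottom links up to
#' both others).
#'
#' @return A tibble with 54 rows, ordered by (`class_id`, `member_id`), with
#'   columns `class_id`, `member_id`, `code`, `s_bm`, `s_bt`, `s_mt`,
#'   `links` (number of directed links, 2..6; a bidirectional pair counts 2),
#'   `n_up`, `n_down` (upward / downward link counts, `links = n_up + n_down`),
#'   `code_index`, `canon` (canonical form of the unordered digraph) and
#'   `alias`.
#' @examples
#' cat54 <- build_catalog()
#' nrow(cat54)                     # 54
#' dplyr::n_distinct(cat54$class_id) # 13
#' @export
build_catalog <- function() {
  if (!is.null(catalog_cache$catalog)) return(catalog_cache$catalog)
  codes <- enumerate_codes()
  con <- codes[codes$connected, ]

  ints <- cbind(state_int(con$s_bm), state_int(con$s_bt), state_int(con$s_mt))
  canon <- integer(nrow(con))
  links <- integer(nrow(con))
  n_up <- integer(nrow(con))
  n_down <- integer(nrow(con))
  for (i in seq_len(nrow(con))) {
    a <- code_adjacency(ints[i, 1], ints[i, 2], ints[i, 3])
    canon[i] <- canonical_digraph(a)$canon
    n_up[i] <- sum(ints[i, ] == 2L) + sum(ints[i, ] == 3L)
    n_down[i] <- sum(ints[i, ] == 1L) + sum(ints[i, ] == 3L)
    links[i] <- n_up[i] + n_down[i]
  }

  # order the 13 classes by (link count, canonical form); links is constant
  # within a class because isomorphism preserves the number of directed links
  cls <- unique(data.frame(canon = canon, links = links))
  cls <- cls[order(cls$links, cls$canon), ]
  cls$class_id <- seq_len(nrow(cls))

  out <- tibble::tibble(
    class_id = cls$class_id[match(canon, cls$canon)],
    code = con$code,
    s_bm = con$s_bm, s_bt = con$s_bt, s_mt = con$s_mt,
    links = links, n_up = n_up, n_down = n_down,
    code_index = con$code_index, canon = canon
  )
  # member_id: lexicographic order of (s_bm, s_bt, s_mt) within class
  out <- out[order(out$class_id, ints[, 1], ints[, 2], ints[, 3]), ]
  out$member_id <- stats::ave(seq_len(nrow(out)), out$class_id,
                              FUN = seq_along)

  out$alias <- NA_character_
  out$alias[out$code == "none-up-up"] <- "fan_in_up"
  out$alias[out$code == "up-none-up"] <- "up_chain"
  out$alias[out$code == "up-up-none"] <- "fan_out_up"

  out <- out[, c("class_id", "member_id", "code", "s_bm", "s_bt", "s_mt",
                 "links", "n_up", "n_down", "code_index", "canon", "alias")]
  catalog_cache$catalog <- out
  out
}

# integer vector of length 64: code_index -> catalog row (0 if not connected)
catalog_lookup <- function() {
  if (is.null(catalog_cache$lookup)) {
    cat54 <- build_catalog()
    lk <- integer(64)
    lk[cat54$code_index] <- seq_len(nrow(cat54))
    catalog_cache$lookup <- lk
  }
  catalog_cache$lookup
}

#' Classify one ordered 3-node configuration
#'
#' Looks up the catalog entry for a pair-state triple. The configuration must
#' be connected; configurations with an isolated node are not substructures
#' and raise an error.
#'
#' @inheritParams is_connected_code
#' @return A one-row tibble, the matching [build_catalog()] entry.
#' @examples
#' classify_triple("up", "none", "up")$alias # "up_chain"
#' @export
classify_triple <- function(s_bm, s_bt, s_mt) {
  stopifnot(length(s_bm) == 1, length(s_bt) == 1, length(s_mt) == 1)
  states <- c(s_bm, s_bt, s_mt)
  if (!all(states %in% PAIR_STATES)) {
    stop("pair states must be one of: ", paste(PAIR_STATES, collapse = ", "))
  }
  if (!is_connected_code(s_bm, s_bt, s_mt)) {
    stop("configuration (", paste(states, collapse = ", "),
         ") contains an isolated node and is not a connected substructure")
  }
  idx <- code_index_from_ints(state_int(s_bm), state_int(s_bt), state_int(s_mt))
  build_catalog()[catalog_lookup()[idx], ]
}

#' Write the substructure catalog to a file
#'
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`. The JSON variant wraps the
#'   rows in an object with a `schema_version` field.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  cat54 <- build_catalog()
  if (format == "tsv") {
    readr::write_tsv(cat54, path)
  } else {
    jsonlite::write_json(
      list(schema_version = 1L, catalog = cat54),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
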