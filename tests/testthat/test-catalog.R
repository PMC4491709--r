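test_that("enumeration covers all 64 pair-state triples exactly once", {
  codes <- enumerate_codes()
  expect_equal(nrow(codes), 64)
  expect_equal(anyDuplicated(codes$code), 0)
  expect_equal(sum(codes$code == "none-none-none"), 1)
  expect_equal(sum(codes$code == "bidir-bidir-bidir"), 1)
  expect_setequal(codes$code_index, 1:64)
})

test_that("isolated-node filter keeps 54 of the 64 configurations", {
  codes <- enumerate_codes()
  expect_equal(sum(codes$connected), 54)
  expect_equal(sum(!codes$connected), 10)
  expect_false(is_connected_code("none", "none", "none"))
  expect_true(is_connected_code("up", "none", "up"))
  # single-pair configurations leave a node isolated
  expect_false(is_connected_code("bidir", "none", "none"))
  expect_false(is_connected_code("none", "down", "none"))
})

test_that("catalog classes agree with brute-force igraph isomorphism grouping", {
  cat54 <- build_catalog()
  graphs <- lapply(seq_len(54), oracle_igraph)
  # independent grouping: pairwise directed isomorphism
  group <- rep(NA_integer_, 54)
  next_id <- 0L
  for (i in seq_len(54)) {
    if (!is.na(group[i])) next
    next_id <- next_id + 1L
    group[i] <- next_id
    for (j in seq_len(54)) {
      if (j > i && is.na(group[j]) &&
          igraph::isomorphic(graphs[[i]], graphs[[j]])) {
        group[j] <- next_id
      }
    }
  }
  expect_equal(max(group), 13)
  # same partition as class_id (up to relabelling)
  expect_equal(length(unique(paste(group, cat54$class_id))), 13)
  sizes <- as.integer(table(cat54$class_id))
  expect_equal(sum(sizes), 54)
  expect_true(all(sizes >= 1 & sizes <= 6))
})

test_that("class size times automorphism group order equals 6 for every class", {
  cat54 <- build_catalog()
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # independent adjacency reconstruction from the oracle edge sets
  adj_of <- function(row) {
    a <- matrix(FALSE, 3, 3)
    for (e in strsplit(oracle_edge_sets()[[row]], " ")) {
      a[as.integer(e[1]), as.integer(e[2])] <- TRUE
    }
    a
  }
  for (q in unique(cat54$class_id)) {
    rows <- which(cat54$class_id == q)
    a <- adj_of(rows[1])
    n_aut <- sum(vapply(perms, function(p) identical(a[p, p], a), logical(1)))
    expect_equal(length(rows) * n_aut, 6)
  }
})

test_that("classify_triple is a left inverse of reading a catalog code", {
  cat54 <- build_catalog()
  for (i in seq_len(nrow(cat54))) {
    entry <- classify_triple(cat54$s_bm[i], cat54$s_bt[i], cat54$s_mt[i])
    expect_equal(entry$class_id, cat54$class_id[i])
    expect_equal(entry$member_id, cat54$member_id[i])
  }
  expect_error(classify_triple("none", "none", "up"), "isolated")
  expect_error(classify_triple("up", "nope", "up"), "pair states")
})

test_that("link counts decompose into up and down links, bidir counting twice", {
  cat54 <- build_catalog()
  expect_true(all(cat54$links == cat54$n_up + cat54$n_down))
  expect_true(all(cat54$links >= 2 & cat54$links <= 6))
  all_bidir <- cat54[cat54$code == "bidir-bidir-bidir", ]
  expect_equal(all_bidir$links, 6)
})

test_that("the three named substructures have two upward links and no other", {
  cat54 <- build_catalog()
  named <- cat54[!is.na(cat54$alias), ]
  expect_setequal(named$alias, c("fan_in_up", "up_chain", "fan_out_up"))
  expect_true(all(named$n_up == 2 & named$n_down == 0))
  expect_equal(cat54$code[match("up_chain", cat54$alias)], "up-none-up")
  expect_equal(cat54$code[match("fan_in_up", cat54$alias)], "none-up-up")
  expect_equal(cat54$code[match("fan_out_up", cat54$alias)], "up-up-none")
})

test_that("catalog export round-trips through TSV and is schema-versioned JSON", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_catalog(tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(build_catalog()))
  write_catalog(js, format = "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$schema_version, 1L)
  expect_equal(length(parsed$catalog), 54)
})
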