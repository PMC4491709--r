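check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("`", name, "` must be a single probability in [0, 1]")
  }
}

#' Pair-configuration probabilities of the ordered random model
#'
#' In the directed ordered random network, each rank-ordered node pair
#' independently receives an upward link with probability `p_up` and a
#' downward link with probability `p_down`. The four pair states then occur
#' with probabilities
#' \deqn{P(none) = (1-p_{up})(1-p_{down}),\quad P(down) = p_{down}(1-p_{up}),}
#' \deqn{P(up) = p_{up}(1-p_{down}),\quad P(bidir) = p_{up}\,p_{down}.}
#'
#' @param p_up,p_down Connection probabilities in \[0, 1\].
#' @return Named numeric vector `(none, down, up, bidir)`, summing to 1.
#' @export
pair_config_probs <- function(p_up, p_down) {
  check_prob(p_up, "p_up"); check_prob(p_down, "p_down")
  c(none = (1 - p_up) * (1 - p_down),
    down = p_down * (1 - p_up),
    up = p_up * (1 - p_down),
    bidir = p_up * p_down)
}

#' Appearance probability of an ordered 3-node configuration
#'
#' The probability that a random triple of the ordered random model shows a
#' given configuration: the product of the three pair-configuration
#' probabilities (six multipliers, one `p` or `1-p` factor per direction per
#' pair). With `p_up = p_down = p` this reduces to \eqn{p^l (1-p)^{6-l}}
#' where `l` is the number of directed links.
#'
#' @param s_bm,s_bt,s_mt Pair states, vectorised (recycled to common length).
#' @inheritParams pair_config_probs
#' @return Numeric vector of probabilities.
#' @examples
#' substructure_prob("none", "none", "none", 0.1, 0.1) # (1 - 0.1)^6
#' @export
substructure_prob <- function(s_bm, s_bt, s_mt, p_up, p_down) {
  pp <- pair_config_probs(p_up, p_down)
  stopifnot(all(c(s_bm, s_bt, s_mt) %in% PAIR_STATES))
  pp[s_bm] * pp[s_bt] * pp[s_mt]
}

#' Analytic motif spectrum of the directed ordered random model
#'
#' Computes, for each of the 54 connected substructures, its appearance
#' probability \eqn{P_{(q,s)}} under the random model and the expected count
#' \eqn{\eta_{(q,s)} = \binom{N}{3} P_{(q,s)}} (the binomial coefficient is
#' the number of node triples).
#'
#' With symmetric probabilities the 54 values collapse to 5 levels (one per
#' link count \eqn{l = 2..6}); with generic asymmetric probabilities they form
#' 13 levels — the *statistical classes*, which differ from the 13
#' isomorphism classes.
#'
#' @param n Number of nodes (at least 3).
#' @inheritParams pair_config_probs
#' @return An `analytic_spectrum`: the catalog tibble plus columns `prob` and
#'   `expected`, with `n`, `p_up`, `p_down` attributes.
#' @export
analytic_spectrum <- function(n, p_up, p_down) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) stop("`n` must be >= 3")
  cat54 <- build_catalog()
  prob <- unname(substructure_prob(cat54$s_bm, cat54$s_bt, cat54$s_mt,
                                   p_up, p_down))
  out <- tibble::tibble(
    class_id = cat54$class_id, member_id = cat54$member_id,
    code = cat54$code, links = cat54$links,
    n_up = cat54$n_up, n_down = cat54$n_down,
    prob = prob, expected = choose(n, 3) * prob
  )
  structure(out, class = c("analytic_spectrum", class(out)),
            n = n, p_up = p_up, p_down = p_down)
}

#' Count distinct probability levels
#'
#' Groups a set of probabilities into distinct levels, treating values whose
#' relative difference is below `rtol` as equal. Products of identical factor
#' multisets can differ in the last ulp depending on evaluation order, so
#' exact comparison would overcount.
#'
#' @param probs Numeric vector.
#' @param rtol Relative tolerance for grouping (default `1e-12`).
#' @return Integer: the number of distinct levels.
#' @export
n_distinct_levels <- function(probs, rtol = 1e-12) {
  p <- sort(probs)
  if (length(p) == 0) return(0L)
  gaps <- diff(p) > rtol * pmax(abs(p[-length(p)]), abs(p[-1]))
  1L + sum(gaps)
}

#' Generate a directed ordered random network
#'
#' For each rank-ordered node pair j < i, independently adds the upward link
#' j -> i with probability `p_up` and the downward link i -> j with
#' probability `p_down`. Node ids are `"n1" .. "nN"` with rank equal to index.
#'
#' @param n Number of nodes.
#' @inheritParams pair_config_probs
#' @param seed Optional integer seed (the draw is made under a local RNG state
#'   so the caller's stream is untouched). With `seed = NULL` the current RNG
#'   stream is used.
#' @return An [ordered_network()].
#' @export
generate_random_network <- function(n, p_up, p_down, seed = NULL) {
  check_prob(p_up, "p_up"); check_prob(p_down, "p_down")
  stopifnot(n >= 1)
  draw <- function() {
    lo <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    hi <- sequence((n - 1L):1L, from = 2:n)
    up <- stats::runif(length(lo)) < p_up
    dn <- stats::runif(length(lo)) < p_down
    lo_id <- paste0("n", lo)
    hi_id <- paste0("n", hi)
    tibble::tibble(
      from = c(lo_id[up], hi_id[dn]),
      to = c(hi_id[up], lo_id[dn])
    )
  }
  edges <- if (n < 2) tibble::tibble(from = character(), to = character())
  else if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ordered_network(edges, nodes = paste0("n", seq_len(n)))
}

# shared ensemble machinery: `generate` is function(rep_seed) -> ordered_network
ensemble_of_networks <- function(generate, reps, seed, kind, params) {
  stopifnot(reps >= 1)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, reps))
  eta <- matrix(0, nrow = reps, ncol = 54L)
  connectance <- numeric(reps)
  triples_cache <- new.env(parent = emptyenv())
  for (k in seq_len(reps)) {
    net <- generate(rep_seeds[k])
    n <- n_nodes(net)
    key <- paste0("n", n)
    if (is.null(triples_cache[[key]])) triples_cache[[key]] <- rank_triples(n)
    eta[k, ] <- count_spectrum_adj(rank_adjacency(net), triples_cache[[key]])
    connectance[k] <- nrow(net$edges) / n^2
  }
  new_motif_ensemble(eta, kind, params, connectance)
}

new_motif_ensemble <- function(eta, kind, params, connectance = NULL) {
  cat54 <- build_catalog()
  reps <- nrow(eta)
  summary <- tibble::tibble(
    class_id = cat54$class_id, member_id = cat54$member_id,
    code = cat54$code,
    mean = colMeans(eta),
    sd = if (reps > 1) apply(eta, 2, stats::sd) else NA_real_,
    n_nonzero = colSums(eta > 0)
  )
  structure(
    list(summary = summary, eta = eta, reps = reps, kind = kind,
         params = params, connectance = connectance),
    class = "motif_ensemble"
  )
}

#' @export
print.motif_ensemble <- function(x, ...) {
  cat("<motif_ensemble> ", x$reps, " replicate(s) of kind '", x$kind, "'\n",
      sep = "")
  cat("  substructures observed at least once: ",
      sum(x$summary$n_nonzero > 0), "/54\n", sep = "")
  if (!is.null(x$connectance)) {
    cat("  mean realized connectance: ",
        format(mean(x$connectance), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Ensemble of directed ordered random networks
#'
#' Generates `reps` networks from the random model and counts each one's
#' ordered motif spectrum. Per-replicate sub-seeds are derived from `seed`,
#' so individual replicates are reproducible.
#'
#' @inheritParams generate_random_network
#' @param reps Number of realizations.
#' @param seed Integer master seed.
#' @return A `motif_ensemble`: per-replicate counts (`$eta`, reps x 54) plus a
#'   `$summary` tibble with per-entry `mean`, `sd` and `n_nonzero`.
#' @export
random_ensemble <- function(n, p_up, p_down, reps = 100, seed = 1) {
  check_prob(p_up, "p_up"); check_prob(p_down, "p_down")
  ensemble_of_networks(
    function(s) generate_random_network(n, p_up, p_down, seed = s),
    reps, seed, kind = "random_model",
    params = list(n = n, p_up = p_up, p_down = p_down, seed = seed)
  )
}
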