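#' Random-reordering null ensemble
#'
#' Builds the null ensemble that tests the role of the node order itself:
#' each replicate applies an independent uniform random permutation to the
#' node ranks while keeping the directed topology fixed, and the ordered motif
#' spectrum is recounted. Because the topology never changes, the collapsed
#' (unordered) spectrum of every replicate equals that of the original
#' network; only the distribution of counts across members within each
#' isomorphism class responds to the reordering.
#'
#' @param net An [ordered_network()].
#' @param n_perm Number of random permutations (ignored when `exhaustive`).
#' @param seed Integer master seed (ignored when `exhaustive`).
#' @param exhaustive If `TRUE`, enumerate all `N!` rank permutations instead
#'   of sampling; the resulting means are the exact permutation-null
#'   expectations. Only feasible for small networks (`N <= 8`).
#' @return A `motif_ensemble` (see [random_ensemble()]).
#' @export
reorder_null <- function(net, n_perm = 1000, seed = 1, exhaustive = FALSE) {
  stopifnot(inherits(net, "ordered_network"), n_perm >= 1)
  n <- n_nodes(net)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to 8 nodes (n! grows)")
    perms <- permutations_of(n)
    triples <- rank_triples(n)
    eta <- t(vapply(
      seq_len(nrow(perms)),
      function(k) as.numeric(count_spectrum_adj(
        rank_adjacency(permute_ranks(net, perms[k, ])), triples)),
      numeric(54)
    ))
    return(new_motif_ensemble(eta, "reorder_null_exhaustive",
                              params = list(n_perm = factorial(n))))
  }
  ensemble_of_networks(
    function(s) permute_ranks(net, withr::with_seed(s, sample.int(n))),
    n_perm, seed, kind = "reorder_null",
    params = list(n_perm = n_perm, seed = seed)
  )
}

# all permutations of 1..n as an n! x n matrix, recursively
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Z-score significance profile
#'
#' Standardizes the deviation of an observed motif spectrum from a null
#' ensemble, per substructure:
#' \deqn{Z_{(q,s)} = \frac{\eta_{(q,s)} - \bar\eta_{(q,s)}}{\sigma_{(q,s)}}}
#' where the mean and standard deviation are taken over the null ensemble
#' (sample standard deviation, n-1 denominator). Substructures absent from
#' the observed network enter with \eqn{\eta = 0}. Entries whose null
#' standard deviation is zero cannot be standardized; they are flagged
#' `degenerate` and get `z = NA` rather than a silent 0 or infinity. No
#' multiple-testing correction is applied to the profile; treat per-entry
#' magnitudes descriptively.
#'
#' @param observed A [count_spectrum()] result (or any data frame with
#'   `class_id`, `member_id`, `eta` over the 54 catalog entries).
#' @param null_mean Either a `motif_ensemble` (its summary supplies both
#'   moments) or a numeric vector of 54 null means in catalog order.
#' @param null_sd Numeric vector of 54 null standard deviations; ignored when
#'   `null_mean` is a `motif_ensemble`.
#' @return A `z_profile` tibble: `class_id`, `member_id`, `code`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `degenerate`.
#' @export
z_profile <- function(observed, null_mean, null_sd = NULL) {
  stopifnot(all(c("class_id", "member_id", "eta") %in% names(observed)))
  obs <- dplyr::arrange(tibble::as_tibble(observed),
                        .data$class_id, .data$member_id)
  if (nrow(obs) != 54) stop("`observed` must cover all 54 catalog entries")

  if (inherits(null_mean, "motif_ensemble")) {
    if (null_mean$reps < 2) {
      stop("null ensemble needs at least 2 replicates to estimate a sd")
    }
    null_sd <- null_mean$summary$sd
    null_mean <- null_mean$summary$mean
  }
  if (length(null_mean) != 54 || length(null_sd) != 54) {
    stop("`null_mean` and `null_sd` must have 54 entries in catalog order")
  }

  degenerate <- !(null_sd > 0) | is.na(null_sd)
  z <- ifelse(degenerate, NA_real_, (obs$eta - null_mean) / null_sd)
  out <- tibble::tibble(
    class_id = obs$class_id, member_id = obs$member_id,
    code = build_catalog()$code,
    observed = obs$eta, null_mean = null_mean, null_sd = null_sd,
    z = z, degenerate = degenerate
  )
  structure(out, class = c("z_profile", class(out)))
}

#' @export
`[.z_profile` <- function(x, ...) {
  out <- NextMethod()
  class(out) <- setdiff(class(out), "z_profile")
  out
}

#' @export
print.z_profile <- function(x, ...) {
  cat("<z_profile> ", sum(!x$degenerate), "/54 entries Z-scored (",
      sum(x$degenerate), " degenerate: null sd = 0)\n", sep = "")
  NextMethod()
}
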