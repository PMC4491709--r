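#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ordered network into its edge table
#'
#' @param x An [ordered_network()].
#' @param ... Unused.
#' @return A tibble with one row per edge: `from`, `to`, their ranks, and the
#'   link `direction` (`up`, `down` or `self`).
#' @method tidy ordered_network
#' @export
tidy.ordered_network <- function(x, ...) {
  fr_rank <- x$nodes$rank[match(x$edges$from, x$nodes$node)]
  to_rank <- x$nodes$rank[match(x$edges$to, x$nodes$node)]
  tibble::tibble(
    from = x$edges$from, to = x$edges$to,
    from_rank = fr_rank, to_rank = to_rank,
    direction = dplyr::case_when(fr_rank < to_rank ~ "up",
                                 fr_rank > to_rank ~ "down",
                                 TRUE ~ "self")
  )
}

#' @rdname tidy.ordered_network
#' @return For `glance()`: a one-row tibble with `n_nodes`, `n_edges`,
#'   `n_self_loops`, `connectance` (\eqn{L/N^2}, self-loops included) and the
#'   up/down link counts.
#' @method glance ordered_network
#' @export
glance.ordered_network <- function(x, ...) {
  ed <- tidy(x)
  tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_self_loops = sum(ed$direction == "self"),
    connectance = nrow(x$edges) / nrow(x$nodes)^2,
    n_up = sum(ed$direction == "up"),
    n_down = sum(ed$direction == "down")
  )
}

#' Tidiers for motif spectra, ensembles and Z-profiles
#'
#' `tidy()` returns the per-substructure table; `glance()` a one-row summary.
#'
#' @param x A `motif_spectrum`, `analytic_spectrum`, `motif_ensemble` or
#'   `z_profile`.
#' @param ... Unused.
#' @name spectrum-tidiers
NULL

#' @rdname spectrum-tidiers
#' @method tidy motif_spectrum
#' @export
tidy.motif_spectrum <- function(x, ...) tibble::as_tibble(unclass1(x))

#' @rdname spectrum-tidiers
#' @method glance motif_spectrum
#' @export
glance.motif_spectrum <- function(x, ...) {
  tibble::tibble(
    n_nodes = attr(x, "n_nodes"), n_edges = attr(x, "n_edges"),
    n_self_loops = attr(x, "n_self_loops"),
    n_triples_counted = sum(x$eta),
    n_substructures = sum(x$eta > 0)
  )
}

#' @rdname spectrum-tidiers
#' @method tidy analytic_spectrum
#' @export
tidy.analytic_spectrum <- function(x, ...) tibble::as_tibble(unclass1(x))

#' @rdname spectrum-tidiers
#' @method glance analytic_spectrum
#' @export
glance.analytic_spectrum <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"), p_up = attr(x, "p_up"), p_down = attr(x, "p_down"),
    n_levels = n_distinct_levels(x$prob),
    total_expected = sum(x$expected)
  )
}

#' @rdname spectrum-tidiers
#' @method tidy motif_ensemble
#' @export
tidy.motif_ensemble <- function(x, ...) x$summary

#' @rdname spectrum-tidiers
#' @method glance motif_ensemble
#' @export
glance.motif_ensemble <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, reps = x$reps,
    n_substructures_union = sum(x$summary$n_nonzero > 0),
    mean_connectance = if (is.null(x$connectance)) NA_real_ else
      mean(x$connectance)
  )
}

#' @rdname spectrum-tidiers
#' @method tidy z_profile
#' @export
tidy.z_profile <- function(x, ...) tibble::as_tibble(unclass1(x))

#' @rdname spectrum-tidiers
#' @method glance z_profile
#' @export
glance.z_profile <- function(x, ...) {
  zz <- x$z[!x$degenerate]
  top <- if (any(!x$degenerate)) x$code[!x$degenerate][which.max(abs(zz))] else
    NA_character_
  tibble::tibble(
    n_scored = sum(!x$degenerate), n_degenerate = sum(x$degenerate),
    max_abs_z = if (length(zz)) max(abs(zz)) else NA_real_,
    top_code = top
  )
}

# drop the package's S3 class but keep the tibble classes
unclass1 <- function(x) {
  class(x) <- setdiff(class(x), c("motif_spectrum", "analytic_spectrum",
                                  "z_profile"))
  attr(x, "n_nodes") <- NULL; attr(x, "n_edges") <- NULL
  attr(x, "n_self_loops") <- NULL; attr(x, "ordering") <- NULL
  attr(x, "n") <- NULL; attr(x, "p_up") <- NULL; attr(x, "p_down") <- NULL
  x
}
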