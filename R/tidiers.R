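# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DCA result into its inter-block pair table
#'
#' @param x A `dca_result`.
#' @param ... Unused.
#' @return Tibble with `col_a`, `col_b`, `di`, sorted by decreasing DI.
#' @export
tidy.dca_result <- function(x, ...) {
  dplyr::arrange(x$inter_pairs, dplyr::desc(.data$di))
}

#' One-row summary of a DCA result
#'
#' @param x A `dca_result`.
#' @param ... Unused.
#' @return Tibble: `n_rows`, `m_eff`, `n_cols`, `n_inter_pairs`,
#'   `max_inter_di`, `median_inter_di`.
#' @export
glance.dca_result <- function(x, ...) {
  tibble::tibble(
    n_rows = x$n_rows, m_eff = x$m_eff,
    n_cols = length(x$retained_cols),
    n_inter_pairs = nrow(x$inter_pairs),
    max_inter_di = if (nrow(x$inter_pairs)) max(x$inter_pairs$di) else
      NA_real_,
    median_inter_di = if (nrow(x$inter_pairs))
      stats::median(x$inter_pairs$di) else NA_real_)
}

#' Tidy a gene-content network into its edge list
#'
#' @param x A `content_network`.
#' @param ... Unused.
#' @return Tibble of edges with a `cluster` column per endpoint's cluster.
#' @export
tidy.content_network <- function(x, ...) {
  cluster_of <- stats::setNames(
    rep(seq_along(x$clusters), lengths(x$clusters)), unlist(x$clusters))
  dplyr::mutate(x$edges,
                cluster_from = unname(cluster_of[.data$from]),
                cluster_to = unname(cluster_of[.data$to]))
}

#' One-row summary of a gene-content network
#'
#' @param x A `content_network`.
#' @param ... Unused.
#' @return Tibble: `n_genomes`, `n_edges`, `n_clusters`,
#'   `universe_size`.
#' @export
glance.content_network <- function(x, ...) {
  tibble::tibble(n_genomes = length(x$nodes), n_edges = nrow(x$edges),
                 n_clusters = length(x$clusters),
                 universe_size = x$universe_size)
}
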