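#' Upper-tail hypergeometric probability
#'
#' `P(X >= k_hit)` for the number of annotated genes drawn when `n_set`
#' genes are sampled without replacement from a universe of `N` genes of
#' which `K` carry the term. Evaluated in log space via the hypergeometric
#' distribution function, inclusive of `k_hit` (the standard
#' overrepresentation convention).
#'
#' @param N Universe size.
#' @param K Annotated genes in the universe.
#' @param n_set Query-set size.
#' @param k_hit Annotated genes in the query set.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper <- function(N, K, n_set, k_hit) {
  if (K < 0 || K > N || n_set < 0 || n_set > N || k_hit < 0 ||
      k_hit > min(K, n_set)) {
    stop("hypergeometric bounds violated: need 0 <= k_hit <= min(K, n_set) <= N")
  }
  if (k_hit == 0) return(1)
  stats::phyper(k_hit - 1, K, N - K, n_set, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1, with input order
#' restored.
#'
#' @param p_values Vector of p-values in `(0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric overrepresentation analysis of a gene set
#'
#' Every term of the database with at least one hit in the query set is
#' tested with [hypergeom_upper()] against the supplied universe; q-values
#' are BH-adjusted across all tested terms of the category. For each term
#' the table reports the hit percentage `100 * k_hit / K` (how much of the
#' term's overall occurrence in the dataset falls inside the query set) and
#' the overrepresentation rate `(k_hit / n_set) / (K / N)` (observed versus
#' expected frequency).
#'
#' @param gene_set Query gene ids (e.g. a clade or module).
#' @param db A [term_db()].
#' @param universe Universe gene ids (typically all network genes).
#' @param fdr_cut Display filter: rows with `q <= fdr_cut` are returned
#'   (default 0.05). The unfiltered table is attached as attribute
#'   `"unfiltered"`.
#' @param universe_mode `"all"` (default) uses `universe` as given;
#'   `"annotated"` restricts it to genes annotated by at least one term of
#'   the category.
#' @return Tibble with columns `term_id`, `description`, `p`, `q`, `k_hit`,
#'   `K`, `n_set`, `N`, `hit_pct`, `overrep`, sorted by `q` then `p`
#'   ascending.
#' @export
enrich <- function(gene_set, db, universe, fdr_cut = 0.05,
                   universe_mode = c("all", "annotated")) {
  stopifnot(inherits(db, "term_db"))
  universe_mode <- match.arg(universe_mode)
  universe <- unique(universe)
  if (universe_mode == "annotated") {
    universe <- intersect(universe, unique(unlist(db$genes, use.names = FALSE)))
  }
  set <- unique(intersect(gene_set, universe))
  empty <- tibble::tibble(term_id = character(), description = character(),
                          p = numeric(), q = numeric(), k_hit = integer(),
                          K = integer(), n_set = integer(), N = integer(),
                          hit_pct = numeric(), overrep = numeric())
  if (!length(set)) {
    warning("query gene set does not intersect the universe")
    attr(empty, "unfiltered") <- empty
    return(empty)
  }
  N <- length(universe)
  n_set <- length(set)
  rows <- purrr::imap(db$genes, function(genes, id) {
    ann <- intersect(genes, universe)
    K <- length(ann)
    k_hit <- length(intersect(ann, set))
    if (k_hit < 1L) return(NULL)
    tibble::tibble(term_id = id, description = db$descriptions[[id]],
                   p = hypergeom_upper(N, K, n_set, k_hit),
                   k_hit = k_hit, K = K, n_set = n_set, N = N,
                   hit_pct = 100 * k_hit / K,
                   overrep = (k_hit / n_set) / (K / N))
  })
  tab <- dplyr::bind_rows(rows)
  if (!nrow(tab)) {
    attr(empty, "unfiltered") <- empty
    return(empty)
  }
  tab <- dplyr::mutate(tab, q = bh_adjust(.data$p))
  tab <- dplyr::arrange(tab, .data$q, .data$p, .data$term_id)
  tab <- dplyr::select(tab, "term_id", "description", "p", "q", "k_hit",
                       "K", "n_set", "N", "hit_pct", "overrep")
  out <- dplyr::filter(tab, .data$q <= fdr_cut)
  attr(out, "unfiltered") <- tab
  out
}
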