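#' Rank intra-module pairwise distances
#'
#' Ranks the `M = n(n-1)/2` pairwise distances of a module over the
#' flattened upper triangle (smallest distance = rank 1; ties get
#' midranks), mirrored back to a symmetric matrix. The diagonal is unused
#' and set to `NA`.
#'
#' @param dist_submatrix Symmetric module distance matrix (zero diagonal).
#' @return Symmetric rank matrix with `NA` diagonal.
#' @export
distance_ranks <- function(dist_submatrix) {
  n <- nrow(dist_submatrix)
  if (n < 2L) stop("need at least 2 genes")
  if (max(abs(dist_submatrix - t(dist_submatrix))) > 1e-8) {
    stop("distance matrix is not symmetric")
  }
  ut <- upper.tri(dist_submatrix)
  r <- rank(dist_submatrix[ut], ties.method = "average")
  R <- matrix(NA_real_, n, n, dimnames = dimnames(dist_submatrix))
  R[ut] <- r
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Average distance ranking of module genes
#'
#' For a module of `n` genes with pairwise distance ranks `R[i, j]`, the
#' average ranking of gene `i` is
#' `avgRank_i = (n + 1) / ((n - 1) * (n(n-1)/2 + 1)) * sum_j R[i, j]`.
#' Lower scores mean a gene is consistently close to its co-members: the
#' score lives on a 1..n scale, with expectation `(n + 1) / 2` under
#' exchangeable ranks and total `n(n+1)/2` when distances are tie-free.
#'
#' @param ranks Rank matrix from [distance_ranks()].
#' @return Named numeric vector of avgRank scores (lower = more central).
#' @export
avg_rank <- function(ranks) {
  n <- nrow(ranks)
  M <- n * (n - 1) / 2
  s <- rowSums(ranks, na.rm = TRUE)
  stats::setNames((n + 1) / ((n - 1) * (M + 1)) * s, rownames(ranks))
}

#' Intramodular hub genes
#'
#' Hubs are the top-ranking gene plus every gene whose avgRank differs from
#' the top score by strictly less than 1.
#'
#' @param scores Named avgRank scores (from [avg_rank()]).
#' @return Character vector of hub gene ids (never empty).
#' @export
hub_genes <- function(scores) {
  if (!length(scores)) stop("no scores given")
  names(scores)[scores - min(scores) < 1]
}

#' Hub table for one module
#'
#' @param dist Full TOM distance matrix (dimnames = gene ids).
#' @param member_genes Gene ids of the module (>= 2).
#' @return Tibble with columns `gene`, `avg_rank`, `is_hub`, sorted by
#'   `avg_rank` ascending.
#' @export
module_hubs <- function(dist, member_genes) {
  missing <- setdiff(member_genes, rownames(dist))
  if (length(missing)) {
    stop("gene(s) absent from distance matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  d <- dist[member_genes, member_genes]
  scores <- avg_rank(distance_ranks(d))
  hubs <- hub_genes(scores)
  tibble::tibble(gene = names(scores), avg_rank = unname(scores),
                 is_hub = names(scores) %in% hubs) |>
    dplyr::arrange(.data$avg_rank, .data$gene)
}

#' Module page document
#'
#' Assembles everything the module view shows: the eigengene-trait
#' associations, per-category enrichment of the module's genes, and the
#' full gene table ranked by avgRank with hub flags.
#'
#' @param bundle A `coex_bundle`.
#' @param module_color Module color name.
#' @param fdr_cut FDR filter for the enrichment blocks (default 0.05).
#' @return A list (JSON-ready) with `module`, `n_genes`, `traits`
#'   (significant associations), `enrichment` (one table per loaded
#'   category), and `genes` (gene, avg_rank, is_hub rows, ascending).
#' @export
module_page <- function(bundle, module_color, fdr_cut = 0.05) {
  stopifnot(inherits(bundle, "coex_bundle"))
  if (!module_color %in% bundle$partition$colors) {
    stop("unknown module color '", module_color, "'")
  }
  genes <- names(bundle$partition$assignment)[bundle$partition$assignment == module_color]
  dist <- tom_distance(bundle$network$tom)
  gene_tab <- module_hubs(dist, genes)
  traits_tab <- if (!is.null(bundle$trait_table)) {
    dplyr::filter(bundle$trait_table, .data$module == module_color,
                  .data$significant)
  } else NULL
  enr <- purrr::map(bundle$term_dbs, function(db) {
    tab <- enrich(genes, db, universe = bundle$network$gene_ids,
                  fdr_cut = fdr_cut)
    purrr::transpose(as.list(tab))
  })
  list(module = module_color, n_genes = length(genes),
       traits = if (is.null(traits_tab)) NULL else purrr::transpose(as.list(traits_tab)),
       enrichment = enr,
       genes = purrr::transpose(as.list(gene_tab)))
}
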