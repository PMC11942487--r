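#' Default coexpression clade for a driver gene
#'
#' Scans the driver leaf's ancestors from parent to root and returns the
#' clade whose leaf count is closest to `target` (default 25). Ties prefer
#' the smaller clade, which yields more specialized enrichment downstream.
#'
#' @param tree A `coex_dendro`.
#' @param driver Driver gene id (must be a leaf).
#' @param target Desired clade size (default 25).
#' @return An object of class `coex_clade`: list with `driver`,
#'   `k_internal` (ancestor steps from the driver leaf), `root_node`
#'   (merge-row index), `genes`, `newick` (the subtree), and `truncated`
#'   (always `FALSE` here).
#' @export
default_clade <- function(tree, driver, target = 25L) {
  chain <- driver_chain(tree, driver)
  sizes <- chain$sizes
  dev <- abs(sizes - target)
  k <- which.min(dev)        # sizes are non-decreasing: first argmin = smaller clade
  make_clade(tree, driver, k, chain, truncated = FALSE)
}

#' Resize a driver's coexpression clade by internal-node count
#'
#' Returns the clade rooted at the `k_internal`-th ancestor of the driver
#' leaf. Expansion is capped at `ceiling(max_fraction * n_total)` genes: a
#' request beyond the cap returns the largest ancestor clade within the cap
#' (flagged as truncated), or the smallest clade (`k = 1`) if even that
#' exceeds the cap. A `k_internal` beyond the driver's depth is clamped to
#' the deepest admissible ancestor, flagged.
#'
#' @param tree A `coex_dendro`.
#' @param driver Driver gene id.
#' @param k_internal Requested number of internal nodes (>= 1).
#' @param max_fraction Cap on clade size as a fraction of all genes
#'   (default 0.25).
#' @return A `coex_clade`; `truncated` is `TRUE` when the request was
#'   reduced to respect the cap or the driver's depth.
#' @export
resize_clade <- function(tree, driver, k_internal, max_fraction = 0.25) {
  if (k_internal < 1L) stop("k_internal must be >= 1")
  chain <- driver_chain(tree, driver)
  n_total <- length(tree$labels)
  cap <- ceiling(max_fraction * n_total)
  truncated <- FALSE
  k <- k_internal
  if (k > length(chain$nodes)) { k <- length(chain$nodes); truncated <- TRUE }
  if (chain$sizes[k] > cap) {
    within <- which(chain$sizes <= cap)
    k_new <- if (length(within)) max(within) else 1L
    if (k_new < k) { k <- k_new; truncated <- TRUE }
  }
  make_clade(tree, driver, k, chain, truncated = truncated)
}

# ancestor chain of a driver with leaf counts, parent -> root
driver_chain <- function(tree, driver) {
  if (!driver %in% tree$labels) {
    near <- utils::head(tree$labels[order(utils::adist(driver, tree$labels))], 3L)
    stop("unknown driver gene '", driver, "'; nearest ids: ",
         paste(near, collapse = ", "))
  }
  nodes <- ancestors(tree, driver)
  idx <- dendro_index(tree)
  list(nodes = nodes, sizes = idx$leaf_count[nodes])
}

make_clade <- function(tree, driver, k, chain, truncated) {
  node <- chain$nodes[k]
  genes <- leaf_set(tree, node)
  structure(list(driver = driver, k_internal = k, root_node = node,
                 genes = genes, newick = subtree_newick(tree, node),
                 truncated = truncated),
            class = "coex_clade")
}

# Newick of the subtree rooted at an internal node (root branch omitted)
subtree_newick <- function(tree, node, digits = 15L) {
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  build <- function(v, parent_h) {
    if (v < 0L) {
      paste0(tree$labels[-v], ":", fmt(parent_h))
    } else {
      h <- tree$height[v]
      paste0("(", build(tree$merge[v, 1L], h), ",",
             build(tree$merge[v, 2L], h), "):", fmt(parent_h - h))
    }
  }
  h <- tree$height[node]
  paste0("(", build(tree$merge[node, 1L], h), ",",
         build(tree$merge[node, 2L], h), ");")
}

#' @export
print.coex_clade <- function(x, ...) {
  cat("<coex_clade> driver ", x$driver, ", k = ", x$k_internal, ", ",
      length(x$genes), " genes", if (x$truncated) " (truncated)", "\n", sep = "")
  invisible(x)
}

#' Assemble the JSON query payload for a driver gene
#'
#' Mirrors the `<driver>/<k>/<category>` query contract: the clade in Newick
#' form, driver details, the clade gene list with module colors, and - when
#' `category` names a term database loaded in the bundle - the enrichment
#' table ranked by adjusted p-value. An unknown or missing category simply
#' omits the enrichment block.
#'
#' @param bundle A `coex_bundle` (see [run_build()]).
#' @param driver Driver gene id.
#' @param k_internal Internal-node count; `NULL` (default) uses the default
#'   clade closest to 25 genes.
#' @param category Term-database keyword, or `NULL`.
#' @param fdr_cut FDR filter for the enrichment block (default 0.05).
#' @return A list (JSON-ready) with fields `schema_version`, `driver`,
#'   `clade` (`newick`, `k_internal`, `n_genes`, `truncated`), `genes`
#'   (id + module per gene), and optionally `enrichment`.
#' @export
api_payload <- function(bundle, driver, k_internal = NULL, category = NULL,
                        fdr_cut = 0.05) {
  stopifnot(inherits(bundle, "coex_bundle"))
  tree <- bundle$tree
  if (!driver %in% tree$labels) {
    return(list(schema_version = payload_schema_version(),
                error = paste0("unknown driver gene '", driver, "'")))
  }
  clade <- if (is.null(k_internal)) default_clade(tree, driver)
           else resize_clade(tree, driver, k_internal)
  module_of <- function(g) {
    m <- bundle$partition$assignment[g]
    ifelse(is.na(m), "grey", unname(m))
  }
  payload <- list(
    schema_version = payload_schema_version(),
    driver = list(id = driver, module = module_of(driver)),
    clade = list(newick = clade$newick, k_internal = clade$k_internal,
                 n_genes = length(clade$genes), truncated = clade$truncated),
    genes = purrr::map(clade$genes, function(g) list(id = g, module = module_of(g)))
  )
  if (!is.null(category) && category %in% names(bundle$term_dbs)) {
    tab <- enrich(clade$genes, bundle$term_dbs[[category]],
                  universe = tree$labels, fdr_cut = fdr_cut)
    payload$enrichment <- list(category = category,
                               table = purrr::transpose(as.list(tab)))
  }
  payload
}

payload_schema_version <- function() "1.0"
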