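#' Run the full network-construction pipeline
#'
#' Correlation -> signed adjacency -> TOM -> average-linkage dendrogram ->
#' dynamic tree cut -> eigengene merging -> trait association, collected in
#' a queryable bundle. Queries never mutate a bundle; rebuilding with the
#' same inputs reproduces it bit for bit.
#'
#' @param expr Genes x samples expression matrix.
#' @param design Optional binary samples x traits matrix; when absent the
#'   bundle is built without a trait table (a warning is logged).
#' @param term_dbs Named list of [term_db()] objects, keyed by category.
#' @param beta Soft-threshold power (default 14) or `"auto"`.
#' @param r2_cut Scale-free R^2 cut for `beta = "auto"`.
#' @param min_cluster_size,deep_split,pam_stage,max_pam_dist,merge_height
#'   Module detection parameters (see [dynamic_tree_cut()] and
#'   [merge_close_modules()]).
#' @param alpha Trait-association significance threshold.
#' @param out_dir Optional directory; when given the bundle is written
#'   there (see [write_bundle()]).
#' @return An object of class `coex_bundle`: list with `expr`, `network`
#'   (`coex_network`), `tree`, `partition`, `trait_table`, `term_dbs`, and
#'   `params`.
#' @export
run_build <- function(expr, design = NULL, term_dbs = list(), beta = 14,
                      r2_cut = 0.85, min_cluster_size = 15L, deep_split = 2L,
                      pam_stage = TRUE, max_pam_dist = NULL,
                      merge_height = 0.25, alpha = 0.05, out_dir = NULL) {
  net <- build_network(expr, beta = beta, r2_cut = r2_cut)
  dist <- tom_distance(net$tom)
  tree <- average_linkage(dist, rownames(expr))
  partition <- detect_modules(expr, tree, dist,
                              min_cluster_size = min_cluster_size,
                              deep_split = deep_split, pam_stage = pam_stage,
                              max_pam_dist = max_pam_dist,
                              merge_height = merge_height)
  trait_table <- NULL
  if (!is.null(design)) {
    if (nrow(partition$eigengenes) > 0L) {
      trait_table <- eigengene_trait_correlation(partition$eigengenes, design,
                                                 alpha = alpha)
    }
  } else {
    warning("no trait design supplied: bundle built without trait table")
  }
  bundle <- structure(list(
    expr = expr, network = net, tree = tree, partition = partition,
    trait_table = trait_table, term_dbs = term_dbs,
    params = list(beta = net$beta, min_cluster_size = min_cluster_size,
                  deep_split = deep_split, pam_stage = pam_stage,
                  merge_height = merge_height, alpha = alpha,
                  version = as.character(utils::packageVersion("coexclade")))),
    class = "coex_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.coex_bundle <- function(x, ...) {
  cat("<coex_bundle> ", length(x$network$gene_ids), " genes, beta = ",
      x$network$beta, ", ", length(x$partition$colors), " modules\n", sep = "")
  invisible(x)
}

# ---- bundle serialization -------------------------------------------------

write_matrix_bin <- function(mat, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(mat)), con, size = 8L)   # row-major float64
  invisible(path)
}

read_matrix_bin <- function(path, gene_ids) {
  n <- length(gene_ids)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n * n, size = 8L)
  matrix(vals, n, n, byrow = TRUE, dimnames = list(gene_ids, gene_ids))
}

#' Write a network bundle to a directory
#'
#' Layout: `network.json` sidecar (gene/sample order, beta, parameters),
#' `correlation.bin` / `adjacency.bin` / `tom.bin` (row-major float64),
#' `tree.nwk`, `expression.tsv`, `modules.tsv` (gene_id, module_color),
#' `eigengenes.tsv`, `trait_associations.tsv`, `merge_log.json`,
#' `terms_<category>.gmt`, and `manifest.json` with md5 digests of every
#' numeric artifact.
#'
#' @param bundle A `coex_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "coex_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  jsonlite::write_json(list(gene_ids = bundle$network$gene_ids,
                            sample_ids = colnames(bundle$expr),
                            beta = bundle$network$beta,
                            params = bundle$params,
                            matrices = c("correlation", "adjacency", "tom"),
                            layout = "row-major float64"),
                       p("network.json"), auto_unbox = TRUE, digits = NA)
  write_matrix_bin(bundle$network$correlation, p("correlation.bin"))
  write_matrix_bin(bundle$network$adjacency, p("adjacency.bin"))
  write_matrix_bin(bundle$network$tom, p("tom.bin"))
  writeLines(to_newick(bundle$tree), p("tree.nwk"))
  write_expression(bundle$expr, p("expression.tsv"))
  utils::write.table(
    data.frame(gene_id = names(bundle$partition$assignment),
               module_color = unname(bundle$partition$assignment)),
    p("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  eig <- bundle$partition$eigengenes
  utils::write.table(
    data.frame(module = rownames(eig), eig, check.names = FALSE),
    p("eigengenes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(merge_log = bundle$partition$merge_log,
                            n_premerge = bundle$partition$n_premerge,
                            var_explained = as.list(bundle$partition$var_explained)),
                       p("merge_log.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$trait_table)) {
    utils::write.table(bundle$trait_table, p("trait_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (cat in names(bundle$term_dbs)) {
    write_term_db(bundle$term_dbs[[cat]], p(paste0("terms_", cat, ".gmt")))
  }
  numeric_files <- c("correlation.bin", "adjacency.bin", "tom.bin",
                     "tree.nwk", "expression.tsv", "modules.tsv",
                     "eigengenes.tsv")
  digests <- as.list(tools::md5sum(vapply(numeric_files, p, "")))
  names(digests) <- numeric_files
  jsonlite::write_json(list(params = bundle$params, digests = digests),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a network bundle from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `coex_bundle`.
#' @export
load_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  side <- jsonlite::read_json(p("network.json"), simplifyVector = TRUE)
  genes <- side$gene_ids
  expr <- read_expression(p("expression.tsv"), drop_zero_variance = FALSE)
  net <- structure(list(gene_ids = genes,
                        correlation = read_matrix_bin(p("correlation.bin"), genes),
                        adjacency = read_matrix_bin(p("adjacency.bin"), genes),
                        tom = read_matrix_bin(p("tom.bin"), genes),
                        beta = side$beta, power_table = NULL),
                   class = "coex_network")
  net$connectivity <- colSums(net$adjacency) - 1
  tree <- parse_newick(readLines(p("tree.nwk"), warn = FALSE)[1L])
  mods <- utils::read.delim(p("modules.tsv"), stringsAsFactors = FALSE)
  assignment <- stats::setNames(mods$module_color, mods$gene_id)
  eig_df <- utils::read.delim(p("eigengenes.tsv"), check.names = FALSE,
                              stringsAsFactors = FALSE)
  eig <- as.matrix(eig_df[, -1L, drop = FALSE])
  rownames(eig) <- eig_df$module
  mlog <- jsonlite::read_json(p("merge_log.json"), simplifyVector = FALSE)
  colors <- rownames(eig)
  partition <- structure(list(assignment = assignment, colors = colors,
                              eigengenes = eig,
                              var_explained = unlist(mlog$var_explained),
                              merge_log = mlog$merge_log,
                              n_premerge = mlog$n_premerge),
                         class = "module_partition")
  trait_table <- NULL
  if (file.exists(p("trait_associations.tsv"))) {
    trait_table <- tibble::as_tibble(
      utils::read.delim(p("trait_associations.tsv"), stringsAsFactors = FALSE))
  }
  gmt_files <- list.files(dir, pattern = "^terms_.*\\.gmt$")
  term_dbs <- list()
  for (f in gmt_files) {
    cat <- sub("^terms_(.*)\\.gmt$", "\\1", f)
    term_dbs[[cat]] <- read_term_db(p(f), cat, format = "gmt")
  }
  structure(list(expr = expr, network = net, tree = tree,
                 partition = partition, trait_table = trait_table,
                 term_dbs = term_dbs, params = side$params),
            class = "coex_bundle")
}

# ---- query-time entry points ---------------------------------------------

#' Run a driver-gene clade query against a bundle
#' @inheritParams api_payload
#' @return The JSON-ready payload list (see [api_payload()]).
#' @export
run_query <- function(bundle, driver, k_internal = NULL, category = NULL,
                      fdr_cut = 0.05) {
  api_payload(bundle, driver, k_internal = k_internal, category = category,
              fdr_cut = fdr_cut)
}

#' Run an enrichment analysis for a clade or explicit gene set
#'
#' @param bundle A `coex_bundle`.
#' @param category Term-database keyword (must be loaded in the bundle).
#' @param genes Explicit gene set; alternatively give `driver` (+ optional
#'   `k_internal`) to enrich a coexpression clade.
#' @param driver,k_internal Clade specification when `genes` is absent.
#' @param fdr_cut FDR display filter (default 0.05).
#' @return The [enrich()] tibble.
#' @export
run_enrich <- function(bundle, category, genes = NULL, driver = NULL,
                       k_internal = NULL, fdr_cut = 0.05) {
  stopifnot(inherits(bundle, "coex_bundle"))
  if (!category %in% names(bundle$term_dbs)) {
    stop("no term database loaded for category '", category, "'")
  }
  if (is.null(genes)) {
    if (is.null(driver)) stop("give either `genes` or `driver`")
    clade <- if (is.null(k_internal)) default_clade(bundle$tree, driver)
             else resize_clade(bundle$tree, driver, k_internal)
    genes <- clade$genes
  }
  enrich(genes, bundle$term_dbs[[category]],
         universe = bundle$network$gene_ids, fdr_cut = fdr_cut)
}

#' Hub table for a module of a bundle
#' @param bundle A `coex_bundle`.
#' @param module_color Module color name.
#' @return The [module_hubs()] tibble.
#' @export
run_hubs <- function(bundle, module_color) {
  stopifnot(inherits(bundle, "coex_bundle"))
  if (!module_color %in% bundle$partition$colors) {
    stop("unknown module color '", module_color, "'")
  }
  genes <- names(bundle$partition$assignment)[bundle$partition$assignment == module_color]
  module_hubs(tom_distance(bundle$network$tom), genes)
}

#' Module page document for a bundle
#' @inheritParams module_page
#' @return See [module_page()].
#' @export
run_module_page <- function(bundle, module_color, fdr_cut = 0.05) {
  module_page(bundle, module_color, fdr_cut = fdr_cut)
}
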