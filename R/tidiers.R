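#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a module partition into a gene-level tibble
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `module`.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) {
  tibble::tibble(gene_id = names(x$assignment), module = unname(x$assignment))
}

#' One-row summary of a module partition
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `n_modules`, `n_premerge`, `n_grey`,
#'   `mean_var_explained`.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(n_genes = length(x$assignment),
                 n_modules = length(x$colors),
                 n_premerge = x$n_premerge,
                 n_grey = sum(x$assignment == "grey"),
                 mean_var_explained = if (length(x$var_explained)) mean(x$var_explained) else NA_real_)
}

#' Tidy a coexpression network into a per-gene connectivity tibble
#' @param x A `coex_network`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `connectivity`.
#' @method tidy coex_network
#' @export
tidy.coex_network <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_ids, connectivity = unname(x$connectivity))
}

#' One-row summary of a coexpression network
#' @param x A `coex_network`.
#' @param ... Unused.
#' @return Tibble with `n_genes`, `beta`, `k_mean`, `k_max`, `tom_mean`.
#' @method glance coex_network
#' @export
glance.coex_network <- function(x, ...) {
  off <- upper.tri(x$tom)
  tibble::tibble(n_genes = length(x$gene_ids), beta = x$beta,
                 k_mean = mean(x$connectivity), k_max = max(x$connectivity),
                 tom_mean = mean(x$tom[off]))
}

#' Tidy a soft-threshold scan
#' @param x A `power_scan` from [pick_soft_threshold()].
#' @param ... Unused.
#' @return The per-power tibble with a `chosen` flag.
#' @method tidy power_scan
#' @export
tidy.power_scan <- function(x, ...) {
  dplyr::mutate(x$table, chosen = .data$power == x$beta)
}

#' Tidy a clade into a gene tibble
#' @param x A `coex_clade`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `is_driver`.
#' @method tidy coex_clade
#' @export
tidy.coex_clade <- function(x, ...) {
  tibble::tibble(gene_id = x$genes, is_driver = x$genes == x$driver)
}

#' Plot a soft-threshold scan
#'
#' Signed scale-free R^2 against candidate power, with the chosen power
#' highlighted and the R^2 cut drawn as a dashed line.
#'
#' @param object A `power_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot power_scan
#' @export
autoplot.power_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = object$r2_cut, linetype = "dashed",
                        color = "red") +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                guide = "none") +
    ggplot2::labs(x = "soft-threshold power", y = "signed scale-free R²") +
    ggplot2::theme_minimal()
}

#' Plot module sizes
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot of gene counts per module, colored by module color.
#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, ...) {
  df <- dplyr::count(tidy(object), .data$module, name = "n_genes")
  df$module <- factor(df$module, levels = c(object$colors, "grey"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$n_genes,
                                   fill = .data$module)) +
    ggplot2::geom_col(color = "black", linewidth = 0.2) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Module-trait association heatmap
#'
#' Tile plot of eigengene-trait correlations, the tabular counterpart of
#' the usual module-trait relationship figure.
#'
#' @param trait_table Tibble from [eigengene_trait_correlation()].
#' @param label_significant Mark cells passing the significance flag with
#'   `*` (default `TRUE`).
#' @return A ggplot.
#' @export
plot_trait_heatmap <- function(trait_table, label_significant = TRUE) {
  p <- ggplot2::ggplot(trait_table,
                       ggplot2::aes(x = .data$trait, y = .data$module,
                                    fill = .data$r)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "tissue trait", y = "module", fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (label_significant) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(trait_table, .data$significant),
      label = "*", vjust = 0.75)
  }
  p
}
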