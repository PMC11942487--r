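#' Correlate module eigengenes with binary tissue traits
#'
#' For every (module, trait) pair, the Pearson correlation `r` between the
#' eigengene and the 0/1 trait column is computed (a point-biserial
#' correlation is exactly a PCC on a binary column), with a two-sided
#' p-value from `t = r * sqrt((m - 2) / (1 - r^2))` on `m - 2` degrees of
#' freedom. A constant trait column (all 0 or all 1) yields `NA` for both
#' `r` and `p`: the association is undefined, not zero. No multiple-testing
#' correction is applied across the grid; the raw p-value is always emitted.
#'
#' @param eigengenes Module x sample matrix (e.g. from a
#'   `module_partition`).
#' @param design Binary samples x traits matrix; sample order must match
#'   the eigengene columns.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return Tibble with columns `module`, `trait`, `r`, `p`, `significant`,
#'   `direction` ("positive"/"negative"/`NA`).
#' @export
eigengene_trait_correlation <- function(eigengenes, design, alpha = 0.05) {
  stopifnot(is.matrix(eigengenes), is.matrix(design))
  if (ncol(eigengenes) != nrow(design)) {
    stop("sample counts differ between eigengenes and trait design")
  }
  if (!is.null(colnames(eigengenes)) && !is.null(rownames(design)) &&
      !identical(colnames(eigengenes), rownames(design))) {
    stop("sample order differs between eigengenes and trait design")
  }
  m <- ncol(eigengenes)
  if (m < 3L) stop("need at least 3 samples")
  grid <- tidyr::expand_grid(module = rownames(eigengenes),
                             trait = colnames(design))
  res <- purrr::pmap(grid, function(module, trait) {
    y <- design[, trait]
    if (stats::var(y) == 0) return(list(r = NA_real_, p = NA_real_))
    r <- stats::cor(eigengenes[module, ], y)
    p <- pcc_pvalue(r, m)
    list(r = r, p = p)
  })
  dplyr::mutate(grid,
    r = vapply(res, `[[`, 0, "r"),
    p = vapply(res, `[[`, 0, "p"),
    significant = !is.na(.data$p) & .data$p <= alpha,
    direction = dplyr::case_when(is.na(r) ~ NA_character_,
                                 r >= 0 ~ "positive",
                                 TRUE ~ "negative"))
}

# two-sided p-value of a Pearson r at m samples (Student t transform)
pcc_pvalue <- function(r, m) {
  if (is.na(r)) return(NA_real_)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt((m - 2) / (1 - r^2))
  2 * stats::pt(abs(t), df = m - 2, lower.tail = FALSE)
}
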