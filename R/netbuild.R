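#' Pearson correlation matrix of genes
#'
#' @param expr Numeric matrix, genes x samples; every gene must have nonzero
#'   variance across samples.
#' @return Symmetric correlation matrix (genes x genes) with unit diagonal.
#' @export
pearson_matrix <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[v == 0], 5L), collapse = ", "))
  }
  r <- stats::cor(t(expr))
  # guard against rounding drift outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Signed adjacency transform
#'
#' Maps correlations into connection strengths via `a = ((1 + r) / 2)^beta`,
#' so perfect positive correlation gives weight 1, perfect negative
#' correlation gives 0, and uncorrelated pairs give `0.5^beta`. The signed
#' transform keeps negatively correlated genes apart instead of folding them
#' onto the positives.
#'
#' @param correlation Matrix with entries in `[-1, 1]`.
#' @param beta Soft-threshold power, `>= 1`.
#' @return Adjacency matrix with entries in `[0, 1]`.
#' @export
signed_adjacency <- function(correlation, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1) {
    stop("beta must be a single number >= 1")
  }
  if (any(correlation < -1 - 1e-12) || any(correlation > 1 + 1e-12)) {
    stop("correlation entries must lie in [-1, 1]")
  }
  ((1 + correlation) / 2)^beta
}

#' Scale-free topology fit index
#'
#' Bins the connectivity distribution into `n_bins` equal-width bins and
#' regresses `log10(frequency)` on `log10(mean connectivity)` over non-empty
#' bins. The returned R^2 is signed as `-sign(slope) * R^2`, so a clean
#' power-law decay scores close to +1.
#'
#' @param connectivity Non-negative per-gene connectivities.
#' @param n_bins Number of histogram bins (default 10).
#' @return List with `r_squared` (signed), `slope`, and the per-bin tibble.
#' @export
scale_free_fit <- function(connectivity, n_bins = 10L) {
  stopifnot(is.numeric(connectivity), all(connectivity >= 0))
  if (length(unique(connectivity)) < 2L) {
    stop("degenerate connectivity histogram: all values equal")
  }
  breaks <- seq(min(connectivity), max(connectivity), length.out = n_bins + 1L)
  bin <- cut(connectivity, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  k_mean <- tapply(connectivity, bin, mean)
  freq <- tapply(connectivity, bin, length) / length(connectivity)
  keep <- !is.na(k_mean) & k_mean > 0 & freq > 0
  if (sum(keep) < 2L) stop("fewer than 2 usable bins in connectivity histogram")
  x <- log10(k_mean[keep])
  y <- log10(freq[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[[2L]]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r_squared = -sign(slope) * r2, slope = slope,
       bins = tibble::tibble(k_mean = as.numeric(k_mean[keep]),
                             freq = as.numeric(freq[keep])))
}

#' Choose the soft-threshold power by scale-free fit
#'
#' For each candidate power the signed adjacency network is formed and the
#' signed scale-free R^2 of its connectivity distribution computed. The
#' smallest power reaching `r2_cut` is chosen; if none qualifies, the power
#' with maximal signed R^2 is returned and flagged.
#'
#' @param expr Genes x samples expression matrix (>= 10 genes).
#' @param powers Ordered integer candidate powers (default `1:20`).
#' @param r2_cut Signed R^2 threshold in `(0, 1]` (default 0.85).
#' @param n_bins Bins for the scale-free fit.
#' @return List with `beta` (chosen power), `reached_cut` (logical), and
#'   `table`: a tibble with one row per power (`power`, `r_squared`, `slope`,
#'   `k_mean`, `k_median`, `k_max`).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_cut = 0.85, n_bins = 10L) {
  if (nrow(expr) < 10L) stop("fewer than 10 genes: scale-free fit is meaningless")
  if (!length(powers)) stop("candidate power list is empty")
  if (r2_cut <= 0 || r2_cut > 1) stop("r2_cut must lie in (0, 1]")
  r <- pearson_matrix(expr)
  rows <- purrr::map(powers, function(p) {
    a <- signed_adjacency(r, p)
    k <- colSums(a) - 1
    fit <- scale_free_fit(k, n_bins)
    tibble::tibble(power = p, r_squared = fit$r_squared, slope = fit$slope,
                   k_mean = mean(k), k_median = stats::median(k), k_max = max(k))
  })
  tab <- dplyr::bind_rows(rows)
  ok <- which(tab$r_squared >= r2_cut)
  res <- if (length(ok)) {
    list(beta = tab$power[ok[1L]], reached_cut = TRUE, table = tab)
  } else {
    list(beta = tab$power[which.max(tab$r_squared)], reached_cut = FALSE, table = tab)
  }
  structure(c(res, list(r2_cut = r2_cut)), class = "power_scan")
}

#' @export
print.power_scan <- function(x, ...) {
  cat("<power_scan> chosen beta = ", x$beta,
      if (!x$reached_cut) " (no power reached the R^2 cut)", "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Topological overlap similarity
#'
#' For a symmetric adjacency `a` with unit diagonal,
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, where
#' `l_ij = sum_{u != i,j} a_iu a_uj` counts shared neighborhood and
#' `k_i = sum_{u != i} a_iu` is the connectivity. The diagonal is 1, so
#' `1 - TOM` is a proper self-distance of zero. Computation is blocked over
#' row chunks; results are identical to the unblocked product.
#'
#' @param adjacency Symmetric matrix, entries in `[0, 1]`, unit diagonal.
#' @param block_size Rows per block for the matrix product (memory control).
#' @return TOM similarity matrix, symmetric, entries in `[0, 1]`, unit
#'   diagonal.
#' @export
tom_similarity <- function(adjacency, block_size = 1024L) {
  n <- nrow(adjacency)
  if (max(abs(adjacency - t(adjacency))) > 1e-8) stop("adjacency is not symmetric")
  if (any(adjacency < 0) || any(adjacency > 1 + 1e-12)) stop("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0            # work with the hollow matrix; l_ij excludes u = i, j
  k <- colSums(a)
  tom <- matrix(0, n, n, dimnames = dimnames(adjacency))
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    l <- a[idx, , drop = FALSE] %*% a   # includes u = i and u = j terms; both are 0 off-diag since diag(a)=0
    num <- l + a[idx, , drop = FALSE]
    den <- outer(k[idx], k, pmin) + 1 - a[idx, , drop = FALSE]
    tom[idx, ] <- num / den
  }
  tom <- (tom + t(tom)) / 2   # symmetrize away rounding drift
  tom[tom > 1] <- 1
  diag(tom) <- 1
  tom
}

#' TOM distance
#' @param tom TOM similarity matrix with entries in `[0, 1]`.
#' @return `1 - tom`, with a zero diagonal.
#' @export
tom_distance <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Build a signed weighted coexpression network
#'
#' Runs correlation -> signed adjacency -> TOM in one call.
#'
#' @param expr Genes x samples expression matrix.
#' @param beta Soft-threshold power, or `"auto"` to select it with
#'   [pick_soft_threshold()].
#' @param r2_cut Scale-free R^2 cut used when `beta = "auto"`.
#' @param block_size Passed to [tom_similarity()].
#' @return An object of class `coex_network`: list with `gene_ids`,
#'   `correlation`, `adjacency`, `tom`, `connectivity`, `beta`, and (for
#'   `"auto"`) the `power_table`.
#' @export
build_network <- function(expr, beta = 14, r2_cut = 0.85, block_size = 1024L) {
  power_table <- NULL
  if (identical(beta, "auto")) {
    pick <- pick_soft_threshold(expr, r2_cut = r2_cut)
    beta <- pick$beta
    power_table <- pick$table
    if (!pick$reached_cut) {
      warning("no candidate power reached r2_cut = ", r2_cut,
              "; using power with maximal signed R^2 (", beta, ")")
    }
  }
  r <- pearson_matrix(expr)
  a <- signed_adjacency(r, beta)
  tom <- tom_similarity(a, block_size = block_size)
  structure(list(gene_ids = rownames(expr), correlation = r, adjacency = a,
                 tom = tom, connectivity = colSums(a) - 1, beta = beta,
                 power_table = power_table),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat("<coex_network> ", length(x$gene_ids), " genes, signed, beta = ",
      x$beta, "\n", sep = "")
  invisible(x)
}
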