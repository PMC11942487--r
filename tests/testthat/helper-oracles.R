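# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive reimplementation used only to check
# the package's optimized code paths.

# per-pair two-pass Pearson correlation
naive_pearson <- function(x) {
  n <- nrow(x)
  r <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- x[i, ]; b <- x[j, ]
    r[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  r
}

# triple-loop TOM evaluation straight from the formula
tom_loop_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- colSums(a)
  tom <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# O(n^3) average linkage: recompute every cross-pair mean at every step
naive_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      m <- mean(d[clusters[[i]], clusters[[j]]])
      if (m < best - 1e-15) { best <- m; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# exact hypergeometric upper tail by direct combinatorial enumeration
# (choose() is exact in double precision for all N <= 25)
hyper_enum_oracle <- function(N, K, n_set, k_hit) {
  xs <- k_hit:min(K, n_set)
  sum(choose(K, xs) * choose(N - K, n_set - xs)) / choose(N, n_set)
}

# adjusted Rand index over two label vectors (grey/background = its own class)
ari <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  sij <- sum(choose(ct, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# random rooted binary ultrametric tree with strictly increasing merge heights
random_tree <- function(n, labels = sprintf("G%03d", seq_len(n))) {
  merge <- matrix(0L, n - 1L, 2L)
  height <- sort(runif(n - 1L))
  active <- as.list(-seq_len(n))
  for (k in seq_len(n - 1L)) {
    pick <- sample(length(active), 2L)
    merge[k, ] <- sort(c(active[[pick[1L]]], active[[pick[2L]]]))
    active[pick] <- NULL
    active[[length(active) + 1L]] <- k
  }
  tree <- structure(list(merge = merge, height = height, order = integer(0),
                         labels = labels, method = "average",
                         call = NULL, dist.method = "tom"),
                    class = c("coex_dendro", "hclust"))
  tree$order <- coexclade:::dendro_leaf_order(tree)
  tree
}

# random symmetric matrix in [0, 1] with unit diagonal (a valid adjacency)
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("G%02d", 1:n), sprintf("G%02d", 1:n))
  a
}

# random distance matrix: symmetric, zero diagonal
random_distance <- function(n) {
  d <- matrix(runif(n * n, 0.05, 1), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  d
}

# a dendrogram built so that one chosen leaf has a prescribed ancestor
# leaf-count profile, e.g. c(2, 10, 24, 30, 200): caterpillar of blocks
tree_with_ancestor_counts <- function(counts) {
  n <- counts[length(counts)]
  stopifnot(counts[1L] >= 2L, all(diff(counts) > 0))
  labels <- sprintf("G%03d", seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  h <- 0
  row <- 0L
  # chain along leaves 1..: first ancestor joins leaves 1..counts[1]
  chain <- -1L
  used <- 1L
  block_root <- function(leaves_idx) {
    # ladder over the given leaf indices; returns node id and updates row/h
    node <- -leaves_idx[1L]
    for (t in leaves_idx[-1L]) {
      row <<- row + 1L; h <<- h + 1e-3
      merge[row, ] <<- sort(c(node, -t)); height[row] <<- h
      node <- row
    }
    node
  }
  for (ci in seq_along(counts)) {
    add <- (used + 1L):counts[ci]
    sub <- block_root(add)
    row <- row + 1L; h <- h + 0.05
    merge[row, ] <- sort(c(chain, sub)); height[row] <- h
    chain <- row
    used <- counts[ci]
  }
  tree <- structure(list(merge = merge[seq_len(row), , drop = FALSE],
                         height = height[seq_len(row)], order = integer(0),
                         labels = labels, method = "average", call = NULL,
                         dist.method = "tom"),
                    class = c("coex_dendro", "hclust"))
  tree$order <- coexclade:::dendro_leaf_order(tree)
  tree
}

# multi-seed pipeline recovery experiment (modules, traits, hubs), cached
.recovery_cache <- new.env(parent = emptyenv())
recovery_experiment <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  rows <- lapply(seeds, function(s) {
    d <- generate(synth_config(seed = s), check_separation = FALSE)
    b <- suppressWarnings(run_build(d$expr, d$design))
    truth <- d$truth
    trait_ok <- 0L; hub_ok <- 0L; matched <- 0L
    dist <- tom_distance(b$network$tom)
    for (col in b$partition$colors) {
      genes <- names(b$partition$assignment)[b$partition$assignment == col]
      planted <- as.integer(names(which.max(table(truth$modules[genes]))))
      if (planted == 0L) next
      matched <- matched + 1L
      tt <- b$trait_table[b$trait_table$module == col, ]
      best <- which.max(tt$r)
      if (identical(tt$trait[best], unname(truth$module_tissue[planted])) &&
          tt$p[best] < 1e-6) trait_ok <- trait_ok + 1L
      hubs <- module_hubs(dist, genes)
      top_gene <- names(which.max(
        truth$loadings[names(truth$modules)[truth$modules == planted]]))
      if (top_gene %in% hubs$gene[hubs$is_hub]) hub_ok <- hub_ok + 1L
    }
    data.frame(seed = s, n_modules = length(b$partition$colors),
               ari = ari(b$partition$assignment[names(truth$modules)],
                         truth$modules),
               matched = matched, trait_ok = trait_ok, hub_ok = hub_ok)
  })
  out <- do.call(rbind, rows)
  .recovery_cache[[key]] <- out
  out
}

# benchmark synthetic dataset + full pipeline build, cached across tests
.benchmark_cache <- new.env(parent = emptyenv())
build_benchmark <- function(seed = 42L) {
  key <- as.character(seed)
  if (is.null(.benchmark_cache[[key]])) {
    d <- generate(synth_config(seed = seed))
    bundle <- suppressWarnings(run_build(d$expr, d$design))
    .benchmark_cache[[key]] <- list(data = d, bundle = bundle)
  }
  .benchmark_cache[[key]]
}
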