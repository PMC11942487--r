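test_that("trees too small for the minimum size leave every gene grey", {
  set.seed(41)
  d <- random_distance(10)
  tree <- average_linkage(d)
  out <- dynamic_tree_cut(tree, d, min_cluster_size = 15L)
  expect_true(all(out == 0L))
})

test_that("well-separated blocks are recovered exactly and purely", {
  set.seed(43)
  # three blocks of 30 genes: tiny within-block distance, large between
  n <- 90
  lab <- sprintf("G%03d", 1:n)
  block <- rep(1:3, each = 30)
  d <- matrix(0.95, n, n, dimnames = list(lab, lab))
  for (b in 1:3) {
    i <- which(block == b)
    d[i, i] <- matrix(runif(30 * 30, 0.05, 0.15), 30, 30)
  }
  d <- (d + t(d)) / 2; diag(d) <- 0
  tree <- average_linkage(d)
  out <- dynamic_tree_cut(tree, d, min_cluster_size = 15L)
  expect_length(unique(out[out > 0]), 3L)
  for (m in unique(out[out > 0])) {
    expect_length(unique(block[match(names(out)[out == m], lab)]), 1L)  # pure
  }
  expect_true(all(out > 0))
})

test_that("module detection recovers planted labels on the synthetic benchmark", {
  bm <- build_benchmark()
  truth <- bm$data$truth$modules
  got <- bm$bundle$partition$assignment[names(truth)]
  expect_gte(ari(got, truth), 0.9)
  expect_identical(length(bm$bundle$partition$colors), 5L)
  # no non-grey module below the minimum size
  sizes <- table(got[got != "grey"])
  expect_true(all(sizes >= 15))
})

test_that("module eigengene matches its definition and a dense SVD oracle", {
  set.seed(47)
  expr <- matrix(rnorm(25 * 30), 25, 30,
                 dimnames = list(sprintf("G%02d", 1:25), sprintf("S%02d", 1:30)))
  # single-gene module: eigengene is the standardized gene itself
  e1 <- module_eigengene(expr, "G01")
  expect_equal(unname(e1$eigengene),
               as.numeric(scale(expr["G01", ])), tolerance = 1e-12)
  expect_equal(e1$var_explained, 1)

  # near-rank-1 module
  shared <- rnorm(30)
  for (i in 1:10) expr[i, ] <- shared + rnorm(30, sd = 0.01)
  ek <- module_eigengene(expr, sprintf("G%02d", 1:10))
  expect_gt(ek$var_explained, 0.99)
  expect_gt(cor(ek$eigengene, shared), 0.999)

  # var_explained equals an independent full SVD on the standardized block
  genes <- sprintf("G%02d", 11:25)
  ev <- module_eigengene(expr, genes)
  xs <- t(scale(t(expr[genes, ])))
  dvals <- svd(xs)$d
  expect_equal(ev$var_explained, dvals[1]^2 / sum(dvals^2), tolerance = 1e-10)
  expect_equal(sd(ev$eigengene), 1, tolerance = 1e-12)    # unit variance
  expect_error(module_eigengene(expr, "G99"), "absent")
})

test_that("close modules merge by eigengene correlation at the 0.25 threshold", {
  set.seed(53)
  m <- 80
  latent <- rnorm(m)
  make_block <- function(latent, k, sd) {
    t(sapply(seq_len(k), function(i) 0.9 * latent + rnorm(m, sd = sd)))
  }
  # two modules on the SAME latent profile: eigengene dissimilarity ~ 0
  expr <- rbind(make_block(latent, 20, 0.3), make_block(latent, 20, 0.3))
  rownames(expr) <- sprintf("G%03d", 1:40); colnames(expr) <- sprintf("S%02d", 1:m)
  assign1 <- stats::setNames(rep(1:2, each = 20), rownames(expr))
  part <- merge_close_modules(expr, assign1)
  expect_length(part$colors, 1L)
  expect_identical(part$n_premerge, 2L)

  # controlled eigengene correlation: r ~ 0.8 merges, r ~ 0.5 does not
  make_pair <- function(r_target) {
    l1 <- rnorm(m); l2 <- r_target * l1 + sqrt(1 - r_target^2) * rnorm(m)
    expr <- rbind(make_block(l1, 20, 0.05), make_block(l2, 20, 0.05))
    rownames(expr) <- sprintf("G%03d", 1:40); colnames(expr) <- sprintf("S%02d", 1:m)
    merge_close_modules(expr, stats::setNames(rep(1:2, each = 20), rownames(expr)))
  }
  expect_length(make_pair(0.80)$colors, 1L)   # dissimilarity ~ 0.20 < 0.25
  expect_length(make_pair(0.50)$colors, 2L)   # dissimilarity ~ 0.50
})

test_that("merging converges, is idempotent, and leaves no close pair behind", {
  set.seed(59)
  m <- 60
  expr <- matrix(rnorm(120 * m), 120, m,
                 dimnames = list(sprintf("G%03d", 1:120), sprintf("S%02d", 1:m)))
  lat <- matrix(rnorm(6 * m), 6, m)
  for (b in 1:6) {
    rows <- ((b - 1) * 20 + 1):(b * 20)
    expr[rows, ] <- expr[rows, ] * 0.4 + 0.85 * lat[((b - 1) %/% 2) + 1, ][col(expr[rows, ])]
  }
  assign0 <- stats::setNames(rep(1:6, each = 20), rownames(expr))
  part <- merge_close_modules(expr, assign0)
  # post-condition: no surviving pair of eigengenes correlates above 1 - 0.25
  if (length(part$colors) >= 2L) {
    cc <- cor(t(part$eigengenes))
    expect_true(all(cc[upper.tri(cc)] <= 1 - 0.25 + 1e-8))
  }
  # idempotence
  again <- merge_close_modules(expr, part$assignment)
  expect_identical(again$assignment, part$assignment)
  # eigengene orientation: members correlate positively on average
  for (col in part$colors) {
    genes <- names(part$assignment)[part$assignment == col]
    mean_r <- mean(apply(expr[genes, , drop = FALSE], 1,
                         function(g) cor(g, part$eigengenes[col, ])))
    expect_gte(mean_r, 0)
  }
})

test_that("color assignment is deterministic, size-ordered and collision-free", {
  # single module gets the first palette color
  a1 <- stats::setNames(c(1L, 1L, 0L), c("g1", "g2", "g3"))
  expect_identical(unname(assign_colors(a1)["1"]), module_palette()[1L])

  # equal-size tie broken by smallest member gene, stable across runs
  a2 <- stats::setNames(c(2L, 2L, 1L, 1L), c("b1", "b2", "a1", "a2"))
  c2 <- assign_colors(a2)
  expect_identical(unname(c2["1"]), module_palette()[1L])  # "a" module first
  expect_identical(unname(c2["2"]), module_palette()[2L])
  expect_identical(c2, assign_colors(a2))

  # 42 modules: unique names, ordered by size
  set.seed(61)
  sizes <- sample(5:60, 42, replace = TRUE)
  a3 <- stats::setNames(rep(seq_len(42), sizes),
                        sprintf("G%04d", seq_len(sum(sizes))))
  c3 <- assign_colors(a3)
  expect_length(unique(c3), 42L)
  ord <- order(-sizes)
  expect_identical(unname(c3[as.character(ord)]),
                   module_palette()[seq_len(42)])

  # palette overflow extends with numbered names
  a4 <- stats::setNames(rep(seq_len(65), each = 2), sprintf("G%04d", 1:130))
  expect_length(unique(assign_colors(a4)), 65L)
})
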