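strict3 <- function() {
  # d(a,b) < d(a,c) < d(b,c)
  d <- matrix(c(0, 0.1, 0.2,
                0.1, 0, 0.3,
                0.2, 0.3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d
}

test_that("distance ranks follow the strict ordering and midrank conventions", {
  R <- distance_ranks(strict3())
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], 2)
  expect_equal(R["b", "c"], 3)
  expect_true(all(is.na(diag(R))))

  # all distances equal, n = 4: every rank is the midrank (M + 1) / 2 = 3.5
  d4 <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d4) <- 0
  R4 <- distance_ranks(d4)
  expect_true(all(R4[upper.tri(R4)] == 3.5))

  set.seed(103)
  d <- random_distance(15)
  R <- distance_ranks(d)
  # independent argsort oracle on the upper triangle
  ut <- upper.tri(d)
  ord <- order(d[ut])
  expect_equal(R[ut][ord], seq_along(ord))      # tie-free: ranks are 1..M
  expect_equal(sum(R[ut]), (105 * 106) / 2)
  expect_error(distance_ranks(matrix(0, 1, 1)), "at least 2")
})

test_that("avgRank reproduces the worked example and its algebraic identities", {
  scores <- avg_rank(distance_ranks(strict3()))
  expect_equal(unname(scores), c(1.5, 2.0, 2.5))
  expect_equal(sum(scores), 3 * 4 / 2)

  # all-equal distances: every gene scores (n + 1) / 2
  for (n in c(4, 9)) {
    d <- matrix(0.5, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
    diag(d) <- 0
    expect_equal(unname(avg_rank(distance_ranks(d))), rep((n + 1) / 2, n))
  }

  # tie-free random modules: sum identity n(n+1)/2
  set.seed(107)
  for (n in c(5, 15, 40)) {
    d <- random_distance(n)
    scores <- avg_rank(distance_ranks(d))
    expect_equal(sum(scores), n * (n + 1) / 2, tolerance = 1e-9)
  }
})

test_that("avgRank depends only on distance ranks and its minimizer is the rank-sum minimizer", {
  set.seed(109)
  d <- random_distance(20)
  s1 <- avg_rank(distance_ranks(d))
  # strictly monotone transform of distances leaves avgRank unchanged
  s2 <- avg_rank(distance_ranks(sqrt(d) + d^3))
  expect_equal(s1, s2, tolerance = 1e-12)
  R <- distance_ranks(d)
  expect_identical(names(which.min(s1)), names(which.min(rowSums(R, na.rm = TRUE))))
})

test_that("hub rule includes the top gene and the strict <1 band", {
  scores <- stats::setNames(c(1.5, 2.0, 2.5), c("a", "b", "c"))
  expect_identical(hub_genes(scores), c("a", "b"))   # 2.5 - 1.5 = 1 not < 1
  expect_identical(hub_genes(stats::setNames(rep(3, 4), letters[1:4])),
                   letters[1:4])                     # all equal: all hubs
  lone <- stats::setNames(c(1, 2.5, 3, 4), letters[1:4])
  expect_identical(hub_genes(lone), "a")             # isolated minimum
})

test_that("module hub table is sorted, complete and flags hubs", {
  set.seed(113)
  d <- random_distance(25)
  tab <- module_hubs(d, rownames(d))
  expect_identical(nrow(tab), 25L)
  expect_false(is.unsorted(tab$avg_rank))
  expect_true(tab$is_hub[1L])
  expect_error(module_hubs(d, c(rownames(d), "nope")), "absent")
})

test_that("a clearly least-noisy gene is recovered as hub across seeds", {
  # one latent profile, constant loading, per-gene noise; gene 1 has far less
  # noise than its 29 co-members, so it is reliably the most central gene
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    m <- 60
    latent <- rnorm(m)
    noise_sd <- c(0.25, rep(1, 29))
    expr <- t(sapply(seq_len(30), function(i) {
      0.8 * latent + rnorm(m, sd = noise_sd[i])
    }))
    dimnames(expr) <- list(sprintf("G%02d", 1:30), sprintf("S%02d", 1:m))
    net <- build_network(expr, beta = 14)
    tab <- module_hubs(tom_distance(net$tom), rownames(expr))
    if ("G01" %in% tab$gene[tab$is_hub]) hits <- hits + 1
  }
  expect_gte(hits, 18L)   # >= 90% of 20 seeds
})

test_that("module page assembles traits, enrichment and the ranked gene table", {
  bm <- build_benchmark()
  bundle <- bm$bundle
  bundle$term_dbs <- list(bp = generate_term_db(bm$data$truth, seed = 11L))
  col <- bundle$partition$colors[1L]
  page <- module_page(bundle, col)
  n_genes <- sum(bundle$partition$assignment == col)
  expect_identical(page$n_genes, n_genes)
  expect_length(page$genes, n_genes)
  av <- vapply(page$genes, function(g) g$avg_rank, 0)
  expect_false(is.unsorted(av))
  expect_true(any(vapply(page$genes, function(g) g$is_hub, TRUE)))
  expect_named(page$enrichment, "bp")
  expect_error(module_page(bundle, "nope"), "unknown module color")
})
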