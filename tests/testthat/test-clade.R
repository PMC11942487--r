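test_that("default clade picks the ancestor closest to the target size", {
  tree <- tree_with_ancestor_counts(c(2, 10, 24, 30, 200))
  clade <- default_clade(tree, "G001")
  expect_length(clade$genes, 24L)
  expect_identical(clade$k_internal, 3L)
  expect_true("G001" %in% clade$genes)

  # tie |20-25| = |30-25| resolves to the smaller clade
  tie <- tree_with_ancestor_counts(c(20, 30))
  expect_length(default_clade(tie, "G001")$genes, 20L)

  # two-leaf tree: the whole tree is the only ancestor
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- average_linkage(d2)
  expect_setequal(default_clade(t2, "A")$genes, c("A", "B"))
  expect_error(default_clade(t2, "Z"), "unknown driver")
})

test_that("default clade choice is optimal over the whole ancestor chain", {
  set.seed(83)
  for (rep in 1:40) {
    tree <- random_tree(200)
    driver <- sample(tree$labels, 1)
    clade <- default_clade(tree, driver)
    idx <- coexclade:::dendro_index(tree)
    sizes <- idx$leaf_count[ancestors(tree, driver)]
    expect_identical(abs(length(clade$genes) - 25L), min(abs(sizes - 25L)))
    # tie rule: no smaller ancestor clade achieves the same deviation
    same <- sizes[abs(sizes - 25L) == min(abs(sizes - 25L))]
    expect_identical(length(clade$genes), min(same))
  }
})

test_that("resize is nested, monotone and respects the 25% expansion cap", {
  tree <- tree_with_ancestor_counts(c(2, 10, 24, 26, 60, 100))
  cap <- ceiling(0.25 * 100)
  # k = 1: driver plus sibling subtree
  expect_length(resize_clade(tree, "G001", 1L)$genes, 2L)
  # request hitting the 60-leaf ancestor is pushed back under the cap (25)
  res <- resize_clade(tree, "G001", 5L)
  expect_length(res$genes, 24L)
  expect_true(res$truncated)
  expect_lte(length(res$genes), cap)
  # k beyond depth clamps, flagged
  deep <- resize_clade(tree, "G001", 99L)
  expect_true(deep$truncated)
  expect_lte(length(deep$genes), cap)

  set.seed(87)
  for (rep in 1:20) {
    rt <- random_tree(200)
    driver <- sample(rt$labels, 1)
    depth <- length(ancestors(rt, driver))
    prev <- character(0)
    for (k in seq_len(depth)) {
      cl <- resize_clade(rt, driver, k)
      expect_true(all(prev %in% cl$genes))       # leaves(k) subset leaves(k+1)
      expect_lte(length(cl$genes), ceiling(0.25 * 200))
      prev <- cl$genes
    }
  }
})

test_that("default clade equals resize at its own internal-node count", {
  set.seed(89)
  tree <- random_tree(120)
  driver <- sample(tree$labels, 1)
  dc <- default_clade(tree, driver)
  rc <- resize_clade(tree, driver, dc$k_internal, max_fraction = 1)
  expect_identical(dc$genes, rc$genes)
})

test_that("query payload carries the clade, module colors and optional enrichment", {
  bm <- build_benchmark()
  db <- generate_term_db(bm$data$truth, seed = 5L)
  bundle <- bm$bundle
  bundle$term_dbs <- list(bp = db)
  driver <- names(bm$data$truth$modules)[bm$data$truth$modules == 1][1]

  # no category: payload has no enrichment block, no error
  p0 <- api_payload(bundle, driver)
  expect_null(p0$enrichment)
  expect_identical(p0$driver$id, driver)
  # unknown category keyword: enrichment silently omitted
  expect_null(api_payload(bundle, driver, category = "zz")$enrichment)

  # loaded category: enrichment present and sorted by adjusted p ascending
  p1 <- api_payload(bundle, driver, category = "bp")
  expect_false(is.null(p1$enrichment))
  qs <- vapply(p1$enrichment$table, function(r) r$q, 0)
  expect_false(is.unsorted(qs))

  # payload newick reparses to exactly the payload gene list
  reparsed <- parse_newick(p1$clade$newick)
  ids <- vapply(p1$genes, function(g) g$id, "")
  expect_setequal(reparsed$labels, ids)
  # every clade gene carries exactly one module color
  cols <- vapply(p1$genes, function(g) g$module, "")
  expect_true(all(nzchar(cols)))

  # unknown driver: structured error document, not an exception
  perr <- api_payload(bundle, "AT9G99999")
  expect_match(perr$error, "unknown driver")
})
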