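test_that("pearson_matrix handles exact duplicates, negations, and matches a naive oracle", {
  set.seed(11)
  x <- matrix(rnorm(5 * 50), 5, 50,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:50)))
  x[2, ] <- x[1, ]          # duplicate
  x[3, ] <- -x[1, ]         # negation
  r <- pearson_matrix(x)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_lt(max(abs(r - naive_pearson(x))), 1e-12)

  x[4, ] <- 7               # constant gene
  expect_error(pearson_matrix(x), "zero-variance.*G4")
})

test_that("signed adjacency closed forms and monotonicity hold", {
  r <- matrix(c(1, -1, 0, 1), 2, 2)  # entries -1, 0, 1
  expect_equal(signed_adjacency(matrix(1), 14), matrix(1))
  expect_equal(signed_adjacency(matrix(-1), 14), matrix(0))
  expect_equal(signed_adjacency(matrix(0), 14), matrix(2^-14))
  for (beta in c(1, 6, 14)) {
    grid <- seq(-1, 1, by = 0.05)
    a <- signed_adjacency(matrix(grid, 1), beta)
    expect_true(all(diff(as.numeric(a)) > 0))   # strictly monotone in r
    expect_true(all(a >= 0 & a <= 1))
  }
  expect_error(signed_adjacency(matrix(0.5), 0.5), "beta")
  expect_error(signed_adjacency(matrix(1.5), 2), "\\[-1, 1\\]")
})

test_that("scale-free fit index recovers perfect fits with the sign convention", {
  # construct connectivities whose binned log-log histogram is exactly linear:
  # place points at bin centers with counts following a power law
  k_centers <- c(1, 2, 4, 8)
  counts <- c(64, 16, 4, 1)          # log10(freq) linear in log10(k), slope < 0
  konn <- rep(k_centers, counts)
  fit <- scale_free_fit(konn, n_bins = 8)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  expect_lt(fit$slope, 0)

  fit_pos <- scale_free_fit(rep(k_centers, rev(counts)), n_bins = 8)
  expect_equal(fit_pos$r_squared, -1.0, tolerance = 1e-9)
  expect_error(scale_free_fit(rep(3, 10)), "degenerate")
})

test_that("scale-free fit matches an independent binned regression", {
  set.seed(7)
  konn <- as.numeric(sample(1:50, 200, replace = TRUE, prob = (1:50)^-1.8))
  fit <- scale_free_fit(konn, n_bins = 10)
  # independent reimplementation
  breaks <- seq(min(konn), max(konn), length.out = 11)
  b <- cut(konn, breaks, include.lowest = TRUE)
  km <- tapply(konn, b, mean); fr <- tapply(konn, b, length) / length(konn)
  ok <- !is.na(km)
  co <- stats::coef(summary(stats::lm(log10(fr[ok]) ~ log10(km[ok]))))
  r2 <- summary(stats::lm(log10(fr[ok]) ~ log10(km[ok])))$r.squared
  expect_equal(fit$r_squared, -sign(co[2, 1]) * r2, tolerance = 1e-9)
  expect_equal(fit$slope, unname(co[2, 1]), tolerance = 1e-9)
})

test_that("soft-threshold power selection behaves and is forced by a single candidate", {
  set.seed(21)
  d <- generate(synth_config(n_modules = 3, genes_per_module = 40,
                             n_background_genes = 30, seed = 21),
                check_separation = FALSE)
  pick <- pick_soft_threshold(d$expr, powers = c(1, 2, 4, 6, 8, 10, 14))
  expect_s3_class(pick, "power_scan")
  expect_true(all(diff(pick$table$k_mean) < 0))       # mean connectivity decreasing
  expect_true(pick$beta %in% pick$table$power)
  if (pick$reached_cut) {
    reached <- pick$table$power[pick$table$r_squared >= 0.85]
    expect_equal(pick$beta, min(reached))
  }
  forced <- pick_soft_threshold(d$expr, powers = 5)
  expect_equal(forced$beta, 5)
  expect_error(pick_soft_threshold(d$expr[1:5, ]), "fewer than 10")
})

test_that("TOM similarity matches the closed forms and the triple-loop oracle", {
  # no shared neighbors: off-diagonal zero
  a0 <- diag(1, 6)
  t0 <- tom_similarity(a0)
  expect_equal(t0, diag(1, 6))
  # complete graph: TOM is exactly 1 everywhere
  a1 <- matrix(1, 5, 5)
  expect_equal(tom_similarity(a1), matrix(1, 5, 5))

  set.seed(33)
  for (n in c(10, 30)) {
    a <- random_adjacency(n)
    tom <- tom_similarity(a)
    expect_lt(max(abs(tom - tom_loop_oracle(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(unname(tom)))
  }
  bad <- random_adjacency(5); bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(tom_similarity(bad), "not symmetric")
})

test_that("blocked TOM equals the unblocked computation", {
  set.seed(5)
  a <- random_adjacency(57)
  # BLAS accumulation order varies with operand shape, so agreement is to
  # floating-point rounding, not bitwise
  expect_lt(max(abs(tom_similarity(a, block_size = 8L) -
                    tom_similarity(a, block_size = 1000L))), 1e-13)
})

test_that("duplicated genes produce an all-ones TOM block", {
  set.seed(9)
  base <- rnorm(40)
  expr <- rbind(G1 = base, G2 = base, G3 = base,
                G4 = rnorm(40), G5 = rnorm(40), G6 = rnorm(40))
  colnames(expr) <- paste0("S", 1:40)
  net <- build_network(expr, beta = 14)
  # cross-adjacency to the unrelated genes is ~0.5^14, which perturbs the
  # duplicate block's TOM away from exactly 1 by O(adjacency); at beta = 14
  # the block is 1 to well under 1e-3
  expect_lt(max(abs(net$tom[1:3, 1:3] - 1)), 1e-3)
  # with the duplicates alone the block is exactly complete: TOM identically 1
  net_only <- build_network(expr[1:3, ], beta = 14)
  expect_lt(max(abs(net_only$tom - 1)), 1e-10)
})

test_that("TOM distance is the exact complement of TOM similarity", {
  set.seed(13)
  tom <- tom_similarity(random_adjacency(12))
  d <- tom_distance(tom)
  expect_equal(unname(d + tom), matrix(1, 12, 12) , tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 12))
})
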