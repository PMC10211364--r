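test_that("Bray-Curtis handles identity, disjoint support and known cases", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(bray_curtis(c(3, 0, 0), c(0, 1, 2)), 0)
  expect_equal(bray_curtis(c(10, 0, 5), c(5, 5, 5)), 2 / 3)
  expect_error(bray_curtis(c(0, 0), c(1, 1)), "all-zero")
  expect_error(bray_curtis(1:3, 1:4), "equal length")

  # joint rescaling is neutral; one-sided rescaling is not
  for (seed in 1:10) {
    x <- withr::with_seed(seed, stats::rexp(6))
    y <- withr::with_seed(seed + 50, stats::rexp(6))
    expect_equal(bray_curtis(3 * x, 3 * y), bray_curtis(x, y),
                 tolerance = 1e-12)
    expect_false(isTRUE(all.equal(bray_curtis(3 * x, y),
                                  bray_curtis(x, y))))
  }
})

test_that("similarity matrix agrees with vegan and is structurally sound", {
  m <- thornscrub_abundance()
  sim <- similarity_matrix(m)
  expect_true(isSymmetric(unclass(sim)))
  expect_equal(unname(diag(sim)), rep(1, 4))
  expect_true(all(sim >= 0 & sim <= 1))

  veg <- 1 - as.matrix(vegan::vegdist(unclass(m), method = "bray"))
  diag(veg) <- 1
  expect_equal(unclass(sim), veg, tolerance = 1e-12, ignore_attr = TRUE)

  # permuting species columns changes nothing
  perm <- m[, rev(colnames(m))]
  expect_equal(unclass(similarity_matrix(perm)), unclass(sim),
               tolerance = 1e-12)
  expect_error(similarity_matrix(m[1, , drop = FALSE]), "two sites")
})

test_that("UPGMA matches the brute-force average-linkage oracle", {
  # two labels: one node at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 0.4)

  for (seed in 1:6) {
    n <- sample(3:6, 1)
    dmat <- withr::with_seed(seed, {
      m <- matrix(stats::runif(n * n, 0.1, 1), n)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      dimnames(m) <- list(letters[1:n], letters[1:n])
      m
    })
    tree <- upgma(dmat)
    coph <- as.matrix(stats::cophenetic(tree))
    oracle <- brute_upgma_cophenetic(dmat)
    expect_equal(coph[letters[1:n], letters[1:n]], oracle,
                 tolerance = 1e-12)
    # ultrametric triple inequality on the tree distances
    for (trip in utils::combn(n, 3, simplify = FALSE)) {
      ds <- sort(c(coph[trip[1], trip[2]], coph[trip[1], trip[3]],
                   coph[trip[2], trip[3]]), decreasing = TRUE)
      expect_lte(ds[1], ds[2] + 1e-12)
    }
  }

  # an ultrametric input is a fixed point: cophenetic == input
  base <- upgma(stats::as.dist(matrix(c(0, .2, .9, .2, 0, .9,
                                        .9, .9, 0), 3,
                                      dimnames = list(letters[1:3],
                                                      letters[1:3]))))
  ultra <- as.matrix(stats::cophenetic(base))
  expect_equal(as.matrix(stats::cophenetic(upgma(ultra))), ultra,
               tolerance = 1e-12)

  asym <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(upgma(asym), "symmetric")
})

test_that("the published distance matrix yields the known merge heights", {
  d <- stats::as.dist(1 - published_similarity())
  tree <- upgma(d)
  expect_equal(tree$height,
               c(0.292, mean(c(0.590, 0.401)),
                 mean(c(0.855, 0.814, 0.745))),
               tolerance = 1e-9)
  # merge order: (10,20), then +30, then +>30
  expect_identical(stats::cutree(tree, 2)[[">30"]] !=
                     stats::cutree(tree, 2)[["10"]], TRUE)
  expect_identical(unname(stats::cutree(tree, 3)[c("10", "20")]),
                   c(1L, 1L))
})

test_that("cophenetic correlation is 1 for ultrametric input, NA for pairs", {
  d <- stats::as.dist(matrix(c(0, .2, .9, .2, 0, .9, .9, .9, 0), 3,
                             dimnames = list(letters[1:3], letters[1:3])))
  tree <- upgma(d)
  ultra <- stats::cophenetic(tree)
  expect_equal(cophenetic_correlation(upgma(ultra), ultra), 1,
               tolerance = 1e-12)
  expect_warning(r <- cophenetic_correlation(
    upgma(matrix(c(0, .3, .3, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))),
    matrix(c(0, .3, .3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))),
    "undefined")
  expect_true(is.na(r))

  # invariant to relabelling
  m <- thornscrub_abundance()
  d1 <- similarity_to_dist(similarity_matrix(m))
  perm <- m[c(3, 1, 4, 2), ]
  d2 <- similarity_to_dist(similarity_matrix(perm))
  expect_equal(cophenetic_correlation(upgma(d2), d2),
               cophenetic_correlation(upgma(d1), d1), tolerance = 1e-12)
})

test_that("bootstrap support is deterministic and finds stable splits", {
  m <- thornscrub_abundance()
  b1 <- branch_support(m, n_reps = 99, seed = 7)
  b2 <- branch_support(m, n_reps = 99, seed = 7)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))

  single <- branch_support(m, n_reps = 1, seed = 2)
  expect_true(all(single$support %in% c(0, 100)))

  # two blocks of duplicated columns: the block split survives every
  # resample (degenerate all-zero rows are redrawn)
  block <- abundance_matrix(matrix(
    c(5, 5, 0, 0,
      3, 3, 0, 0,
      0, 0, 4, 4,
      0, 0, 6, 6), nrow = 4,
    dimnames = list(c("A", "B", "C", "D"), paste0("sp", 1:4))))
  bs <- branch_support(block, n_reps = 50, seed = 5)
  expect_equal(unname(bs$support), rep(100, ape::Nnode(
    ape::as.phylo(bs$tree))))

  nwk <- write_newick(bs)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "100")
})
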