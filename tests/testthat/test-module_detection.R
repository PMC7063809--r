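test_that("TOM dissimilarity is the off-diagonal complement", {
  set.seed(20)
  tom <- topological_overlap(random_adjacency(12))
  d <- tom_dissimilarity(tom)
  off <- upper.tri(d)
  expect_equal(d[off] + tom[off], rep(1, sum(off)), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 12))
  expect_equal(d[2, 5], 1 - tom[2, 5])
})

test_that("average-linkage heights match a naive O(n^3) oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 12
    d <- matrix(runif(n * n), n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    dend <- hierarchical_cluster(d)
    expect_equal(dend$height, average_linkage_heights_oracle(d),
                 tolerance = 1e-10)
  }
  expect_error(hierarchical_cluster(matrix(0, 2, 3)), "square")
})

test_that("well-separated blocks cluster cleanly with a final top merge", {
  d <- matrix(1, 10, 10)
  d[1:5, 1:5] <- 0.05
  d[6:10, 6:10] <- 0.05
  diag(d) <- 0
  dimnames(d) <- list(letters[1:10], letters[1:10])
  dend <- hierarchical_cluster(d)
  expect_equal(max(dend$height), 1)
  expect_setequal(unname(stats::cutree(dend, k = 2)[1:5]),
                  unname(rep(stats::cutree(dend, k = 2)[1], 5)))
})

test_that("dynamic cut separates perfect blocks and enforces the size floor", {
  ## two tight blocks over a loose background
  set.seed(22)
  n <- 60
  d <- matrix(runif(n * n, 0.95, 1), n)
  d <- (d + t(d)) / 2
  d[1:20, 1:20] <- 0.05
  d[21:40, 21:40] <- 0.05
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  dend <- hierarchical_cluster(d)
  labels <- cut_tree_dynamic(dend, d, min_module_size = 10)
  expect_equal(length(unique(labels[1:20])), 1L)
  expect_equal(length(unique(labels[21:40])), 1L)
  expect_true(all(labels[1:20] > 0))
  expect_false(labels[1] == labels[21])
  expect_true(all(labels[41:60] == 0))

  ## a single block below the floor dissolves to grey
  d2 <- matrix(runif(400, 0.95, 1), 20)
  d2 <- (d2 + t(d2)) / 2
  d2[1:8, 1:8] <- 0.05                      # 8 < min_module_size
  diag(d2) <- 0
  dimnames(d2) <- list(sprintf("h%02d", 1:20), sprintf("h%02d", 1:20))
  lab2 <- cut_tree_dynamic(hierarchical_cluster(d2), d2,
                           min_module_size = 10)
  expect_true(all(lab2 == 0))

  expect_warning(cut_tree_dynamic(dend, d, min_module_size = 100),
                 "exceeds")
})

test_that("planted modules are recovered on simulated expression", {
  ## moderate cohort size so assignment noise stays small
  hits <- vapply(1:12, function(s) {
    d <- planted_dataset(400 + s, n_samples = 100)
    tom <- topological_overlap(adjacency(pairwise_correlation(d$expr), 7))
    part <- detect_modules(d$expr, tom)
    adjusted_rand_index(d$truth$planted_labels, part$labels)
  }, 0)
  expect_gte(mean(hits >= 0.9), 0.9)
})

test_that("merging fuses modules driven by one factor and respects the height", {
  set.seed(23)
  n <- 30
  f <- rnorm(n)
  lam <- sqrt(0.9)
  expr <- rbind(
    t(sapply(1:20, function(i) lam * f + sqrt(1 - lam^2) * rnorm(n))),
    t(sapply(1:20, function(i) lam * f + sqrt(1 - lam^2) * rnorm(n))),
    t(sapply(1:20, function(i) rnorm(n))))   # independent third module
  rownames(expr) <- sprintf("g%02d", 1:60)
  colnames(expr) <- sprintf("S%d", 1:n)
  labels <- stats::setNames(rep(c(1L, 2L, 3L), each = 20), rownames(expr))
  part <- merge_close_modules(expr, labels, merge_cut_height = 0.25)
  ## the two same-factor modules fuse; the independent one survives
  expect_equal(length(part$sizes), 2L)
  expect_equal(unname(part$labels[1]), unname(part$labels[21]))
  expect_false(part$labels[1] == part$labels[41])
  ## after merging no eigengene pair is closer than the cut height
  eig <- eigengene_set(expr, part)
  ec <- stats::cor(t(eig$eigengenes))
  expect_true(all(1 - ec[upper.tri(ec)] >= 0.25))
})

test_that("chain merging matches an exhaustive small-instance oracle", {
  ## three modules with eigengene correlations ~ (0.9, 0.9, ~0.1+):
  ## the 0.9 pairs chain-merge into one module
  set.seed(24)
  n <- 40
  f1 <- rnorm(n)
  f2 <- 0.9 * f1 + sqrt(1 - 0.81) * rnorm(n)
  f3 <- rnorm(n)
  mk <- function(f, k = 15) t(sapply(seq_len(k), function(i)
    sqrt(0.95) * f + sqrt(0.05) * rnorm(n)))
  expr <- rbind(mk(f1), mk(f2), mk(f3))
  rownames(expr) <- sprintf("g%02d", 1:45)
  colnames(expr) <- sprintf("S%d", 1:n)
  labels <- stats::setNames(rep(1:3, each = 15), rownames(expr))
  part <- merge_close_modules(expr, labels)
  expect_equal(length(part$sizes), 2L)
  expect_equal(unname(part$labels[1]), unname(part$labels[16]))
  expect_false(part$labels[1] == part$labels[31])
  expect_error(merge_close_modules(expr, labels, merge_cut_height = 0),
               "merge_cut_height")
})

test_that("module colors follow the size-ranked standard sequence", {
  labels <- stats::setNames(rep(c(1L, 2L, 3L), c(100, 50, 30)),
                            sprintf("g%03d", 1:180))
  cmap <- assign_colors(labels)
  expect_identical(unname(cmap[c("1", "2", "3")]),
                   c("turquoise", "blue", "brown"))
  expect_identical(unname(cmap["0"]), "grey")
  ## 9th largest is magenta, 22nd is darkgreen
  expect_identical(module_colors()[9], "magenta")
  expect_identical(module_colors()[22], "darkgreen")
  ## no modules: only grey
  none <- assign_colors(stats::setNames(rep(0L, 5), letters[1:5]))
  expect_identical(unname(none), "grey")
  ## beyond the palette: numbered fallback
  big <- stats::setNames(rep(1:40, each = 2), sprintf("g%02d", 1:80))
  cmap40 <- assign_colors(big)
  expect_true(any(grepl("^module", cmap40)))
})

test_that("partitions are size-consistent and cover every gene once", {
  d <- planted_dataset(26, n_samples = 40, sizes = c(25, 35), wmc = 0.8,
                       n_background = 60)
  tom <- topological_overlap(adjacency(pairwise_correlation(d$expr), 7))
  part <- detect_modules(d$expr, tom)
  expect_equal(length(part$labels), nrow(d$expr))
  expect_true(all(part$sizes >= 10))
  expect_equal(sum(part$sizes) + sum(part$labels == 0), nrow(d$expr))
  expect_identical(unname(part$colors[part$labels == 0][1]), "grey")
})

test_that("noiseless planted data is recovered exactly", {
  d <- planted_dataset(27, wmc = 1, n_background = 0)
  tom <- topological_overlap(adjacency(pairwise_correlation(d$expr), 7))
  part <- detect_modules(d$expr, tom)
  expect_equal(adjusted_rand_index(d$truth$planted_labels, part$labels), 1)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(28)
  for (rep in 1:20) {
    a <- sample(0:4, 60, replace = TRUE)
    b <- sample(0:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
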