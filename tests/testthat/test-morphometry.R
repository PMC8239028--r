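test_that("SWC reading validates structure and round-trips coordinates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cable.swc")
  writeLines(c("# comment line",
               "1 1 0 0 0 1 -1",
               "2 3 50.123456 0 0 1 1",
               "3 3 100 0 0 1 2"), p)
  tree <- read_swc(p)
  expect_equal(nrow(tree$nodes), 3)
  expect_equal(tree$root, 1)
  expect_equal(compute_metrics(tree)$n_bifurcations, 0)
  # round trip preserves coordinates
  p2 <- file.path(dir, "copy.swc")
  write_swc(tree, p2)
  back <- read_swc(p2)
  expect_equal(back$nodes$x, tree$nodes$x, tolerance = 1e-6)
  # dangling parent
  pbad <- file.path(dir, "bad.swc")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1 9"), pbad)
  expect_error(read_swc(pbad), "undeclared parent 9")
  # multiple roots
  proot <- file.path(dir, "roots.swc")
  writeLines(c("1 1 0 0 0 1 -1", "2 1 1 0 0 1 -1"), proot)
  expect_error(read_swc(proot), "exactly one root")
  # cycle
  expect_error(as_neuron_tree(data.frame(
    id = 1:3, type = c(1, 3, 3), x = 0, y = 0, z = 0, radius = 1,
    parent = c(-1, 3, 2))), "cycle")
})

test_that("morphometric features match hand geometry", {
  cable <- straight_cable_tree()
  m <- compute_metrics(cable)
  expect_equal(m$width, 100)
  expect_equal(m$n_bifurcations, 0)
  expect_equal(m$contraction, 1.0)
  expect_equal(m$branch_path_length, 100)
  # right-angle branch: two 50 um segments, chord 50*sqrt(2)
  ra <- compute_metrics(right_angle_tree())
  expect_equal(ra$contraction, sqrt(2) / 2, tolerance = 1e-12)
  # Y tree: one bifurcation, width spans the two tips
  y <- compute_metrics(y_tree())
  expect_equal(y$n_bifurcations, 1)
  expect_equal(y$width, 60)
  expect_equal(y$n_branches, 3)
  # multifurcation counts once
  multi <- as_neuron_tree(data.frame(
    id = 1:5, type = c(1, 3, 3, 3, 3),
    x = c(0, 0, 10, -10, 5), y = c(0, 10, 20, 20, 20), z = 0,
    radius = 1, parent = c(-1, 1, 2, 2, 2)))
  expect_equal(compute_metrics(multi)$n_bifurcations, 1)
  expect_error(compute_metrics(as_neuron_tree(data.frame(
    id = 1:2, type = c(1, 3), x = 0, y = 0, z = 0, radius = 1,
    parent = c(-1, 1)))), "degenerate")
})

test_that("features are invariant under rigid translation", {
  tree <- y_tree()
  shifted <- tree
  shifted$nodes$x <- shifted$nodes$x + 123
  shifted$nodes$y <- shifted$nodes$y - 45
  shifted$nodes$z <- shifted$nodes$z + 7
  m0 <- compute_metrics(tree); m1 <- compute_metrics(shifted)
  for (f in c("width", "n_bifurcations", "branch_path_length", "contraction"))
    expect_equal(m1[[f]], m0[[f]], label = f)
  # width ignores the other two axes
  tall <- tree; tall$nodes$y <- tall$nodes$y * 10
  expect_equal(compute_metrics(tall)$width, m0$width)
})

test_that("sholl counts sphere crossings from the soma", {
  cable <- straight_cable_tree()
  expect_equal(unname(sholl(cable, seq(10, 90, by = 10))), rep(1L, 9))
  expect_equal(unname(sholl(cable, 150)), 0L)
  y <- y_tree()  # bifurcates 50 um from the soma
  expect_equal(unname(sholl(y, c(25, 70))), c(1L, 2L))
  # nonincreasing beyond the arbor extent and zero past it
  withr::with_seed(11, tr <- generate_neurons("SC.cl", "RE", 1, seed = 6)[[1]])
  d_max <- max(sqrt(rowSums(tr$nodes[, c("x", "y", "z")]^2)))
  radii <- seq(d_max, d_max * 2, length.out = 5)
  expect_equal(unname(sholl(tr, radii[-1])), rep(0L, 4))
})

test_that("PCA scores match a direct eigendecomposition oracle", {
  withr::with_seed(13, {
    rec <- data.frame(width = rnorm(20, 100, 20),
                      n_bifurcations = rpois(20, 8),
                      branch_path_length = rnorm(20, 60, 10),
                      contraction = runif(20, 0.7, 1))
  })
  p <- morpho_pca(rec)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  X <- scale(as.matrix(rec))
  eig <- eigen(stats::cov(X))
  scores_oracle <- X %*% eig$vectors
  for (k in 1:4) {
    expect_equal(abs(p$scores[, k]), abs(scores_oracle[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)  # up to sign
  }
  # two distinct points: PC1 carries everything
  two <- data.frame(width = c(1, 2, 1), n_bifurcations = c(1, 2, 1),
                    branch_path_length = c(3, 4, 3), contraction = c(0.5, 0.9, 0.5))
  p2 <- morpho_pca(two)
  expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-9)
  # zero-variance feature dropped with a warning
  rec$contraction <- 1
  expect_warning(p3 <- morpho_pca(rec), "zero-variance")
  expect_equal(ncol(p3$scores), 3)
})

test_that("group comparisons use exact Wilcoxon and BH correction", {
  rec <- data.frame(group = rep(c("g1", "g2"), each = 3),
                    width = c(1, 2, 3, 10, 20, 30))
  out <- group_compare(rec, parameters = "width")
  # exact two-sided p for complete separation of 3 vs 3: 2/choose(6,3)
  expect_equal(out$p_raw, 0.1)
  expect_true(all(out$p_adjusted >= out$p_raw))
  # all-equal tied groups: statistic at the null center
  tied <- data.frame(group = rep(c("g1", "g2"), each = 4), width = 5)
  expect_equal(group_compare(tied, parameters = "width")$p_raw, 1)
  # BH monotonicity across many tests
  withr::with_seed(14, {
    rec2 <- data.frame(group = rep(c("a", "b", "c", "d"), each = 6),
                       width = rnorm(24), n_bifurcations = rnorm(24),
                       branch_path_length = rnorm(24), contraction = rnorm(24))
  })
  out2 <- group_compare(rec2)
  ord <- order(out2$p_raw)
  expect_true(all(diff(out2$p_adjusted[ord]) >= -1e-12))
  expect_identical(out2$significant, out2$p_adjusted < 0.05)
  # under-sized groups excluded and flagged
  rec3 <- rbind(rec, data.frame(group = "tiny", width = 1))
  out3 <- group_compare(rec3, parameters = "width")
  expect_equal(attr(out3, "excluded_groups"), "tiny")
})
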