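test_that("weight matrix reproduces planted counts and marginalizes over layers", {
  counts <- data.frame(
    roi_name = c("A", "A", "B"),
    level = c(90L, 96L, 90L),
    zone = c("SC.m", "SC.m", "SC.cl"),
    layer = c("sg", "ig", "dg"),
    count = c(10, 5, 7))
  wz <- build_weight_matrix(counts, "zone")
  expect_equal(wz["A", "SC.m"], 15)  # summed over levels
  expect_equal(wz["B", "SC.cl"], 7)
  expect_equal(sum(wz), 22)
  wzl <- build_weight_matrix(counts, "zone_layer")
  expect_equal(wzl["A", "SC.m.sg"], 10)
  expect_equal(wzl["A", "SC.m.ig"], 5)
  # zone granularity equals zone x layer summed over layers
  for (z in SC_ZONES) {
    cols <- grep(paste0("^", z, "\\."), colnames(wzl))
    expect_equal(rowSums(wzl[, cols, drop = FALSE]), wz[, z])
  }
  # an empty case contributes an all-zero row
  counts0 <- rbind(counts, data.frame(roi_name = "C", level = 90L,
                                      zone = "SC.m", layer = "sg", count = 0))
  expect_equal(sum(build_weight_matrix(counts0, "zone")["C", ]), 0)
})

test_that("overlap is the common-labeling ratio over source labeling", {
  a <- data.frame(x = 1:50, y = 1)
  b <- data.frame(x = 1:200, y = 1)
  expect_equal(overlap(a, a), 1.0)
  expect_equal(overlap(a, data.frame(x = 1:50, y = 2)), 0.0)
  expect_equal(overlap(a, b), 1.0)    # A entirely inside B
  expect_equal(overlap(b, a), 0.25)   # |A|/|B|
  expect_error(overlap(data.frame(x = integer(0), y = integer(0)), a), "empty")
})

test_that("cohort overlap matrix is a symmetrized directed ratio with unit diagonal", {
  fix <- small_cohort(seed = 5, per_zone = 2, n_px = 200)
  om <- overlap_matrix(fix$cases)
  expect_equal(unname(diag(om$directed)), rep(1, length(fix$cases)))
  expect_true(all(om$directed >= 0 & om$directed <= 1))
  expect_equal(om$symmetric, (om$directed + t(om$directed)) / 2)
  expect_equal(om$symmetric, t(om$symmetric))
})

test_that("row normalization equalizes totals and preserves proportions", {
  m <- matrix(c(60, 40, 0, 25, 15, 10), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
  nm <- normalize_totals(m)
  expect_equal(unname(rowSums(nm)), c(100, 100))
  expect_equal(nm["B", ], m["B", ] * 2)
  expect_equal(nm["A", ] / sum(nm["A", ]), m["A", ] / sum(m["A", ]),
               tolerance = 1e-12)
  # already-equal rows unchanged, zero rows flagged
  eq <- matrix(c(1, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(normalize_totals(eq)["A", ], eq["A", ], ignore_attr = TRUE)
  z <- rbind(m, Z = c(0, 0, 0))
  expect_equal(attr(normalize_totals(z), "zero_rows"), "Z")
})

test_that("modularity matches closed forms on the two-triangle graph", {
  w <- two_triangles()
  expect_equal(modularity_q(w, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_q(w, rep(1, 6)), 0)
  expect_lte(modularity_q(w, 1:6), 0)  # all singletons: no intra terms
  # agrees with the per-community summation oracle on random partitions
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- sample(1:3, 6, replace = TRUE)
      expect_equal(modularity_q(w, p), oracle_modularity(w, p))
    }
  })
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "zero total weight")
})

test_that("louvain finds exact optima on small graphs and respects baselines", {
  w <- two_triangles()
  p <- louvain(w, seed = 1)
  expect_equal(unname(p$membership), c(1, 1, 1, 2, 2, 2))
  expect_equal(p$modularity, brute_force_best_q(w))
  # fully connected uniform graph collapses to one community
  full <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(full) <- 0
  pf <- louvain(full, seed = 2)
  expect_equal(pf$n_communities, 1)
  expect_equal(pf$modularity, brute_force_best_q(full), tolerance = 1e-12)
  # Q never below the all-singletons baseline
  withr::with_seed(19, {
    for (i in 1:10) {
      g <- random_small_graph(7)
      res <- louvain(g, seed = i)
      expect_gte(res$modularity, modularity_q(g, 1:7) - 1e-12)
      expect_lte(res$modularity, brute_force_best_q(g) + 1e-12)
    }
  })
  expect_error(louvain(matrix(numeric(0), 0, 0)), "empty")
})

test_that("louvain recovers a planted two-block structure across seeds", {
  n <- 10
  w <- matrix(0.05, 2 * n, 2 * n)
  w[1:n, 1:n] <- 1
  w[(n + 1):(2 * n), (n + 1):(2 * n)] <- 1
  diag(w) <- 0
  dimnames(w) <- list(paste0("v", 1:(2 * n)), paste0("v", 1:(2 * n)))
  truth <- rep(1:2, each = n)
  for (s in 1:25) {
    p <- louvain(w, seed = s)
    expect_equal(adjusted_rand(p$membership, truth), 1,
                 label = paste("seed", s))
  }
})

test_that("louvain agrees with an independent implementation on a cohort graph", {
  skip_if_not_installed("igraph")
  fix <- small_cohort(seed = 2, per_zone = 3, n_px = 200)
  om <- overlap_matrix(fix$cases)
  w <- om$symmetric; diag(w) <- 0
  ours <- louvain(om, seed = 4)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  withr::with_seed(1, theirs <- igraph::cluster_louvain(g))
  expect_equal(adjusted_rand(ours$membership, igraph::membership(theirs)), 1)
  expect_equal(ours$modularity,
               igraph::modularity(g, igraph::membership(theirs),
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-9)
})

test_that("consensus reports the modal partition up to label permutation", {
  P <- c(a = 1, b = 1, c = 2, d = 2)
  P2 <- c(a = 1, b = 2, c = 2, d = 2)
  res <- consensus_partition(list(P, P, P, P2, P2))
  expect_equal(res$consensus$membership, c(a = 1, b = 1, c = 2, d = 2))
  expect_equal(res$mode_count, 3)
  expect_equal(res$n_runs, 5)
  expect_equal(res$n_communities_mean, 2)
  expect_equal(res$n_communities_sd, 0)
  # identical partitions
  res5 <- consensus_partition(list(P, P, P, P, P))
  expect_equal(res5$mode_count, 5)
  # label-permuted copies are the same partition
  Pperm <- c(a = 2, b = 2, c = 1, d = 1)
  resp <- consensus_partition(list(P, Pperm, Pperm))
  expect_equal(resp$mode_count, 3)
  # invariant under run order
  res_shuffled <- consensus_partition(list(P2, P, P2, P, P))
  expect_equal(res_shuffled$consensus$membership, res$consensus$membership)
  expect_error(consensus_partition(list()), "no partitions")
  expect_error(consensus_partition(list(P, c(a = 1, b = 1, c = 1))),
               "different node sets")
})

test_that("matrix reordering groups communities and preserves entries", {
  withr::with_seed(21, {
    w <- matrix(0.05, 8, 8)
    w[1:4, 1:4] <- 0.9; w[5:8, 5:8] <- 0.9
    diag(w) <- 0
    labels <- paste0("r", 1:8)
    dimnames(w) <- list(labels, labels)
    shuffle <- sample(8)
    ws <- w[shuffle, shuffle]
    part <- louvain(ws, seed = 1)
    ro <- reorder_matrix(ws, part)
    # bijection: multiset of entries preserved
    expect_equal(sort(as.vector(ro$matrix)), sort(as.vector(ws)))
    # block structure: within-block mean exceeds between-block mean
    b <- ro$block_boundaries
    blocks <- list(1:b[1], (b[1] + 1):b[2])
    within <- mean(c(ro$matrix[blocks[[1]], blocks[[1]]],
                     ro$matrix[blocks[[2]], blocks[[2]]]))
    between <- mean(ro$matrix[blocks[[1]], blocks[[2]]])
    expect_gt(within, between)
    # idempotent on already-ordered input
    part0 <- louvain(w, seed = 1)
    ro0 <- reorder_matrix(w, part0)
    expect_equal(ro0$order, 1:8)
  })
})

test_that("winner-takes-all colors cells by the dominant community", {
  atlas <- build_default_atlas()
  lvl <- atlas$`90`
  mkcase <- function(name, px) list(roi_name = name, zone = "SC.m",
                                    levels = list(`90` = list(
                                      terminal = px,
                                      passage = data.frame(x = integer(0), y = integer(0)))))
  # community 1 puts 10 pixels in cell (row 0-9, col 20-29); community 2 puts 3
  px1 <- data.frame(x = 20:29, y = rep(205, 10))
  px2 <- data.frame(x = 21:23, y = rep(206, 3))
  cases <- list(mkcase("A", px1), mkcase("B", px2))
  part <- structure(list(membership = c(A = 1L, B = 2L), n_communities = 2L),
                    class = "sc_partition")
  map <- winner_takes_all(cases, part, lvl, cell_size = 10)
  expect_equal(map[21, 3], 1L)      # cell containing both: majority wins
  expect_true(all(is.na(map[1, ]))) # unlabeled cells unassigned
  # tie goes to the lowest community index
  px3 <- data.frame(x = 21:23, y = rep(207, 3))
  cases_tie <- list(mkcase("A", px2), mkcase("B", px3))
  map_tie <- winner_takes_all(cases_tie, part, lvl, cell_size = 10)
  expect_equal(map_tie[21, 3], 1L)
})
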