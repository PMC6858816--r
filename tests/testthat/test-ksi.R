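test_that("the scaled KS statistic matches hand values and the brute-force oracle", {
  expect_equal(ks_scaled(1:5, 1:5), 0)
  expect_equal(ks_scaled(1:8, 9:16), sqrt(64 / 16) * 1)   # disjoint supports
  set.seed(1)
  for (i in 1:30) {
    x <- sample(round(rnorm(sample(1:30, 1), 0, 2), 1))
    y <- round(rnorm(sample(1:30, 1), sample(c(0, 1), 1), 2), 1)  # ties likely
    expect_equal(ks_scaled(x, y), naive_ks(x, y), tolerance = 1e-12)
  }
  expect_error(ks_scaled(numeric(0), 1:3), "empty")
})

test_that("the exact Peacock statistic matches hand values and full enumeration", {
  x <- rbind(c(0, 0), c(1, 1))
  y <- rbind(c(2, 2), c(3, 3))
  expect_equal(peacock_nd(x, y), 1)        # one quadrant separates completely
  expect_equal(peacock_nd(x, x), 0)
  set.seed(2)
  for (i in 1:15) {
    for (d in 2:3) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      a <- matrix(round(rnorm(n1 * d), 1), n1, d)
      b <- matrix(round(rnorm(n2 * d), 1), n2, d)
      expect_equal(peacock_nd(a, b), naive_peacock(a, b), tolerance = 1e-12)
    }
  }
  expect_error(peacock_nd(matrix(1, 2, 4), matrix(1, 2, 4)), "d = 2 or 3")
})

test_that("Peacock collapses to the univariate statistic on a degenerate coordinate", {
  set.seed(3)
  x1 <- rnorm(12); y1 <- rnorm(9, 0.8)
  a <- cbind(x1, 5)
  b <- cbind(y1, 5)
  expect_equal(peacock_nd(a, b), ks_scaled(x1, y1), tolerance = 1e-12)
})

test_that("KS statistics are symmetric and invariant to joint monotone transforms", {
  set.seed(4)
  for (i in 1:10) {
    a <- matrix(rnorm(16), 8, 2); b <- matrix(rnorm(12, 0.5), 6, 2)
    expect_equal(peacock_nd(a, b), peacock_nd(b, a), tolerance = 1e-12)
    expect_equal(ks_scaled(a[, 1], b[, 1]), ks_scaled(b[, 1], a[, 1]))
    ta <- cbind(exp(a[, 1]), atan(a[, 2]))
    tb <- cbind(exp(b[, 1]), atan(b[, 2]))
    expect_equal(peacock_nd(ta, tb), peacock_nd(a, b), tolerance = 1e-12)
    expect_equal(ks_scaled(exp(a[, 1]), exp(b[, 1])), ks_scaled(a[, 1], b[, 1]))
    # the multivariate statistic dominates each univariate margin
    expect_gte(peacock_nd(a, b) + 1e-12, ks_scaled(a[, 1], b[, 1]))
    expect_gte(peacock_nd(a, b) + 1e-12, ks_scaled(a[, 2], b[, 2]))
  }
})

test_that("KSI search finds a strongly shifted clade and reports its nodeset", {
  tr <- simulate_tree(60, seed = 5)
  ie <- milkphylo:::internal_edges(tr)
  cl <- milkphylo:::edge_clades(tr)
  sz <- lengths(cl)
  e <- ie[sz[ie] >= 8 & sz[ie] <= 20][1]
  node <- tr$edge[e, 2]
  Y <- milkphylo:::sim_ou_tips(tr, 0, diag(3), c(0, 0, 0))
  set.seed(6)
  Y2 <- Y; Y2[cl[[e]], ] <- Y2[cl[[e]], ] + 10      # +10 sd planted shift
  tm <- tm_from_matrix(tr, Y2)
  for (set in list("fat", c("fat", "protein", "sugar"))) {
    res <- ksi_search(tr, tm, set, n_ranks = 2)
    expect_equal(res$node[1], node)
    expect_equal(res$ratio[1], 1)
    expect_true(grepl(paste0("nd", node), res$nodeset[1]))
    expect_lt(res$statistic[2], res$statistic[1])
  }
})

test_that("KSI search depends only on the tree shape, not its representation", {
  tr <- simulate_tree(40, seed = 7)
  Y <- milkphylo:::sim_ou_tips(tr, 0, diag(3), c(0, 0, 0))
  e <- milkphylo:::internal_edges(tr)[5]
  cl <- milkphylo:::edge_clades(tr)[[e]]
  Y[cl, 1] <- Y[cl, 1] + 6
  tm <- tm_from_matrix(tr, Y)
  r1 <- ksi_search(tr, tm, "fat", n_ranks = 2)
  # ladderize changes node numbering and edge order but not the topology
  tr2 <- ape::ladderize(tr)
  r2 <- ksi_search(tr2, tm, "fat", n_ranks = 2)
  tips1 <- phangorn::Descendants(tr, r1$node[1], "tips")[[1]]
  tips2 <- phangorn::Descendants(tr2, r2$node[1], "tips")[[1]]
  expect_setequal(tr$tip.label[tips1], tr2$tip.label[tips2])
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-12)
  # shuffling trait-table rows changes nothing (species matched by name)
  perm <- sample(nrow(tm))
  tmp <- trait_matrix(tm$species[perm], tm$fat[perm], tm$protein[perm],
                      tm$sugar[perm], scale = "logit")
  r3 <- ksi_search(tr, tmp, "fat", n_ranks = 2)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-12)
})

test_that("species missing a trait are dropped only for sets using that trait", {
  tr <- simulate_tree(30, seed = 8)
  Y <- milkphylo:::sim_ou_tips(tr, 0, diag(3), c(0, 0, 0))
  tm <- tm_from_matrix(tr, Y)
  tm <- impose_missingness(tm, 0.2, "sugar", seed = 9)
  r_fp <- ksi_search(tr, tm, c("fat", "protein"), n_ranks = 1)
  r_fs <- ksi_search(tr, tm, c("fat", "sugar"), n_ranks = 1)
  expect_equal(attr(r_fp, "n_species"), 30)
  expect_equal(attr(r_fs, "n_species"), 24)
})

test_that("the stacked KSI table has one block per trait set", {
  tr <- simulate_tree(24, seed = 10)
  tm <- tm_from_matrix(tr, milkphylo:::sim_ou_tips(tr, 0, diag(3), c(0, 0, 0)))
  res <- ksi_all_sets(tr, tm, n_ranks = 2, min_clade = 3)
  tab <- ksi_table(res)
  expect_equal(length(unique(tab$traits)), 7)
  expect_true(all(tab$rank %in% 1:2))
  expect_equal(nrow(ksi_table(list())), 0)
})

test_that("the search stops early with a warning when species run out", {
  tr <- simulate_tree(12, seed = 11)
  tm <- tm_from_matrix(tr, milkphylo:::sim_ou_tips(tr, 0, diag(3), c(0, 0, 0)))
  expect_warning(res <- ksi_search(tr, tm, "fat", n_ranks = 6, min_clade = 3),
                 "stopped early|no testable")
  expect_lt(nrow(res), 6)
})
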