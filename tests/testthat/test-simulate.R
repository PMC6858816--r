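test_that("simulated trees are ultrametric, unit height, and seed-deterministic", {
  tr <- simulate_tree(30, seed = 5)
  expect_equal(ape::Ntip(tr), 30)
  d <- diag(phylo_covariance(tr))
  expect_true(all(abs(d - 1) < 1e-8))
  expect_identical(ape::write.tree(simulate_tree(30, seed = 5)),
                   ape::write.tree(tr))
  t3 <- simulate_tree(3, seed = 1)
  expect_equal(t3$Nnode, 2)
  expect_error(simulate_tree(2), "n >= 3")
})

test_that("Brownian simulation has the closed-form contrast and tip covariance", {
  # zero rate: every tip equals the root state
  tr <- simulate_tree(10, seed = 2)
  s0 <- simulate_bm_traits(tr, matrix(0, 3, 3), root_state = c(1, -2, 0.5), seed = 3)
  expect_equal(s0$fat, rep(1, 10))
  expect_equal(s0$sugar, rep(0.5, 10))
  # 2-tip unit-branch tree: Var(x_A - x_B) = 2 * Sigma, cross-trait too
  t2 <- tree2()
  Sig <- matrix(c(1, 0.5, 0, 0.5, 1, -0.3, 0, -0.3, 1), 3)
  set.seed(11)
  diffs <- t(vapply(seq_len(2000), function(i) {
    s <- simulate_bm_traits(t2, Sig, c(0, 0, 0))
    c(s$fat[1] - s$fat[2], s$protein[1] - s$protein[2], s$sugar[1] - s$sugar[2])
  }, numeric(3)))
  expect_equal(unname(cov(diffs)), unname(2 * Sig), tolerance = 0.15)
  # 3-tip tree: across-replicate tip covariance of one trait approximates A
  t3 <- tree3()
  A <- phylo_covariance(t3)
  set.seed(12)
  tips <- t(vapply(seq_len(3000), function(i)
    simulate_bm_traits(t3, diag(3), c(0, 0, 0))$fat, numeric(3)))
  expect_equal(unname(cov(tips)), unname(A), tolerance = 0.18)
})

test_that("scalar OU reduces to Brownian motion at alpha 0 and pins tips at strong pull", {
  tr <- simulate_tree(20, seed = 4)
  Sig <- diag(3)
  bm <- simulate_bm_traits(tr, Sig, c(0, 0, 0), seed = 9)
  ou0 <- simulate_scou_traits(tr, 0, Sig, c(0, 0, 0), seed = 9)
  expect_equal(as.data.frame(ou0), as.data.frame(bm))  # identical sample paths
  # very strong pull: tips sit at their regime's optimum
  e <- milkphylo:::internal_edges(tr)[2]
  clade <- milkphylo:::edge_clades(tr)[[e]]
  th <- matrix(c(3, -3, 1), 1)
  ouS <- simulate_scou_traits(tr, 500, Sig, c(0, 0, 0), shifts = e, delta = th,
                              seed = 10)
  expect_true(all(abs(ouS$fat[clade] - 3) < 0.3))
  expect_true(all(abs(ouS$fat[-clade]) < 0.3))
  expect_error(simulate_scou_traits(tr, 1, Sig, shifts = c(e, e),
                                    delta = rbind(th, th)), "two shifts")
})

test_that("long-branch OU samples match the stationary variance rates/(2 alpha)", {
  star <- read_newick(text = paste0("(", paste0("t", 1:300, ":1", collapse = ","), ");"))
  alpha <- 5
  s <- simulate_scou_traits(star, alpha, diag(3), c(0, 0, 0), seed = 6)
  expect_equal(var(s$fat), 1 / (2 * alpha), tolerance = 0.25)
  expect_equal(mean(s$fat), 0, tolerance = 3 * sqrt(0.1 / 300) * 3)
})

test_that("covariates and effects wire through the 9-column design", {
  tr <- simulate_tree(60, seed = 8)
  zero <- simulate_bm_traits(tr, matrix(0, 3, 3), c(0, 0, 0), seed = 1)
  B0 <- matrix(0, 9, 3)
  out0 <- attach_covariates_and_effects(tr, zero, B0, seed = 21)
  expect_equal(out0$traits$fat, zero$fat)            # B = 0 leaves traits alone
  expect_equal(ncol(out0$X), 9)
  expect_true(all(out0$X[out0$covariates$diet == "herbivore",
                         c("diet_omnivore", "diet_carnivore")] == 0))
  # a single arid effect of 1 on fat appears exactly as the group difference
  B <- B0; B["arid" == rownames(milk_preset_params()$B), ] <- 0
  B[2, 1] <- 1
  out1 <- attach_covariates_and_effects(tr, zero, B, seed = 21)
  g <- split(out1$traits$fat, out1$covariates$arid)
  expect_equal(mean(g[["1"]]) - mean(g[["0"]]), 1, tolerance = 1e-12)
})

test_that("missingness is imposed exactly, at random, reproducibly", {
  tr <- simulate_tree(124, seed = 9)
  s <- simulate_bm_traits(tr, diag(3), c(0, 0, 0), seed = 2)
  m <- impose_missingness(s, 15 / 124, "sugar", seed = 3)
  expect_equal(sum(is.na(m$sugar)), 15)
  expect_equal(sum(is.na(m$fat)), 0)
  m2 <- impose_missingness(s, 15 / 124, "sugar", seed = 3)
  expect_identical(which(is.na(m2$sugar)), which(is.na(m$sugar)))
  s_id <- impose_missingness(s, 0, "sugar", seed = 1)
  expect_identical(s_id$sugar, s$sugar)
  expect_identical(s_id$fat, s$fat)
  expect_error(impose_missingness(s, 1), "fraction")
})

test_that("the study-scale preset records a truth sufficient for recovery scoring", {
  sim <- simulate_milk_dataset("paper124", seed = 2)
  expect_equal(length(sim$data$species), 124)
  expect_equal(sum(is.na(sim$data$traits$sugar)), 15)
  expect_equal(trait_scale(sim$data$traits), "logit")
  tr <- sim$truth
  expect_equal(unname(diag(tr$Sigma_P) / (diag(tr$Sigma_P) + diag(tr$Sigma_R))),
               unname(tr$h2), tolerance = 1e-12)
  expect_equal(dim(tr$B), c(9L, 3L))
  sim2 <- simulate_milk_dataset("paper124", seed = 2)
  expect_identical(as.data.frame(sim2$data$traits), as.data.frame(sim$data$traits))
  tiny <- simulate_milk_dataset("tiny", seed = 1)
  expect_equal(length(tiny$data$species), 16)
  expect_equal(sum(is.na(tiny$data$traits$sugar)), 0)
})

test_that("the published-regime scenario plants six nested shifts", {
  sc <- milk_shift_scenario(seed = 3)
  expect_equal(length(sc$shifts), 6)
  expect_equal(sum(is.na(sc$traits$sugar)), 15)
  # mirounga and otariid clades nest inside the pinniped clade
  expect_true(all(sc$clades$mirounga %in% sc$clades$pinnipeds))
  expect_true(all(sc$clades$otariids %in% sc$clades$pinnipeds))
  expect_length(intersect(sc$clades$primates, sc$clades$pinnipeds), 0)
  # planted mean levels back-transform to the published regime table
  expect_equal(unname(back_transform_optima(sc$theta["pinnipeds", "fat"])),
               59.78315, tolerance = 1e-6)
})
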