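test_that("the scalar-OU likelihood at alpha 0 equals the Brownian mixed-model likelihood", {
  tr <- simulate_tree(15, seed = 1)
  set.seed(2)
  Y <- matrix(rnorm(45), 15, 3)
  rates <- milkphylo:::theta_to_cov(c(0.2, 0.4, -0.1, 0.1, 0.2, -0.3), 3)
  root <- c(0.5, -1, 0.2)
  ll_ou <- scou_loglik(Y, tr, integer(0), matrix(root, 1), alpha = 0, rates = rates)
  ll_pmm <- pmm_loglik(Y, matrix(1, 15, 1), phylo_covariance(tr),
                       rates, matrix(0, 3, 3), matrix(root, 1))
  expect_equal(ll_ou, ll_pmm, tolerance = 1e-8)
})

test_that("the likelihood is continuous in alpha at zero", {
  tr <- simulate_tree(10, seed = 3)
  set.seed(4)
  Y <- matrix(rnorm(30), 10, 3)
  Th <- matrix(c(0.1, -0.2, 0), 1)
  l0 <- scou_loglik(Y, tr, integer(0), Th, 0, diag(3))
  leps <- scou_loglik(Y, tr, integer(0), Th, 1e-8, diag(3))
  expect_lt(abs(leps - l0), 1e-4)
})

test_that("strong pull on a long branch approaches the stationary density", {
  t2 <- tree2()
  alpha <- 60
  y <- matrix(c(0.15, -0.2, 0.3, 0.1, -0.12, 0.05), 2, 3)
  th <- c(0.1, -0.1, 0.2)
  ll <- scou_loglik(y, t2, integer(0), matrix(th, 1), alpha, diag(3))
  statn <- sum(dnorm(sweep(y, 2, th), sd = sqrt(1 / (2 * alpha)), log = TRUE))
  expect_equal(ll, statn, tolerance = 1e-3)
})

test_that("the likelihood ignores the order in which shifts are listed", {
  tr <- simulate_tree(20, seed = 5)
  ie <- milkphylo:::internal_edges(tr)
  cl <- milkphylo:::edge_clades(tr)
  two <- ie[lengths(cl)[ie] >= 3][1:2]
  set.seed(6)
  Y <- matrix(rnorm(60), 20, 3)
  Th <- rbind(c(0, 0, 0), c(2, 1, -1), c(-1, 0.5, 2))
  l12 <- scou_loglik(Y, tr, two, Th, 0.5, diag(3))
  l21 <- scou_loglik(Y, tr, rev(two), Th[c(1, 3, 2), ], 0.5, diag(3))
  expect_equal(l12, l21, tolerance = 1e-10)
  expect_error(scou_loglik(Y, tr, 9999, Th[1:2, ], 0.5, diag(3)), "non-existent")
  expect_error(scou_loglik(Y, tr, c(two[1], two[1]), Th, 0.5, diag(3)), "two shifts")
})

test_that("half-life and optimum back-transforms follow their formulas", {
  expect_equal(half_life(log(2), 1), 1)
  expect_equal(half_life(0.07, 1), log(2) / 0.07)    # about 9.9 tree heights
  expect_equal(half_life(0.2, 1), 2 * half_life(0.4, 1))
  expect_warning(hl <- half_life(0), "infinite")
  expect_equal(hl, Inf)
  expect_equal(back_transform_optima(0), 50)
  expect_equal(back_transform_optima(logit(0.5978315)), 59.78315, tolerance = 1e-10)
  th <- matrix(c(-2, 0, 3), 1)
  expect_equal(logit(back_transform_optima(th) / 100), th, tolerance = 1e-10)
})

test_that("a fixed-K fit recovers planted shifts and K = 0 yields one regime", {
  tr <- simulate_tree(64, seed = 7)
  ie <- milkphylo:::internal_edges(tr)
  cl <- milkphylo:::edge_clades(tr)
  cand <- ie[lengths(cl)[ie] >= 6 & lengths(cl)[ie] <= 20]
  e1 <- cand[1]
  e2 <- cand[!vapply(cand, function(e)
    length(intersect(cl[[e]], cl[[e1]])) > 0, TRUE)][1]
  delta <- matrix(6, 2, 3)
  s <- simulate_scou_traits(tr, 0, diag(3), c(0, 0, 0), shifts = c(e1, e2),
                            delta = delta, seed = 8)
  f2 <- fit_shifts_em(s, tr, K = 2)
  expect_equal(milkphylo:::partition_signature(tr, f2$shifts),
               milkphylo:::partition_signature(tr, c(e1, e2)))
  expect_equal(nrow(f2$Theta), 3)
  # planted regime mean levels recovered within the stated tolerance
  reg <- f2$tip_regimes[tr$tip.label[cl[[e1]]]]
  k <- as.integer(names(which.max(table(reg))))
  expect_true(all(abs(f2$Theta[k + 1, ] - 6) < 0.6))
  f0 <- fit_shifts_em(s, tr, K = 0)
  expect_equal(f0$K, 0)
  expect_equal(nrow(f0$Theta), 1)
  expect_gt(f2$loglik, f0$loglik)
})

test_that("K selection tracks a full, monotone criterion curve", {
  tr <- simulate_tree(48, seed = 9)
  s <- simulate_bm_traits(tr, diag(3), c(0, 0, 0), seed = 10)
  f <- select_K(s, tr, K_max = 3)
  cc <- f$criterion_curve
  expect_equal(cc$K, 0:3)
  expect_true(all(diff(cc$loglik) >= -1e-6))   # K shifts nest K - 1
  expect_equal(f$K, cc$K[which.min(cc$criterion)])
})

test_that("equivalent shift allocations are enumerated on a hand-built tree", {
  tr <- read_newick(text = "(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
  # shift on the (D,E) stem colours {D,E}; the allocation on the (A,B,C) stem
  # colours the complementary set - the same unordered partition
  ie <- milkphylo:::internal_edges(tr)
  cl <- milkphylo:::edge_clades(tr)
  e_de <- ie[vapply(ie, function(e) setequal(tr$tip.label[cl[[e]]], c("D", "E")), TRUE)]
  e_abc <- ie[vapply(ie, function(e) setequal(tr$tip.label[cl[[e]]], c("A", "B", "C")), TRUE)]
  s <- simulate_scou_traits(tr, 0, diag(3), c(0, 0, 0), shifts = e_de,
                            delta = matrix(8, 1, 3), seed = 11)
  f <- fit_shifts_em(s, tr, K = 1, alpha_grid = c(0, 0.5))
  sols <- equivalent_solutions(f, tr)
  expect_equal(sort(vapply(sols, identity, 0L)), sort(c(e_de, e_abc)))
  # every enumerated allocation attains the same maximized likelihood
  pre <- milkphylo:::scou_pre(tr, f$alpha)
  Y <- milkphylo:::scou_data(s, tr)$Y
  lls <- vapply(sols, function(ss) milkphylo:::scou_gls_set(Y, pre, ss)$ll, 0)
  expect_lt(max(lls) - min(lls), 1e-6)
  f0 <- fit_shifts_em(s, tr, K = 0, alpha_grid = c(0))
  expect_equal(equivalent_solutions(f0, tr), list(integer(0)))
})

test_that("fits partition every tip into exactly one regime", {
  tr <- simulate_tree(40, seed = 12)
  ie <- milkphylo:::internal_edges(tr)
  cl <- milkphylo:::edge_clades(tr)
  e <- ie[lengths(cl)[ie] >= 8][1]
  s <- simulate_scou_traits(tr, 0, diag(3), c(0, 0, 0), shifts = e,
                            delta = matrix(5, 1, 3), seed = 13)
  f <- fit_shifts_em(s, tr, K = 1)
  expect_equal(length(f$tip_regimes), 40)
  expect_setequal(unique(f$tip_regimes), 0:1)
})

test_that("missing cells are imputed as conditional means that track the truth", {
  tr <- simulate_tree(96, seed = 14)
  ie <- milkphylo:::internal_edges(tr)
  cl <- milkphylo:::edge_clades(tr)
  cand <- ie[lengths(cl)[ie] >= 8 & lengths(cl)[ie] <= 30]
  e1 <- cand[1]
  e2 <- cand[!vapply(cand, function(e)
    length(intersect(cl[[e]], cl[[e1]])) > 0, TRUE)][1]
  s <- simulate_scou_traits(tr, 0, milk_preset_params()$Sigma_P,
                            c(0, 0, 0), shifts = c(e1, e2),
                            delta = matrix(c(4, -2, 3, 1, -3, 2), 2, 3), seed = 15)
  sm <- impose_missingness(s, 0.12, "sugar", seed = 16)
  f <- fit_shifts_em(sm, tr, K = 2)
  expect_equal(nrow(f$imputed), round(0.12 * 96))
  truth <- s$sugar[match(f$imputed$species, s$species)]
  expect_gt(cor(truth, f$imputed$value), 0.9)
})
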