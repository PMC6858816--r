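test_that("the design matrix has the fixed 9-column layout with herbivore reference", {
  cv <- covariate_table(c("A", "B", "C"), arid = c(0, 1, 0), aquatic = c(0, 2, 3),
                        diet = c("herbivore", "omnivore", "carnivore"),
                        female_mass = c(-1, 0, 1), rep_output = c(0, 0.1, -0.1),
                        lactation_length = c(0.2, -0.1, -0.1),
                        precociality = c(0, 1, 3), centered = TRUE)
  X <- build_design(cv)
  expect_equal(colnames(X), c("intercept", "arid", "aquatic", "diet_omnivore",
                              "diet_carnivore", "female_mass", "rep_output",
                              "lactation_length", "precociality"))
  expect_equal(unname(X[1, c("diet_omnivore", "diet_carnivore")]), c(0, 0))
  expect_equal(unname(X[3, c("diet_omnivore", "diet_carnivore")]), c(0, 1))
  cv$arid[2] <- NA
  expect_error(build_design(cv), "missing covariate")
})

test_that("the stacked likelihood matches iid normal densities on a star tree", {
  star <- star3()
  A <- phylo_covariance(star)      # identity
  set.seed(1)
  Y <- matrix(rnorm(9), 3, 3)
  X <- matrix(1, 3, 1)
  ll <- pmm_loglik(Y, X, A, matrix(0, 3, 3), diag(3), matrix(0, 1, 3))
  expect_equal(ll, sum(dnorm(Y, log = TRUE)), tolerance = 1e-8)
})

test_that("the stacked likelihood matches hand-built Gaussian densities on small trees", {
  # one trait, two tips: independent normals with variances from the tree
  t2 <- tree2()
  A2 <- phylo_covariance(t2)
  y2 <- matrix(c(0.3, -1.1), 2, 1)
  sp <- 0.7; sr <- 0.4; b <- 0.25
  ll2 <- pmm_loglik(y2, matrix(1, 2, 1), A2, matrix(sp, 1, 1), matrix(sr, 1, 1),
                    matrix(b, 1, 1))
  V2 <- sp * A2 + sr * diag(2)
  expect_equal(ll2, mvn_logdens(as.vector(y2), rep(b, 2), V2), tolerance = 1e-8)
  # two correlated traits on a three-tip tree, with one missing cell
  t3 <- tree3()
  A3 <- phylo_covariance(t3)
  SP <- matrix(c(1, 0.5, 0.5, 0.8), 2)
  SR <- matrix(c(0.3, -0.1, -0.1, 0.4), 2)
  B <- rbind(c(0.2, -0.3))
  Y <- rbind(c(0.1, 0.5), c(-0.4, NA), c(1.2, 0.9))
  ll3 <- pmm_loglik(Y, matrix(1, 3, 1), A3, SP, SR, B)
  V <- SP %x% A3 + SR %x% diag(3)
  obs <- !is.na(as.vector(Y))
  expect_equal(ll3, mvn_logdens(as.vector(Y)[obs],
                                as.vector(matrix(1, 3, 1) %*% B)[obs],
                                V[obs, obs]), tolerance = 1e-8)
})

test_that("the likelihood is invariant to consistent relabeling of species and traits", {
  tr <- simulate_tree(8, seed = 3)
  A <- phylo_covariance(tr)
  set.seed(4)
  Y <- matrix(rnorm(24), 8, 3)
  X <- cbind(1, rnorm(8))
  SP <- milkphylo:::theta_to_cov(c(0.1, 0.3, -0.2, 0.1, 0, -0.1), 3)
  SR <- milkphylo:::theta_to_cov(c(-0.5, 0.1, -0.4, 0, 0.2, -0.6), 3)
  B <- rbind(c(0.1, 0.2, 0.3), c(-1, 0, 1))
  ll <- pmm_loglik(Y, X, A, SP, SR, B)
  perm <- sample(8)
  expect_equal(pmm_loglik(Y[perm, ], X[perm, ], A[perm, perm], SP, SR, B), ll,
               tolerance = 1e-10)
  tp <- c(3, 1, 2)   # reorder the traits everywhere
  expect_equal(pmm_loglik(Y[, tp], X, A, SP[tp, tp], SR[tp, tp], B[, tp]), ll,
               tolerance = 1e-10)
})

test_that("diagonal covariances decouple into per-trait phylogenetic GLS likelihoods", {
  tr <- simulate_tree(10, seed = 6)
  A <- phylo_covariance(tr)
  set.seed(7)
  Y <- matrix(rnorm(30), 10, 3)
  X <- cbind(1, rnorm(10))
  B <- rbind(c(0, 0.5, 1), c(0.2, 0.2, 0.2))
  sp <- c(1, 0.5, 2); sr <- c(0.2, 0.4, 0.1)
  ll <- pmm_loglik(Y, X, A, diag(sp), diag(sr), B)
  per_trait <- vapply(1:3, function(k)
    mvn_logdens(Y[, k], as.vector(X %*% B[, k]), sp[k] * A + sr[k] * diag(10)), 0)
  expect_equal(ll, sum(per_trait), tolerance = 1e-8)
})

test_that("profiled fixed effects equal the closed-form phylogenetic GLS estimator", {
  tr <- simulate_tree(9, seed = 8)
  A <- phylo_covariance(tr)
  set.seed(9)
  y <- matrix(rnorm(9), 9, 1)
  X <- cbind(1, rnorm(9))
  g <- pmm_gls(y, X, A, matrix(1.3, 1, 1), matrix(0, 1, 1))
  expect_equal(unname(g$B), unname(gls_oracle(X, 1.3 * A, y)), tolerance = 1e-6)
})

test_that("fit_pmm validates its inputs", {
  sim <- simulate_milk_dataset("tiny", seed = 1)
  raw <- sim$data
  raw$traits <- raw_traits(raw$traits)
  expect_error(fit_pmm(raw), "logit")
  expect_error(fit_pmm(sim$data, min_species = 30), "at least 30")
})

test_that("the MCMC backend keeps derived quantities in range with honest intervals", {
  sim <- simulate_milk_dataset("tiny", seed = 3, n = 40)
  fit <- fit_pmm(sim$data, method = "mcmc", seed = 5, min_species = 10,
                 control = list(iter = 600, burn = 200, thin = 2))
  expect_true(all(fit$h2 >= 0 & fit$h2 <= 1))
  expect_true(all(fit$h2_draws >= 0 & fit$h2_draws <= 1))
  expect_true(all(abs(fit$r_P[upper.tri(fit$r_P)]) <= 1))
  expect_true(all(fit$h2_ci[1, ] <= fit$h2 & fit$h2 <= fit$h2_ci[2, ]))
  expect_true(all(fit$ci_lo <= fit$B & fit$B <= fit$ci_hi))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
})

test_that("summaries expose the coefficient table and the h2/correlation matrix", {
  sim <- simulate_milk_dataset("tiny", seed = 2, n = 40)
  fit <- fit_pmm(sim$data, seed = 1, min_species = 10)
  tabs <- summarize_pmm(fit)
  expect_equal(nrow(tabs$coefficients), 9)
  expect_equal(tabs$coefficients$fat_beta, unname(fit$B[, "fat"]))
  M <- as.matrix(tabs$covariances[, -1])
  expect_equal(unname(diag(M)), unname(fit$h2))
  expect_equal(unname(M[1, 2]), unname(fit$r_P[1, 2]))
  expect_equal(unname(M[2, 1]), unname(fit$r_R[2, 1]))
})
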