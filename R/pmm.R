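# Trivariate phylogenetic mixed model: Gaussian model for stacked logit-scale
# trait values with covariance Sigma_P (x) A + Sigma_R (x) I, ecological fixed
# effects, and derived heritabilities and correlations.

#' Build the fixed-effect design matrix
#'
#' Columns in the fixed order: intercept, arid, aquatic (ordinal score), diet
#' dummies for omnivore and carnivore (herbivore is the reference), female
#' mass, reproductive output, relative lactation length, precociality (ordinal
#' score). Ordinal predictors enter as numeric scores.
#'
#' @param covariates a [covariate_table()] with no missing values among the
#'   included species.
#' @return an n x 9 numeric matrix with species rownames.
#' @export
build_design <- function(covariates) {
  cc <- as.data.frame(covariates)
  used <- c("arid", "aquatic", "diet", "female_mass", "rep_output",
            "lactation_length", "precociality")
  if (anyNA(cc[, used]))
    stop_input("missing covariate values; drop those species before building the design")
  if (any(!cc$diet %in% diet_levels())) stop_input("unseen diet level")
  X <- cbind(intercept = 1,
             arid = as.numeric(cc$arid),
             aquatic = as.numeric(cc$aquatic),
             diet_omnivore = as.numeric(cc$diet == "omnivore"),
             diet_carnivore = as.numeric(cc$diet == "carnivore"),
             female_mass = cc$female_mass,
             rep_output = cc$rep_output,
             lactation_length = cc$lactation_length,
             precociality = as.numeric(cc$precociality))
  rownames(X) <- cc$species
  X
}

# stacked covariance of vec(Y) (trait-major): Sigma_P (x) A + Sigma_R (x) I
pmm_vcov_stacked <- function(A, Sigma_P, Sigma_R) {
  n <- nrow(A)
  Sigma_P %x% A + Sigma_R %x% diag(n)
}

# Cholesky, falling back to a small relative ridge when the matrix is
# numerically indefinite; NULL if it is not PD even then
chol_jitter <- function(V, jitter = 1e-8) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  d <- mean(diag(V))
  tryCatch(chol(V + diag(jitter * d, nrow(V))), error = function(e) NULL)
}

#' Log-likelihood of the phylogenetic mixed model
#'
#' Gaussian log-density of the observed trait cells: `vec(Y)` (traits stacked
#' column-wise) has mean `vec(X B)` and covariance
#' `Sigma_P (x) A + Sigma_R (x) I`; missing cells are marginalized by row
#' selection of the stacked system, the exact treatment for ignorable
#' missingness.
#'
#' @param Y n x p matrix of trait values (logit scale), `NA` for missing.
#' @param X n x q design matrix.
#' @param A n x n phylogenetic covariance from [phylo_covariance()].
#' @param Sigma_P,Sigma_R p x p phylogenetic and residual covariance matrices.
#' @param B q x p fixed-effect matrix.
#' @param jitter relative ridge added to the covariance diagonal before
#'   factorization.
#' @return the log-likelihood (a single number).
#' @export
pmm_loglik <- function(Y, X, A, Sigma_P, Sigma_R, B, jitter = 1e-8) {
  Y <- as.matrix(Y); X <- as.matrix(X); B <- as.matrix(B)
  y <- as.vector(Y)
  obs <- !is.na(y)
  mu <- as.vector(X %*% B)
  V <- pmm_vcov_stacked(A, Sigma_P, Sigma_R)[obs, obs, drop = FALSE]
  ch <- chol_jitter(V, jitter)
  if (is.null(ch)) stop_input("covariance not positive definite after jitter")
  r <- y[obs] - mu[obs]
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (sum(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Generalized least squares for the stacked mixed model
#'
#' Fixed effects that maximize the likelihood for given covariance matrices,
#' with missing cells marginalized. This is the profile step used inside
#' [fit_pmm()] and, with `Sigma_R = 0` and one trait, the classic phylogenetic
#' GLS estimator.
#'
#' @inheritParams pmm_loglik
#' @return a list: `B` (q x p), `cov_B` (covariance of `vec(B)`), `loglik`.
#' @export
pmm_gls <- function(Y, X, A, Sigma_P, Sigma_R, jitter = 1e-8) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); p <- ncol(Y); q <- ncol(X)
  y <- as.vector(Y)
  obs <- !is.na(y)
  V <- pmm_vcov_stacked(A, Sigma_P, Sigma_R)[obs, obs, drop = FALSE]
  ch <- chol_jitter(V, jitter)
  if (is.null(ch)) return(NULL)
  Xbig <- (diag(p) %x% X)[obs, , drop = FALSE]
  Xw <- backsolve(ch, Xbig, transpose = TRUE)
  yw <- backsolve(ch, y[obs], transpose = TRUE)
  XtX <- crossprod(Xw)
  cB <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(cB)) return(NULL)
  bvec <- backsolve(cB, backsolve(cB, crossprod(Xw, yw), transpose = TRUE))
  r <- yw - Xw %*% bvec
  ll <- -0.5 * (sum(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  B <- matrix(bvec, q, p, dimnames = list(colnames(X), colnames(Y)))
  list(B = B, cov_B = chol2inv(cB), loglik = ll)
}

# log-Cholesky parameterization of a p x p covariance: diagonal entries of L
# are stored on the log scale so every theta maps to a PD matrix
theta_to_cov <- function(theta, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

cov_to_theta <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

cov2cor_safe <- function(S) {
  d <- sqrt(pmax(diag(S), 1e-300))
  S / tcrossprod(d)
}

derive_pmm_quantities <- function(Sigma_P, Sigma_R) {
  h2 <- diag(Sigma_P) / (diag(Sigma_P) + diag(Sigma_R))
  list(h2 = h2, r_P = cov2cor_safe(Sigma_P), r_R = cov2cor_safe(Sigma_R))
}

#' Fit the trivariate phylogenetic mixed model
#'
#' Estimates the 9 x 3 fixed-effect matrix, the phylogenetic covariance
#' `Sigma_P` and the residual covariance `Sigma_R` of the logit-scale milk
#' traits. Two backends share one contract:
#'
#' * `"ml"` (default): maximum likelihood by quasi-Newton over a log-Cholesky
#'   parameterization of the two covariance matrices, with the fixed effects
#'   profiled out by GLS at every step. Deterministic and fast. Intervals and
#'   p-values for the coefficients are Wald (Gaussian GLS conditional on the
#'   estimated covariances); with `nboot > 0` a parametric bootstrap supplies
#'   percentile intervals and tail-fraction p-values for every quantity,
#'   including heritabilities and correlations.
#' * `"mcmc"`: Bayesian sampling — the coefficient matrix is drawn from its
#'   exact Gaussian conditional, the covariance parameters by adaptive
#'   random-walk Metropolis under weakly informative normal priors on the
#'   log-Cholesky scale. Intervals are posterior quantiles and p-values the
#'   two-sided posterior tail fraction `2 min(Pr(b > 0), Pr(b < 0))`.
#'
#' The phylogenetic covariance `A` is computed from the tree as supplied;
#' with a unit-height tree, `Sigma_P` is per unit tree height and the
#' heritabilities `Sigma_P[ii] / (Sigma_P[ii] + Sigma_R[ii])` are scale-free.
#' Species with missing covariates are dropped (the model needs a complete
#' design row); missing trait cells are marginalized exactly.
#'
#' @param data an [trim_and_align()] result with logit-scale traits and
#'   covariates.
#' @param method `"ml"` or `"mcmc"`.
#' @param seed integer seed (used by the bootstrap and MCMC backends).
#' @param nboot parametric-bootstrap replicates for the ML backend (0 = Wald
#'   only).
#' @param min_species minimum species with complete covariates.
#' @param control list: `maxit` (optimizer iterations), `iter`, `burn`, `thin`
#'   (MCMC), `grad_tol` (convergence check on the gradient norm).
#' @return an object of class `"pmm_fit"`: fields `B`, `ci_lo`, `ci_hi`, `p`,
#'   `Sigma_P`, `Sigma_R`, `h2`, `r_P`, `r_R`, interval arrays for the derived
#'   quantities when available, `loglik`, `convergence`, `method`, `n`.
#' @export
fit_pmm <- function(data, method = c("ml", "mcmc"), seed = NULL, nboot = 0,
                    min_species = 30, control = list()) {
  method <- match.arg(method)
  if (!inherits(data, "aligned_dataset")) stop_input("data must be an aligned_dataset")
  if (is.null(data$covariates)) stop_input("covariates are required to fit the mixed model")
  if (trait_scale(data$traits) != "logit")
    stop_input("traits must be on the logit scale (see logit_traits)")
  cc <- as.data.frame(data$covariates)
  used <- c("arid", "aquatic", "diet", "female_mass", "rep_output",
            "lactation_length", "precociality")
  keep <- complete.cases(cc[, used])
  if (sum(keep) < nrow(cc))
    message("dropping ", sum(!keep), " species with missing covariates from the mixed model")
  if (sum(keep) < min_species)
    stop_input("need at least ", min_species, " species with complete covariates; have ",
               sum(keep))
  A <- phylo_covariance(data$tree)[keep, keep, drop = FALSE]
  Y <- trait_values(data$traits)[keep, , drop = FALSE]
  covs <- data$covariates[keep, , drop = FALSE]
  class(covs) <- class(data$covariates)
  X <- build_design(covs)
  if (!is.null(seed)) set.seed(seed)

  S <- cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- S + diag(1e-3 * mean(diag(S)) + 1e-8, ncol(Y))
  theta0 <- c(cov_to_theta(S / 2), cov_to_theta(S / 2))
  nth <- length(theta0) / 2
  p <- ncol(Y)

  negll <- function(theta) {
    SP <- theta_to_cov(theta[seq_len(nth)], p)
    SR <- theta_to_cov(theta[nth + seq_len(nth)], p)
    g <- pmm_gls(Y, X, A, SP, SR)
    if (is.null(g)) return(1e10)
    -g$loglik
  }

  if (method == "ml") {
    maxit <- control$maxit %||% 400
    reltol <- control$reltol %||% 1e-8
    opt <- optim(theta0, negll, method = "BFGS",
                 control = list(maxit = maxit, reltol = reltol))
    if (opt$convergence != 0) {
      opt2 <- optim(opt$par + rnorm(length(theta0), 0, 0.05), negll, method = "BFGS",
                    control = list(maxit = maxit, reltol = reltol))
      if (opt2$value < opt$value) opt <- opt2
      if (opt$convergence != 0)
        stop_convergence("mixed-model optimizer did not converge (code ",
                         opt$convergence, "): ", opt$message %||% "")
    }
    fit <- pmm_point_fit(opt$par, Y, X, A, nth, p)
    fit$convergence <- list(code = opt$convergence, counts = opt$counts,
                            value = -opt$value)
    if (nboot > 0) fit <- pmm_bootstrap(fit, Y, X, A, nboot, nth, p, control)
    fit$method <- "ml"
  } else {
    fit <- pmm_mcmc(theta0, Y, X, A, nth, p, control)
    fit$method <- "mcmc"
  }
  fit$n <- nrow(Y)
  fit$n_obs <- sum(!is.na(Y))
  fit$species <- rownames(Y)
  class(fit) <- "pmm_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assemble a pmm_fit (point estimates + Wald inference for B) from theta
pmm_point_fit <- function(theta, Y, X, A, nth, p) {
  SP <- theta_to_cov(theta[seq_len(nth)], p)
  SR <- theta_to_cov(theta[nth + seq_len(nth)], p)
  dimnames(SP) <- dimnames(SR) <- list(colnames(Y), colnames(Y))
  g <- pmm_gls(Y, X, A, SP, SR)
  se <- matrix(sqrt(diag(g$cov_B)), ncol(X), p,
               dimnames = dimnames(g$B))
  z <- g$B / se
  der <- derive_pmm_quantities(SP, SR)
  list(B = g$B, se = se,
       ci_lo = g$B - 1.96 * se, ci_hi = g$B + 1.96 * se,
       p = 2 * pnorm(-abs(z)),
       Sigma_P = SP, Sigma_R = SR, theta = theta,
       h2 = der$h2, r_P = der$r_P, r_R = der$r_R,
       h2_ci = NULL, r_P_ci = NULL, r_R_ci = NULL,
       loglik = g$loglik)
}

# parametric bootstrap: simulate from the fitted model (same missingness
# pattern), refit from the fitted theta, summarize percentile intervals
pmm_bootstrap <- function(fit, Y, X, A, nboot, nth, p, control) {
  n <- nrow(Y)
  obs <- !is.na(as.vector(Y))
  V <- pmm_vcov_stacked(A, fit$Sigma_P, fit$Sigma_R)
  ch <- chol_jitter(V)
  mu <- as.vector(X %*% fit$B)
  maxit <- control$maxit %||% 200
  draws <- vector("list", nboot)
  for (b in seq_len(nboot)) {
    ystar <- mu + as.vector(crossprod(ch, rnorm(length(mu))))
    ystar[!obs] <- NA
    Yb <- matrix(ystar, n, p, dimnames = dimnames(Y))
    negb <- function(theta) {
      SP <- theta_to_cov(theta[seq_len(nth)], p)
      SR <- theta_to_cov(theta[nth + seq_len(nth)], p)
      g <- pmm_gls(Yb, X, A, SP, SR)
      if (is.null(g)) return(1e10)
      -g$loglik
    }
    ob <- optim(fit$theta, negb, method = "BFGS",
                control = list(maxit = maxit, reltol = 1e-9))
    fb <- pmm_point_fit(ob$par, Yb, X, A, nth, p)
    draws[[b]] <- list(B = fb$B, h2 = fb$h2,
                       r_P = fb$r_P[upper.tri(fb$r_P)],
                       r_R = fb$r_R[upper.tri(fb$r_R)])
  }
  qfun <- function(get, probs) apply(vapply(draws, get, get(draws[[1]]) * 0), 1, quantile, probs)
  Bd <- vapply(draws, function(d) as.vector(d$B), as.vector(fit$B))
  fit$ci_lo <- matrix(apply(Bd, 1, quantile, 0.025), nrow(fit$B), p, dimnames = dimnames(fit$B))
  fit$ci_hi <- matrix(apply(Bd, 1, quantile, 0.975), nrow(fit$B), p, dimnames = dimnames(fit$B))
  fit$p <- matrix(apply(Bd, 1, function(v) max(2 * min(mean(v > 0), mean(v < 0)), 1 / length(v))),
                  nrow(fit$B), p, dimnames = dimnames(fit$B))
  h2d <- vapply(draws, function(d) d$h2, fit$h2)
  fit$h2_ci <- apply(h2d, 1, quantile, c(0.025, 0.975))
  rpd <- vapply(draws, function(d) d$r_P, numeric(p * (p - 1) / 2))
  rrd <- vapply(draws, function(d) d$r_R, numeric(p * (p - 1) / 2))
  fit$r_P_ci <- apply(rpd, 1, quantile, c(0.025, 0.975))
  fit$r_R_ci <- apply(rrd, 1, quantile, c(0.025, 0.975))
  fit$nboot <- nboot
  fit
}

# Metropolis-within-Gibbs sampler: exact Gaussian conditional for B, adaptive
# random-walk MH on the 2 * nth log-Cholesky covariance parameters with
# N(0, 2^2) priors
pmm_mcmc <- function(theta0, Y, X, A, nth, p, control) {
  iter <- control$iter %||% 3000
  burn <- control$burn %||% 1000
  thin <- control$thin %||% 2
  prior_sd <- control$prior_sd %||% 2
  q <- ncol(X)
  theta <- theta0
  g <- pmm_gls(Y, X, A, theta_to_cov(theta[seq_len(nth)], p),
               theta_to_cov(theta[nth + seq_len(nth)], p))
  Bvec <- as.vector(g$B)
  obs <- !is.na(as.vector(Y))
  yobs <- as.vector(Y)[obs]
  Xbig <- (diag(p) %x% X)[obs, , drop = FALSE]
  loglik_at <- function(theta, Bvec) {
    V <- pmm_vcov_stacked(A, theta_to_cov(theta[seq_len(nth)], p),
                          theta_to_cov(theta[nth + seq_len(nth)], p))[obs, obs]
    ch <- chol_jitter(V)
    if (is.null(ch)) return(list(ll = -Inf))
    r <- yobs - Xbig %*% Bvec
    z <- backsolve(ch, r, transpose = TRUE)
    list(ll = -0.5 * (sum(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2)),
         ch = ch)
  }
  cur <- loglik_at(theta, Bvec)
  lprior <- function(th) sum(dnorm(th, 0, prior_sd, log = TRUE))
  scale <- 0.1
  acc <- 0; tries <- 0
  keep <- list()
  for (it in seq_len(iter)) {
    # B | theta: exact Gaussian conditional
    Xw <- backsolve(cur$ch, Xbig, transpose = TRUE)
    yw <- backsolve(cur$ch, yobs, transpose = TRUE)
    cB <- chol(crossprod(Xw) + diag(1e-10, ncol(Xw)))
    bhat <- backsolve(cB, backsolve(cB, crossprod(Xw, yw), transpose = TRUE))
    Bvec <- as.vector(bhat + backsolve(cB, rnorm(length(bhat))))
    cur <- loglik_at(theta, Bvec)
    # theta: joint random-walk MH
    prop <- theta + rnorm(length(theta), 0, scale)
    cand <- loglik_at(prop, Bvec)
    tries <- tries + 1
    if (is.finite(cand$ll) &&
        log(runif(1)) < cand$ll + lprior(prop) - cur$ll - lprior(theta)) {
      theta <- prop; cur <- cand; acc <- acc + 1
    }
    if (it <= burn && it %% 50 == 0) {  # crude adaptation toward ~25% acceptance
      rate <- acc / tries
      scale <- scale * exp(0.5 * (rate - 0.25))
      acc <- 0; tries <- 0
    }
    if (it > burn && (it - burn) %% thin == 0) {
      SP <- theta_to_cov(theta[seq_len(nth)], p)
      SR <- theta_to_cov(theta[nth + seq_len(nth)], p)
      der <- derive_pmm_quantities(SP, SR)
      keep[[length(keep) + 1]] <- list(B = Bvec, SP = SP, SR = SR, h2 = der$h2,
                                       r_P = der$r_P[upper.tri(der$r_P)],
                                       r_R = der$r_R[upper.tri(der$r_R)],
                                       ll = cur$ll)
    }
  }
  nk <- length(keep)
  Bd <- vapply(keep, `[[`, numeric(q * p), "B")
  Bmed <- matrix(apply(Bd, 1, median), q, p,
                 dimnames = list(colnames(X), colnames(Y)))
  ci <- apply(Bd, 1, quantile, c(0.025, 0.975))
  pval <- apply(Bd, 1, function(v) max(2 * min(mean(v > 0), mean(v < 0)), 1 / nk))
  SPm <- apply(vapply(keep, function(k) k$SP, matrix(0, p, p)), c(1, 2), median)
  SRm <- apply(vapply(keep, function(k) k$SR, matrix(0, p, p)), c(1, 2), median)
  dimnames(SPm) <- dimnames(SRm) <- list(colnames(Y), colnames(Y))
  h2d <- vapply(keep, `[[`, numeric(p), "h2")
  rpd <- vapply(keep, `[[`, numeric(p * (p - 1) / 2), "r_P")
  rrd <- vapply(keep, `[[`, numeric(p * (p - 1) / 2), "r_R")
  der <- derive_pmm_quantities(SPm, SRm)
  list(B = Bmed,
       ci_lo = matrix(ci[1, ], q, p, dimnames = dimnames(Bmed)),
       ci_hi = matrix(ci[2, ], q, p, dimnames = dimnames(Bmed)),
       p = matrix(pval, q, p, dimnames = dimnames(Bmed)),
       Sigma_P = SPm, Sigma_R = SRm, theta = theta,
       h2 = apply(h2d, 1, median),
       r_P = der$r_P, r_R = der$r_R,
       h2_ci = apply(h2d, 1, quantile, c(0.025, 0.975)),
       r_P_ci = apply(rpd, 1, quantile, c(0.025, 0.975)),
       r_R_ci = apply(rrd, 1, quantile, c(0.025, 0.975)),
       h2_draws = h2d,
       loglik = median(vapply(keep, `[[`, 0, "ll")),
       convergence = list(draws = nk, accept_scale = scale))
}

#' @export
print.pmm_fit <- function(x, ...) {
  cat("Phylogenetic mixed model fit (", x$method, "), ", x$n, " species, logLik = ",
      round(x$loglik, 2), "\n", sep = "")
  cat("  h2:", paste(names(x$h2), round(x$h2, 3), collapse = ", "), "\n")
  rp <- x$r_P[upper.tri(x$r_P)]
  cat("  phylogenetic correlations (fp, fs, ps):", paste(round(rp[c(1, 2, 3)], 3), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a mixed-model fit as publication-style tables
#'
#' Produces the two standard summaries: a coefficient table (9 terms x 3
#' traits with estimate, interval and p-value per trait) and a covariance
#' table whose diagonal holds the phylogenetic heritabilities, upper triangle
#' the phylogenetic correlations, lower triangle the residual correlations.
#'
#' @param fit a [fit_pmm()] result.
#' @return a list with data frames `coefficients` and `covariances`.
#' @export
summarize_pmm <- function(fit) {
  traits <- colnames(fit$B)
  coefs <- data.frame(term = rownames(fit$B), stringsAsFactors = FALSE)
  for (tr in traits) {
    coefs[[paste0(tr, "_beta")]] <- fit$B[, tr]
    coefs[[paste0(tr, "_lo")]] <- fit$ci_lo[, tr]
    coefs[[paste0(tr, "_hi")]] <- fit$ci_hi[, tr]
    coefs[[paste0(tr, "_p")]] <- fit$p[, tr]
  }
  rownames(coefs) <- NULL
  M <- matrix(NA_real_, length(traits), length(traits),
              dimnames = list(traits, traits))
  diag(M) <- fit$h2
  M[upper.tri(M)] <- fit$r_P[upper.tri(fit$r_P)]
  M[lower.tri(M)] <- fit$r_R[lower.tri(fit$r_R)]
  cov_df <- data.frame(trait = traits, M, check.names = FALSE)
  rownames(cov_df) <- NULL
  list(coefficients = coefs, covariances = cov_df)
}
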