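# Scalar Ornstein-Uhlenbeck shift-regime modeling: all traits share one
# selection strength alpha; "shifts" are jumps in the optimum vector placed at
# the start of tree edges, defining selection regimes. On an ultrametric tree
# the tip means are linear in clade indicators, so for fixed alpha the model
# is a multivariate GLS with an edge-selection problem, profiled over an
# alpha grid.

# depth (root distance) of every node; tips first, then internals
node_depths <- function(tree) ape::node.depth.edgelength(tree)

# tip covariance (relative, per trait) under scalar OU with fixed root:
# C[i,j] = exp(-alpha (d_i + d_j - 2 t_ij)) (1 - exp(-2 alpha t_ij)) / (2 alpha)
# which is the Brownian matrix t_ij at alpha = 0
scou_covariance <- function(tree, alpha) {
  T0 <- phylo_covariance(tree)
  if (alpha == 0) return(T0)
  d <- diag(T0)
  exp(-alpha * (outer(d, d, "+") - 2 * T0)) * (1 - exp(-2 * alpha * T0)) / (2 * alpha)
}

# tip sets below each edge (indexed by rows of tree$edge)
edge_clades <- function(tree) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  names(desc) <- NULL
  desc
}

internal_edges <- function(tree) which(tree$edge[, 2] > ape::Ntip(tree))

# regime index of every tip given shift edges: 0 = root regime, k = most
# recent shift (position in `shifts`) on the root-to-tip path
tip_regimes <- function(tree, shifts) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  reg <- integer(ntot)
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    k <- match(e, shifts)
    reg[tree$edge[e, 2]] <- if (!is.na(k)) k else reg[tree$edge[e, 1]]
  }
  reg[seq_len(ape::Ntip(tree))]
}

# mean-effect design of shift edges: column e is, for tips below edge e,
# 1 - exp(-alpha * (time from the edge's start to the tip)), an indicator at
# alpha = 0
edge_design <- function(tree, alpha, edges, clades = edge_clades(tree),
                        depths = node_depths(tree)) {
  n <- ape::Ntip(tree)
  U <- matrix(0, n, length(edges))
  for (j in seq_along(edges)) {
    e <- edges[j]
    tips <- clades[[e]]
    s <- depths[tree$edge[e, 1]]
    U[tips, j] <- if (alpha > 0) 1 - exp(-alpha * (depths[tips] - s)) else 1
  }
  U
}

#' Log-likelihood of tip traits under scalar OU with optimum shifts
#'
#' Gaussian log-density of the observed trait cells under a scalar
#' Ornstein-Uhlenbeck process: tip means follow the piecewise-constant optima
#' through the exact decay `exp(-alpha t)`, the covariance is the closed-form
#' OU tip covariance times the trait rate matrix, and missing cells are
#' marginalized. At `alpha = 0` this is exactly the Brownian-motion likelihood
#' with step-change means.
#'
#' @param Y n x p matrix of logit-scale trait values in tree tip order (`NA`
#'   allowed).
#' @param tree a `"phylo"` object.
#' @param shifts integer vector of edge indices carrying optimum shifts.
#' @param Theta (K+1) x p optima: row 1 is the root regime, row k+1 the regime
#'   created by `shifts[k]`.
#' @param alpha common selection strength, >= 0.
#' @param rates p x p PSD rate matrix of the driving noise.
#' @param root root state; defaults to the root optimum `Theta[1, ]`.
#' @return the log-likelihood.
#' @export
scou_loglik <- function(Y, tree, shifts, Theta, alpha, rates, root = NULL) {
  Y <- as.matrix(Y)
  Theta <- matrix(Theta, ncol = ncol(Y))
  if (nrow(Theta) != length(shifts) + 1)
    stop_input("Theta must have one row per regime (K + 1)")
  if (alpha < 0) stop_input("alpha must be >= 0")
  if (length(shifts) && (any(shifts < 1) || any(shifts > nrow(tree$edge))))
    stop_input("shift on non-existent edge")
  if (anyDuplicated(shifts)) stop_input("two shifts on one edge")
  if (is.null(root)) root <- Theta[1, ]
  M <- scou_means(tree, shifts, Theta, alpha, root)
  C <- scou_covariance(tree, alpha)
  mvn_marginal_loglik(Y, M, rates, C)
}

# tip mean matrix under the scalar OU shift model
scou_means <- function(tree, shifts, Theta, alpha, root) {
  n <- ape::Ntip(tree)
  p <- ncol(Theta)
  depths <- node_depths(tree)
  # optimum-change vector of each shift: new regime minus the regime above it
  parentreg <- shift_parent_regimes(tree, shifts)
  M <- matrix(rep(Theta[1, ], each = n), n, p)
  if (alpha > 0)
    M <- M + exp(-alpha * depths[seq_len(n)]) %o% (root - Theta[1, ])
  if (length(shifts)) {
    delta <- Theta[-1, , drop = FALSE] - Theta[parentreg + 1, , drop = FALSE]
    U <- edge_design(tree, alpha, shifts)
    M <- M + U %*% delta
  }
  M
}

# regime index (0-based, 0 = root) directly above each shift edge
shift_parent_regimes <- function(tree, shifts) {
  if (!length(shifts)) return(integer(0))
  ntot <- ape::Ntip(tree) + tree$Nnode
  reg <- integer(ntot)
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  out <- integer(length(shifts))
  for (e in ord) {
    k <- match(e, shifts)
    if (!is.na(k)) {
      out[k] <- reg[tree$edge[e, 1]]
      reg[tree$edge[e, 2]] <- k
    } else reg[tree$edge[e, 2]] <- reg[tree$edge[e, 1]]
  }
  out
}

# Gaussian log-density of observed cells of Y with mean M and covariance
# rates (x) C (vec stacked trait-major)
mvn_marginal_loglik <- function(Y, M, rates, C, jitter = 1e-8) {
  y <- as.vector(Y)
  obs <- !is.na(y)
  V <- (rates %x% C)[obs, obs, drop = FALSE]
  ch <- chol_jitter(V, jitter)
  if (is.null(ch)) stop_input("covariance not positive definite after jitter")
  r <- y[obs] - as.vector(M)[obs]
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (sum(obs) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Phylogenetic half-life
#'
#' Time for the expected trait value to move halfway to its optimum,
#' `ln(2) / alpha`, expressed in units of the tree height.
#'
#' @param alpha selection strength (> 0).
#' @param tree_height total tree height in the same time units as `alpha`
#'   (1 for trees rescaled by [scale_tree_height()]).
#' @return `ln(2) / (alpha * tree_height)`; `+Inf` with a warning for
#'   `alpha <= 0` (no pull: pure Brownian motion).
#' @export
half_life <- function(alpha, tree_height = 1) {
  if (alpha <= 0) {
    warning("alpha <= 0: half-life is infinite (Brownian motion)")
    return(Inf)
  }
  log(2) / (alpha * tree_height)
}

#' Back-transform logit-scale optima to percentages
#'
#' Inverse logit then times 100, per cell: the g/100 g scale on which milk
#' concentrations are reported.
#'
#' @param Theta_logit numeric matrix (or vector) of logit-scale optima.
#' @return same shape, in g/100 g.
#' @export
back_transform_optima <- function(Theta_logit) {
  100 * inv_logit(Theta_logit)
}

#' Default selection-strength grid
#'
#' The Brownian limit (alpha = 0, where shifts are step changes in the mean
#' and optima are reported as mean levels) plus a log-spaced grid from
#' effectively Brownian behaviour (half-life hundreds of tree heights) to very
#' strong pull (half-life ~1% of tree height), for unit-height trees. Ties in
#' the profile likelihood resolve to the smallest alpha.
#'
#' @param length.out number of positive grid points.
#' @return numeric vector.
#' @export
default_alpha_grid <- function(length.out = 8) {
  c(0, exp(seq(log(1e-3), log(50), length.out = length.out)))
}

# ---- fitting ---------------------------------------------------------------

# extract (Y, tree) from the accepted input forms
scou_data <- function(data, tree) {
  if (inherits(data, "aligned_dataset")) {
    tree <- data$tree
    if (trait_scale(data$traits) != "logit")
      stop_input("traits must be on the logit scale")
    Y <- trait_values(data$traits)
  } else if (inherits(data, "trait_matrix")) {
    if (is.null(tree)) stop_input("tree required when data is a trait table")
    Y <- trait_values(data)[match(tree$tip.label, data$species), , drop = FALSE]
  } else {
    if (is.null(tree)) stop_input("tree required")
    Y <- as.matrix(data)
  }
  rownames(Y) <- tree$tip.label
  list(Y = Y, tree = tree)
}

# per-alpha precomputation
scou_pre <- function(tree, alpha) {
  C <- scou_covariance(tree, alpha)
  ch <- chol(C + diag(1e-10 * mean(diag(C)), nrow(C)))
  ie <- internal_edges(tree)
  clades <- edge_clades(tree)
  U <- edge_design(tree, alpha, ie, clades)
  colnames(U) <- as.character(ie)
  # whitened [1 | U] computed once: candidate fits just subset columns
  Xw <- backsolve(ch, cbind(1, U), transpose = TRUE)
  list(alpha = alpha, C = C, ch = ch, logdetC = 2 * sum(log(diag(ch))),
       internal = ie, clades = clades, U = U, Xw = Xw)
}

# complete-data profile log-likelihood of a shift edge set (matrix-normal GLS)
scou_gls_set <- function(Yc, pre, set, Zw = backsolve(pre$ch, Yc, transpose = TRUE)) {
  n <- nrow(Yc); p <- ncol(Yc)
  Xw <- pre$Xw[, c(1L, match(set, pre$internal) + 1L), drop = FALSE]
  fit <- lm.fit(Xw, Zw)
  res <- as.matrix(fit$residuals)
  Sres <- crossprod(res) / n
  ld <- determinant(Sres + diag(1e-12, p), logarithm = TRUE)$modulus
  ll <- -0.5 * (n * p * log(2 * pi) + p * pre$logdetC + n * as.numeric(ld) + n * p)
  cf <- as.matrix(fit$coefficients)
  cf[is.na(cf)] <- 0
  list(ll = ll, mu = cf[1, ], delta = cf[-1, , drop = FALSE], rates = Sres)
}

# does a shift set leave every regime (including the root's) with at least
# one tip? checked on precomputed clade tip sets: a shift's regime is empty
# iff its clade is covered by shifts nested strictly inside it
parsimonious_set <- function(set, clades, ntip) {
  if (!length(set)) return(TRUE)
  cl <- clades[set]
  if (length(unique(unlist(cl))) >= ntip) return(FALSE)  # empty root regime
  for (j in seq_along(set)) {
    tips <- cl[[j]]
    inner <- cl[-j]
    nested <- inner[vapply(inner, function(x)
      length(x) < length(tips) && all(x %in% tips), TRUE)]
    if (length(nested) && all(tips %in% unlist(nested))) return(FALSE)
  }
  TRUE
}

# rank internal edges by a group-lasso path of whitened traits on whitened
# edge indicators; returns the top-K edge set (or NULL on failure)
lasso_edge_set <- function(Yc, pre, K, Zw = backsolve(pre$ch, Yc, transpose = TRUE)) {
  E <- length(pre$internal)
  if (K == 0 || E == 0) return(integer(0))
  g <- tryCatch(
    glmnet::glmnet(pre$Xw, Zw, family = "mgaussian", intercept = FALSE,
                   standardize = TRUE, penalty.factor = c(0, rep(1, E)),
                   nlambda = 100, lambda.min.ratio = 1e-4),
    error = function(e) NULL)
  if (is.null(g)) return(NULL)
  norms <- Reduce(`+`, lapply(g$beta, function(b) as.matrix(b[-1, , drop = FALSE])^2))
  nact <- colSums(norms > 0)
  j <- which(nact >= K)[1]
  if (is.na(j)) j <- which.max(nact)
  top <- order(-norms[, j])[seq_len(min(K, sum(norms[, j] > 0)))]
  if (length(top) < K) return(NULL)
  sort(pre$internal[top])
}

# hill-climbing swap refinement of a shift set under the parsimony constraint
swap_refine <- function(Yc, pre, tree, set, Zw, max_pass = 2) {
  if (!length(set)) return(set)
  best <- scou_gls_set(Yc, pre, set, Zw)$ll
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (j in seq_along(set)) {
      for (e in setdiff(pre$internal, set)) {
        cand <- sort(c(set[-j], e))
        if (!parsimonious_set(cand, pre$clades, nrow(Yc))) next
        ll <- scou_gls_set(Yc, pre, cand, Zw)$ll
        if (ll > best + 1e-9) {
          set <- cand; best <- ll; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  set
}

# best single edge to add to `base` (forward step)
forward_edge <- function(Yc, pre, tree, base, Zw) {
  cand_edges <- setdiff(pre$internal, base)
  best <- NULL; bll <- -Inf
  for (e in cand_edges) {
    cand <- sort(c(base, e))
    if (!parsimonious_set(cand, pre$clades, nrow(Yc))) next
    ll <- scou_gls_set(Yc, pre, cand, Zw)$ll
    if (ll > bll) { bll <- ll; best <- cand }
  }
  best
}

# one (alpha, K) fit on (possibly incomplete) data by imputation-EM
fit_scou_alpha_K <- function(Y, tree, pre, K, base = NULL, em_max = 10,
                             em_tol = 1e-3, swap_pass = 2) {
  n <- nrow(Y); p <- ncol(Y)
  miss <- is.na(Y)
  Yc <- Y
  # initial completion: per-trait Gaussian conditional mean under this
  # alpha's tip covariance around the observed mean
  for (j in seq_len(p)) {
    mj <- miss[, j]
    if (!any(mj)) next
    mu <- mean(Y[, j], na.rm = TRUE)
    Coo <- pre$C[!mj, !mj] + diag(1e-10 * mean(diag(pre$C)), sum(!mj))
    Yc[mj, j] <- mu + pre$C[mj, !mj, drop = FALSE] %*% solve(Coo, Y[!mj, j] - mu)
  }
  iter_max <- if (any(miss)) em_max else 1L
  set <- integer(0); g <- NULL
  for (it in seq_len(iter_max)) {
    Zw <- backsolve(pre$ch, Yc, transpose = TRUE)
    if (it <= 2) {  # full candidate generation early; later passes refine
      cands <- list(lasso_edge_set(Yc, pre, K, Zw))
      if (!is.null(base)) cands <- c(cands, list(forward_edge(Yc, pre, tree, base, Zw)))
      if (length(set)) cands <- c(cands, list(set))
      cands <- Filter(function(s) !is.null(s) && length(s) == K &&
                        parsimonious_set(s, pre$clades, n), cands)
      if (K > 0 && !length(cands)) {
        # build up greedily from scratch as a last resort
        s <- integer(0)
        for (k in seq_len(K)) s <- forward_edge(Yc, pre, tree, s, Zw)
        cands <- list(s)
      }
      if (K == 0) cands <- list(integer(0))
      lls <- vapply(cands, function(s) scou_gls_set(Yc, pre, s, Zw)$ll, 0)
      set <- cands[[which.max(lls)]]
    }
    set <- swap_refine(Yc, pre, tree, set, Zw,
                       max_pass = if (it == 1) swap_pass else 1)
    g <- scou_gls_set(Yc, pre, set, Zw)
    if (!any(miss)) break
    # E-step: conditional expectation of missing cells given current params
    M <- matrix(rep(g$mu, each = n), n, p)
    if (length(set)) M <- M + pre$U[, match(set, pre$internal), drop = FALSE] %*% g$delta
    V <- g$rates %x% pre$C
    obs <- !as.vector(miss)
    mv <- as.vector(M)
    cond <- mv[!obs] + V[!obs, obs, drop = FALSE] %*%
      solve(V[obs, obs] + diag(1e-10 * mean(diag(V)), sum(obs)),
            as.vector(Y)[obs] - mv[obs])
    Ynew <- Yc
    Ynew[miss] <- cond
    delta_imp <- max(abs(Ynew[miss] - Yc[miss]))
    Yc <- Ynew
    if (delta_imp < em_tol) break
  }
  # observed-data log-likelihood at the final parameters
  M <- matrix(rep(g$mu, each = n), n, p)
  if (length(set)) M <- M + pre$U[, match(set, pre$internal), drop = FALSE] %*% g$delta
  ll_obs <- mvn_marginal_loglik(Y, M, g$rates, pre$C)
  list(set = set, mu = g$mu, delta = g$delta, rates = g$rates,
       loglik = ll_obs, Yc = Yc, alpha = pre$alpha)
}

# assemble the user-facing fit object
build_shift_fit <- function(rec, Y, tree, criterion_curve = NULL) {
  alpha <- rec$alpha
  p <- ncol(Y)
  K <- length(rec$set)
  traits <- colnames(Y)
  # Regime values are reported as expected tip-level trait values (root level
  # plus cumulative mean changes). These equal the OU optima in the strong-pull
  # (equilibrium) limit; under weak pull the raw optimum delta / (1 - e^(-a t))
  # is barely identifiable and diverges as alpha -> 0, while the mean level is
  # what the data constrain and what regime tables report.
  Theta <- matrix(NA_real_, K + 1, p, dimnames = list(NULL, traits))
  Theta[1, ] <- rec$mu
  if (K > 0) {
    preg <- shift_parent_regimes(tree, rec$set)
    clades <- edge_clades(tree)
    U <- edge_design(tree, alpha, rec$set, clades)
    for (k in seq_len(K)) {
      w <- mean(U[clades[[rec$set[k]]], k])
      Theta[k + 1, ] <- Theta[preg[k] + 1, ] + w * rec$delta[k, ]
    }
  }
  miss <- is.na(Y)
  imputed <- NULL
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)
    imputed <- data.frame(species = rownames(Y)[idx[, 1]],
                          trait = traits[idx[, 2]],
                          value = rec$Yc[miss], stringsAsFactors = FALSE)
  }
  structure(list(K = K, shifts = rec$set, delta = rec$delta, Theta = Theta,
                 Theta_pct = back_transform_optima(Theta), alpha = alpha,
                 rates = rec$rates, root = rec$mu, loglik = rec$loglik,
                 half_life = if (alpha > 0) half_life(alpha, tree_height(tree)) else Inf,
                 tip_regimes = setNames(tip_regimes(tree, rec$set), rownames(Y)),
                 imputed = imputed, criterion_curve = criterion_curve),
            class = "shift_fit")
}

#' @export
print.shift_fit <- function(x, ...) {
  cat("Scalar-OU shift fit: K =", x$K, "shifts, alpha =", signif(x$alpha, 3),
      "(half-life", signif(x$half_life, 3), "tree heights), logLik =",
      round(x$loglik, 2), "\n")
  if (x$K > 0) cat("  shift edges:", paste(x$shifts, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a scalar-OU model with a fixed number of optimum shifts
#'
#' For each selection strength on a grid, alternates conditional-mean
#' imputation of missing cells (E-step) with shift-placement and parameter
#' updates (M-step: a group-lasso ranking of candidate internal edges,
#' forward-step candidates, and hill-climbing swaps, each scored by the exact
#' profile likelihood), and returns the best fit over the grid. Shifts are
#' allowed on internal edges only and every regime must contain at least one
#' tip.
#'
#' @param data an [trim_and_align()] result with logit traits, a
#'   [trait_matrix()], or a plain matrix in tip order.
#' @param tree a `"phylo"` object (taken from `data` when it is an aligned
#'   dataset).
#' @param K number of shifts (0 = single regime).
#' @param alpha_grid selection-strength grid (see [default_alpha_grid()]).
#' @param seed optional integer seed (the search is deterministic; the seed
#'   only matters for downstream reproducibility bookkeeping).
#' @param em_max maximum imputation-EM iterations.
#' @param control list: `swap_pass` (swap-refinement passes).
#' @return an object of class `"shift_fit"`: shift edges, mean changes
#'   (`delta`), regime optima `Theta` (logit) and `Theta_pct` (g/100 g),
#'   `alpha`, `rates`, `root`, observed-data `loglik`, `half_life`,
#'   `tip_regimes`, and `imputed` values for originally missing cells.
#' @export
fit_shifts_em <- function(data, tree = NULL, K, alpha_grid = default_alpha_grid(),
                          seed = NULL, em_max = 10, control = list()) {
  if (!is.null(seed)) set.seed(seed)
  sd_ <- scou_data(data, tree)
  Y <- sd_$Y; tree <- sd_$tree
  if (K > length(internal_edges(tree))) stop_input("K exceeds the number of internal edges")
  swap_pass <- control$swap_pass %||% 2
  best <- NULL
  for (alpha in alpha_grid) {
    pre <- scou_pre(tree, alpha)
    base <- NULL
    rec <- NULL
    for (k in 0:K) {  # chain bases upward so the K-shift fit nests the best smaller fits
      rec <- fit_scou_alpha_K(Y, tree, pre, k, base = base, em_max = em_max,
                              swap_pass = swap_pass)
      base <- rec$set
    }
    if (is.null(best) || rec$loglik > best$loglik) best <- rec
  }
  if (is.null(best)) stop_convergence("no scalar-OU fit improved over initialization")
  build_shift_fit(best, Y, tree)
}

# penalized-likelihood criterion for K shifts. p(K) free parameters: p-vector
# root optimum, K p-vector shifts, p(p+1)/2 rates, one alpha. "pbic" adds a
# selection correction 2 log C(E, K) for choosing K of E internal edges.
scou_criterion <- function(loglik, K, p, n_obs, n_edges,
                           criterion = c("pbic", "bic")) {
  criterion <- match.arg(criterion)
  npar <- p * (K + 1) + p * (p + 1) / 2 + 1
  val <- -2 * loglik + npar * log(n_obs)
  if (criterion == "pbic") val <- val + 2 * lchoose(n_edges, K)
  val
}

#' Select the number of shift regimes
#'
#' Fits every K from 0 to `K_max` (sharing the selection-strength grid and
#' chaining each K's search from the best smaller fit, so the log-likelihood
#' is non-decreasing in K) and picks the K minimizing a penalized-likelihood
#' criterion. The full criterion curve is stored so near-ties between
#' neighbouring K are visible.
#'
#' @inheritParams fit_shifts_em
#' @param K_max largest number of shifts to consider.
#' @param criterion `"pbic"` (default) penalizes both the parameter count and
#'   the number of ways K edges can be chosen; `"bic"` is the plain
#'   Schwarz penalty.
#' @return the selected `"shift_fit"`, with `$criterion_curve` a data frame
#'   (`K`, `loglik`, `criterion`, `alpha`).
#' @export
select_K <- function(data, tree = NULL, K_max, criterion = c("pbic", "bic"),
                     alpha_grid = default_alpha_grid(), seed = NULL,
                     em_max = 10, control = list()) {
  criterion <- match.arg(criterion)
  if (K_max < 1) stop_input("K_max must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sd_ <- scou_data(data, tree)
  Y <- sd_$Y; tree <- sd_$tree
  p <- ncol(Y)
  n_obs <- sum(!is.na(Y))
  swap_pass <- control$swap_pass %||% 2
  ie <- internal_edges(tree)
  K_max <- min(K_max, length(ie))
  recs <- vector("list", K_max + 1)
  for (alpha in alpha_grid) {
    pre <- scou_pre(tree, alpha)
    base <- NULL
    for (k in 0:K_max) {
      rec <- fit_scou_alpha_K(Y, tree, pre, k, base = base, em_max = em_max,
                              swap_pass = swap_pass)
      base <- rec$set
      if (is.null(recs[[k + 1]]) || rec$loglik > recs[[k + 1]]$loglik)
        recs[[k + 1]] <- rec
    }
  }
  lls <- vapply(recs, `[[`, 0, "loglik")
  crit <- vapply(0:K_max, function(k)
    scou_criterion(lls[k + 1], k, p, n_obs, length(ie), criterion), 0)
  curve <- data.frame(K = 0:K_max, loglik = lls, criterion = crit,
                      alpha = vapply(recs, `[[`, 0, "alpha"))
  khat <- which.min(crit) - 1L
  build_shift_fit(recs[[khat + 1]], Y, tree, criterion_curve = curve)
}

# canonical signature of the tip partition induced by a shift set
partition_signature <- function(tree, set) {
  reg <- tip_regimes(tree, set)
  cells <- split(seq_along(reg), reg)
  cells <- cells[order(vapply(cells, min, 0L))]
  paste(vapply(cells, function(v) paste(v, collapse = ","), ""), collapse = "|")
}

#' Enumerate shift allocations equivalent to a fitted solution
#'
#' On an ultrametric tree, every allocation of K shifts that colours the tips
#' into the same regimes spans the same space of tip means, hence attains the
#' identical maximized likelihood — the model cannot distinguish them
#' (degeneracy). This enumerates all internal-edge K-sets inducing the fitted
#' partition, exhaustively when feasible and otherwise by substituting
#' alternatives for one fitted shift at a time. The first (lexicographically
#' smallest) set is the canonical report.
#'
#' @param fit a `"shift_fit"`.
#' @param tree the tree the fit used.
#' @param max_exhaustive enumerate all K-subsets when `choose(E, K)` is below
#'   this bound.
#' @return a list of sorted integer edge vectors, lexicographically ordered;
#'   always contains the fitted set.
#' @export
equivalent_solutions <- function(fit, tree, max_exhaustive = 5e4) {
  set <- sort(fit$shifts)
  K <- length(set)
  if (K == 0) return(list(integer(0)))
  ie <- internal_edges(tree)
  clades <- edge_clades(tree)
  ntip <- ape::Ntip(tree)
  sig <- partition_signature(tree, set)
  sols <- list()
  if (choose(length(ie), K) <= max_exhaustive) {
    cmb <- combn(ie, K)
    for (j in seq_len(ncol(cmb))) {
      s <- cmb[, j]
      if (parsimonious_set(s, clades, ntip) && partition_signature(tree, s) == sig)
        sols[[length(sols) + 1]] <- s
    }
  } else {
    # local search: per-shift single substitutions, then their combinations
    alts <- lapply(seq_len(K), function(j) {
      cand <- vapply(ie, function(e) {
        s <- sort(unique(c(set[-j], e)))
        length(s) == K && parsimonious_set(s, clades, ntip) &&
          partition_signature(tree, s) == sig
      }, TRUE)
      ie[cand]
    })
    grid <- expand.grid(alts, KEEP.OUT.ATTRS = FALSE)
    for (j in seq_len(nrow(grid))) {
      s <- sort(unique(as.integer(unlist(grid[j, ]))))
      if (length(s) == K && parsimonious_set(s, clades, ntip) &&
          partition_signature(tree, s) == sig)
        sols[[length(sols) + 1]] <- s
    }
  }
  sols <- unique(lapply(sols, as.integer))
  keys <- vapply(sols, function(s) paste(sprintf("%08d", s), collapse = ""), "")
  sols[order(keys)]
}
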