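# Seed-deterministic generators for trees, covariates and trivariate traits
# with the covariance structure the downstream models assume.

# symmetric PSD square root via eigendecomposition (handles singular matrices)
matrix_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Simulate an ultrametric birth-death tree
#'
#' Conditioned on `n` extant tips and rescaled to unit height, so simulated
#' rates, selection strengths and (co)variances are per unit of tree depth.
#'
#' @param n number of tips (>= 3).
#' @param birth,death speciation and extinction rates.
#' @param seed optional integer seed.
#' @return a unit-height `"phylo"` object with tips `t1..tn`.
#' @export
simulate_tree <- function(n, birth = 1, death = 0, seed = NULL) {
  if (n < 3) stop_input("need n >= 3 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n, birth = birth, death = death)
  scale_tree_height(tree)
}

# shared recursion for BM (alpha = 0) and scalar OU along the tree.
# shifts: edge indices (rows of tree$edge); delta: K x p matrix. For alpha > 0
# delta changes the optimum at the start of the edge; at alpha == 0 the
# process is BM and delta is applied directly to the mean (step change).
# Draws one p-vector of standard normals per edge in a fixed preorder, so
# alpha = 0 reproduces the BM sample path exactly, draw for draw.
sim_ou_tips <- function(tree, alpha, Sigma, root, shifts = integer(0), delta = NULL) {
  p <- length(root)
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p)
  if (anyDuplicated(shifts)) stop_input("two shifts on one edge")
  n_edge <- nrow(tree$edge)
  if (length(shifts) && (any(shifts < 1) || any(shifts > n_edge)))
    stop_input("shift edge index out of range")
  if (length(shifts) && (is.null(delta) || nrow(as.matrix(delta)) != length(shifts)))
    stop_input("delta must have one row per shift edge")
  S <- matrix_sqrt(Sigma)
  ntot <- ape::Ntip(tree) + tree$Nnode
  X <- matrix(NA_real_, ntot, p)       # trait value at each node
  TH <- matrix(NA_real_, ntot, p)      # optimum in force at each node
  rootnode <- ape::Ntip(tree) + 1L
  X[rootnode, ] <- root
  TH[rootnode, ] <- root               # root sits at the root optimum
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]; len <- tree$edge.length[e]
    th <- TH[par, ]
    jump <- 0
    k <- match(e, shifts)
    if (!is.na(k)) {
      d <- as.matrix(delta)[k, ]
      if (alpha > 0) th <- th + d else jump <- d
    }
    z <- rnorm(p)
    if (alpha > 0) {
      m <- th + (X[par, ] - th) * exp(-alpha * len)
      sdf <- sqrt((1 - exp(-2 * alpha * len)) / (2 * alpha))
    } else {
      m <- X[par, ] + jump
      sdf <- sqrt(len)
    }
    X[ch, ] <- m + sdf * as.numeric(S %*% z)
    TH[ch, ] <- th
  }
  tips <- X[seq_len(ape::Ntip(tree)), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

as_trait_matrix_sim <- function(tips) {
  trait_matrix(rownames(tips), tips[, 1], tips[, 2], tips[, 3], scale = "logit")
}

#' Simulate trivariate Brownian-motion traits on a tree
#'
#' Recursive simulation: each child value is the parent value plus a
#' multivariate normal increment with covariance `branch length * Sigma_P`.
#' Values are on the logit scale.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param Sigma_P 3x3 positive semi-definite rate (covariance) matrix.
#' @param root_state numeric length-3 root value (logit scale).
#' @param seed optional integer seed.
#' @return a [trait_matrix()] on the logit scale, rows in tip order.
#' @export
simulate_bm_traits <- function(tree, Sigma_P, root_state = c(0, 0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_trait_matrix_sim(sim_ou_tips(tree, alpha = 0, Sigma = Sigma_P, root = root_state))
}

#' Simulate traits under a scalar Ornstein-Uhlenbeck process with shifts
#'
#' All three traits share one selection strength `alpha`; optima are piecewise
#' constant along the tree, jumping by `delta[k, ]` at the start of shift edge
#' `shifts[k]`. Transitions use the exact OU Gaussian (mean decay
#' `exp(-alpha t)`, stationary variance `Sigma_rates / (2 alpha)`), so the
#' simulation is exact at any branch length. At `alpha = 0` the process is
#' Brownian motion and shifts become step changes in the mean.
#'
#' @param tree a `"phylo"` object.
#' @param alpha selection strength, >= 0.
#' @param Sigma_rates 3x3 PSD rate matrix of the driving noise.
#' @param root numeric length-3 root state (taken to be the root optimum).
#' @param shifts integer vector of edge indices (rows of `tree$edge`).
#' @param delta K x 3 matrix of optimum changes, one row per shift.
#' @param seed optional integer seed.
#' @return a [trait_matrix()] on the logit scale.
#' @export
simulate_scou_traits <- function(tree, alpha, Sigma_rates, root = c(0, 0, 0),
                                 shifts = integer(0), delta = NULL, seed = NULL) {
  if (alpha < 0) stop_input("alpha must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  as_trait_matrix_sim(sim_ou_tips(tree, alpha, Sigma_rates, root, shifts, delta))
}

# univariate BM tip values using the current RNG state (liability generator)
sim_bm_liability <- function(tree) {
  as.numeric(sim_ou_tips(tree, 0, matrix(1, 1, 1), 0))
}

#' Simulate ecological covariates with phylogenetic signal
#'
#' Discrete predictors are generated by thresholding a Brownian-motion
#' liability, so categories cluster in clades the way real ecological traits
#' do (aquatic mammals are a few clades, not a random scatter). Continuous
#' predictors are Brownian values standardized to the declared spread and
#' mean-centered, matching the log10-centered coding the mixed model expects.
#'
#' @param tree a `"phylo"` object.
#' @param seed optional integer seed.
#' @param prop_arid fraction of species in arid habitat.
#' @param aquatic_breaks cumulative fractions for aquatic levels 0..2 (the
#'   remainder is level 3).
#' @param diet_breaks cumulative fractions for herbivore and omnivore.
#' @param sd_mass,sd_output,sd_lactation spreads of the continuous predictors
#'   on the log10 scale.
#' @return a [covariate_table()] with `centered = TRUE`, rows in tip order.
#' @export
simulate_covariates <- function(tree, seed = NULL, prop_arid = 0.2,
                                aquatic_breaks = c(0.85, 0.90, 0.95),
                                diet_breaks = c(0.5, 0.8),
                                sd_mass = 1, sd_output = 0.3, sd_lactation = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  cut_ord <- function(l, probs) {
    br <- quantile(l, probs = probs, names = FALSE)
    findInterval(l, br)
  }
  std <- function(l, s) s * (l - mean(l)) / max(sd(l), 1e-12)
  arid <- as.integer(cut_ord(sim_bm_liability(tree), 1 - prop_arid))
  aquatic <- cut_ord(sim_bm_liability(tree), aquatic_breaks)
  diet <- diet_levels()[cut_ord(sim_bm_liability(tree), diet_breaks) + 1L]
  prec <- cut_ord(sim_bm_liability(tree), c(0.25, 0.5, 0.75))
  covariate_table(tree$tip.label, arid = arid, aquatic = aquatic, diet = diet,
                  female_mass = std(sim_bm_liability(tree), sd_mass),
                  rep_output = std(sim_bm_liability(tree), sd_output),
                  lactation_length = std(sim_bm_liability(tree), sd_lactation),
                  precociality = prec, centered = TRUE)
}

#' Add ecological covariates and their fixed effects to simulated traits
#'
#' Generates a covariate table with phylogenetic signal (see
#' [simulate_covariates()]), builds the 9-column design matrix, and shifts the
#' logit-scale trait values by `X %*% B`.
#'
#' @param tree a `"phylo"` object.
#' @param traits a logit-scale [trait_matrix()] aligned to the tree tips.
#' @param B 9 x 3 fixed-effect matrix in the [build_design()] column order
#'   (the intercept row is usually 0, the baseline being the simulation's root
#'   state).
#' @param seed optional integer seed.
#' @return a list with elements `traits` (shifted), `covariates`, `X`.
#' @export
attach_covariates_and_effects <- function(tree, traits, B, seed = NULL) {
  covs <- simulate_covariates(tree, seed = seed)
  X <- build_design(covs)
  B <- as.matrix(B)
  if (nrow(B) != ncol(X)) stop_input("B must have ", ncol(X), " rows")
  shift <- X %*% B
  out <- traits
  idx <- match(traits$species, tree$tip.label)
  for (j in seq_along(c("fat", "protein", "sugar")))
    out[[c("fat", "protein", "sugar")[j]]] <-
      out[[c("fat", "protein", "sugar")[j]]] + shift[idx, j]
  list(traits = out, covariates = covs, X = X)
}

#' Mask trait values completely at random
#'
#' Exactly `round(fraction * n)` entries of one trait are set missing, chosen
#' uniformly among species with an observed value.
#'
#' @param traits a [trait_matrix()].
#' @param fraction fraction in `[0, 1)`.
#' @param trait trait column to mask (default `"sugar"`, the trait with
#'   incomplete coverage in compiled milk data).
#' @param seed optional integer seed.
#' @return the trait table with masked entries `NA`; the masked species are in
#'   attribute `"masked"`.
#' @export
impose_missingness <- function(traits, fraction, trait = "sugar", seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop_input("fraction must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(traits)
  k <- round(fraction * n)
  out <- traits
  if (k > 0) {
    avail <- which(!is.na(traits[[trait]]))
    if (k > length(avail)) stop_input("not enough observed values to mask")
    idx <- sample(avail, k)
    out[[trait]][idx] <- NA_real_
    attr(out, "masked") <- traits$species[idx]
  } else attr(out, "masked") <- character(0)
  out
}

#' Generative parameters mimicking published mammalian milk estimates
#'
#' Phylogenetic and residual covariance matrices assembled from published
#' phylogenetic heritabilities (0.976, 0.997, 0.872 for fat, protein, sugar),
#' phylogenetic correlations (0.675, -0.750, -0.473) and residual correlations
#' (0.156, 0.380, 0.251), with total logit-scale variances (1.5, 1.0, 2.0);
#' fixed effects from the published trivariate mixed-model coefficient table;
#' root state at the published intercepts (about 12.0% fat, 8.7% protein,
#' 3.9% sugar back-transformed).
#'
#' @return a list with `Sigma_P`, `Sigma_R`, `B` (9 x 3, intercept row zero),
#'   `root`, `h2`, `r_P`, `total_var`.
#' @export
milk_preset_params <- function() {
  traits <- c("fat", "protein", "sugar")
  h2 <- c(fat = 0.976, protein = 0.997, sugar = 0.872)
  r_P <- matrix(c(1, 0.675, -0.750,
                  0.675, 1, -0.473,
                  -0.750, -0.473, 1), 3, dimnames = list(traits, traits))
  r_R <- matrix(c(1, 0.156, 0.380,
                  0.156, 1, 0.251,
                  0.380, 0.251, 1), 3, dimnames = list(traits, traits))
  v <- c(fat = 1.5, protein = 1.0, sugar = 2.0)
  sdP <- sqrt(h2 * v); sdR <- sqrt((1 - h2) * v)
  Sigma_P <- r_P * tcrossprod(sdP)
  Sigma_R <- r_R * tcrossprod(sdR)
  B <- rbind(intercept        = c(0, 0, 0),
             arid             = c(-0.190, -0.166, -0.019),
             aquatic          = c(0.220, 0.044, -0.376),
             diet_omnivore    = c(0.194, -0.029, 0.089),
             diet_carnivore   = c(0.799, 0.162, -0.376),
             female_mass      = c(-0.049, -0.034, -0.103),
             rep_output       = c(0.150, 0.167, -0.246),
             lactation_length = c(-0.901, 0.105, 0.398),
             precociality     = c(0.066, -0.031, -0.039))
  colnames(B) <- traits
  root <- c(fat = -2.161, protein = -2.347, sugar = -3.204)
  list(Sigma_P = Sigma_P, Sigma_R = Sigma_R, B = B, root = root,
       h2 = h2, r_P = r_P[upper.tri(r_P)], total_var = v)
}

#' Simulate a complete synthetic milk dataset
#'
#' One call producing everything the pipeline consumes: a unit-height tree,
#' logit-scale traits generated as Brownian phylogenetic effects plus
#' independent residual noise plus ecological fixed effects, covariates with
#' phylogenetic signal, and missing sugar values. The `"paper124"` preset uses
#' 124 species, the published covariance/effect structure
#' ([milk_preset_params()]) and 15 missing sugar values; `"tiny"` is a
#' 16-species, fully observed variant for examples.
#'
#' @param preset `"paper124"` or `"tiny"`.
#' @param seed integer seed controlling every random draw.
#' @param n optional tip-count override.
#' @return a list of class `"synthetic_dataset"`: `data` (an
#'   [trim_and_align()] result with logit traits) and `truth` (all generating
#'   parameter values, sufficient to score any estimator).
#' @export
simulate_milk_dataset <- function(preset = c("paper124", "tiny"), seed = 1, n = NULL) {
  preset <- match.arg(preset)
  par <- milk_preset_params()
  n <- if (!is.null(n)) n else if (preset == "paper124") 124L else 16L
  miss_frac <- if (preset == "paper124") 15 / 124 else 0
  set.seed(seed)
  tree <- simulate_tree(n)
  tips <- sim_ou_tips(tree, 0, par$Sigma_P, par$root)
  E <- matrix(rnorm(n * 3), n, 3) %*% matrix_sqrt(par$Sigma_R)
  traits <- as_trait_matrix_sim(tips + E)
  eff <- attach_covariates_and_effects(tree, traits, par$B)
  traits <- impose_missingness(eff$traits, miss_frac, "sugar")
  data <- trim_and_align(tree, traits, eff$covariates)
  truth <- c(par, list(n = n, masked = attr(traits, "masked"), seed = seed,
                       alpha = 0, shifts = integer(0)))
  structure(list(data = data, truth = truth), class = "synthetic_dataset")
}

#' Simulate the published six-regime shift scenario
#'
#' Builds a 124-tip unit-height tree and plants the published milk selection
#' regimes on it: four disjoint clades playing the roles of primates,
#' marsupials, perissodactyls and pinnipeds, plus two subclades nested inside
#' the pinniped-like clade (elephant seals and otariids). Mean changes are the
#' logit differences between the published back-transformed regime optima and
#' the published root composition (12.01% fat, 7.62% protein, 3.56% sugar);
#' trait noise uses the preset phylogenetic covariance, and 15 sugar values
#' are masked. The pull toward these optima was reported as very weak
#' (half-life several times the tree height), so tip data are generated in the
#' Brownian limit with step-change means. If a simulated tree lacks the
#' required nested clade structure the generator deterministically retries
#' with a derived seed.
#'
#' @param seed integer seed.
#' @param n number of tips.
#' @param missing_frac fraction of masked sugar values.
#' @return a list: `tree`, `traits` (logit [trait_matrix()] with missing
#'   sugar), `shifts` (named edge indices), `delta` (mean changes), `theta` /
#'   `theta_pct` (regime optima, logit and g/100 g), `root`, `clades` (tip
#'   labels per regime), `core_pinnipeds` (pinniped tips outside the two
#'   nested subclades).
#' @export
milk_shift_scenario <- function(seed = 1, n = 124, missing_frac = 15 / 124) {
  for (attempt in 0:19) {
    out <- try(milk_shift_scenario_once(seed + attempt * 1000003L, n, missing_frac),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop_convergence("could not place the regime scenario on a simulated tree")
}

milk_shift_scenario_once <- function(seed, n, missing_frac) {
  par <- milk_preset_params()
  set.seed(seed %% .Machine$integer.max)
  tree <- simulate_tree(n)
  clades <- edge_clades(tree)
  ie <- internal_edges(tree)
  sz <- lengths(clades)
  is_sub <- function(f, e) all(clades[[f]] %in% clades[[e]])
  pin <- mir <- ota <- NA_integer_
  for (e in ie[order(abs(sz[ie] - 14))]) {
    if (sz[e] < 8 || sz[e] > 26) next
    subs <- ie[ie != e & sz[ie] >= 2 & sz[ie] <= 5 & vapply(ie, is_sub, TRUE, e = e)]
    if (length(subs) < 2) next
    for (a in subs) {
      for (b in subs) {
        if (a >= b || length(intersect(clades[[a]], clades[[b]])) ||
            sz[a] + sz[b] >= sz[e]) next
        mir <- a; ota <- b
      }
    }
    if (!is.na(mir)) { pin <- e; break }
  }
  if (is.na(pin)) stop_input("no nested clade structure")
  taken <- clades[[pin]]
  pick_disjoint <- function(lo, hi, target) {
    ok <- ie[sz[ie] >= lo & sz[ie] <= hi]
    ok <- ok[!vapply(ok, function(f) any(clades[[f]] %in% taken), TRUE)]
    if (!length(ok)) stop_input("no disjoint clade of the required size")
    f <- ok[which.min(abs(sz[ok] - target))]
    taken <<- c(taken, clades[[f]])
    f
  }
  pri <- pick_disjoint(12, 30, 20)
  mar <- pick_disjoint(8, 24, 14)
  per <- pick_disjoint(4, 12, 7)
  opt_pct <- rbind(primates = c(3.18224, 2.36287, 7.18186),
                   marsupials = c(6.83607, 7.95330, 7.71032),
                   perissodactyls = c(1.20587, 2.37018, 6.06746),
                   pinnipeds = c(59.78315, 7.97800, 0.76505),
                   mirounga = c(44.72456, 8.36046, 0.00007),
                   otariids = c(43.04597, 10.83272, 0.08824))
  colnames(opt_pct) <- c("fat", "protein", "sugar")
  root <- logit(c(fat = 12.01, protein = 7.62, sugar = 3.56) / 100)
  theta <- logit(opt_pct / 100)
  shifts <- c(primates = pri, marsupials = mar, perissodactyls = per,
              pinnipeds = pin, mirounga = mir, otariids = ota)
  parent <- rbind(root, root, root, root,
                  theta["pinnipeds", ], theta["pinnipeds", ])
  delta <- theta - parent
  # drift represents within-regime variation only: the planted shifts carry
  # the between-clade share of the preset's phylogenetic variance
  traits <- simulate_scou_traits(tree, 0, par$Sigma_P / 3, root,
                                 shifts = unname(shifts), delta = delta)
  traits <- impose_missingness(traits, missing_frac, "sugar")
  list(tree = tree, traits = traits, shifts = shifts, delta = delta,
       theta = theta, theta_pct = opt_pct, root = root,
       clades = lapply(shifts, function(e) tree$tip.label[clades[[e]]]),
       core_pinnipeds = tree$tip.label[setdiff(clades[[pin]],
                                               c(clades[[mir]], clades[[ota]]))])
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic milk dataset:", x$truth$n, "species, seed", x$truth$seed, "\n")
  cat("  masked sugar values:", length(x$truth$masked), "\n")
  invisible(x)
}
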