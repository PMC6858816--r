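# Fixtures and independent brute-force oracles used across test files.

tree3 <- function() read_newick(text = "((A:1,B:1):1,C:2);")
tree2 <- function() read_newick(text = "(A:1,B:1);")
star3 <- function() read_newick(text = "(A:1,B:1,C:1);")

# brute-force scaled KS: evaluate both ECDFs at every pooled point
naive_ks <- function(x, y) {
  pts <- c(x, y)
  d <- max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
  sqrt(length(x) * length(y) / (length(x) + length(y))) * d
}

# brute-force Peacock: loop over every orientation and every grid point built
# from pooled per-axis coordinates, counting sample fractions directly
naive_peacock <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d <- ncol(x)
  axes <- lapply(seq_len(d), function(k) sort(unique(c(x[, k], y[, k]))))
  grid <- as.matrix(expand.grid(axes))
  orients <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  best <- 0
  count_frac <- function(S, g, o) {
    inbox <- rep(TRUE, nrow(S))
    for (k in seq_len(d))
      inbox <- inbox & if (o[k]) S[, k] >= g[k] else S[, k] <= g[k]
    mean(inbox)
  }
  for (oi in seq_len(nrow(orients))) {
    o <- orients[oi, ]
    for (gi in seq_len(nrow(grid))) {
      g <- grid[gi, ]
      best <- max(best, abs(count_frac(x, g, o) - count_frac(y, g, o)))
    }
  }
  sqrt(nrow(x) * nrow(y) / (nrow(x) + nrow(y))) * best
}

# closed-form GLS estimate (X' A^-1 X)^-1 X' A^-1 y
gls_oracle <- function(X, A, y) {
  Ai <- solve(A)
  solve(t(X) %*% Ai %*% X, t(X) %*% Ai %*% y)
}

# multivariate normal log-density from first principles
mvn_logdens <- function(y, mu, V) {
  r <- y - mu
  as.numeric(-0.5 * (length(y) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V) %*% r))
}

# quick trivariate trait table on a tree's tips from a plain matrix
tm_from_matrix <- function(tree, M, scale = "logit") {
  trait_matrix(tree$tip.label, M[, 1], M[, 2], M[, 3], scale = scale)
}
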