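# Kolmogorov-Smirnov Importance: rank-based clade-distinctiveness testing.
# The clade statistic is the sample-size-scaled KS distance between the trait
# distribution inside a clade and outside it; for trait pairs and triples the
# distance is the exact Peacock multidimensional KS statistic.

#' Sample-size-scaled two-sample Kolmogorov-Smirnov statistic
#'
#' `sqrt(n1 n2 / (n1 + n2)) * sup_t |F1(t) - F2(t)|` with empirical CDFs
#' evaluated at all pooled data points, so ties are handled exactly. The
#' scaling makes statistics comparable across clades of different sizes.
#'
#' @param x,y numeric samples (length >= 1, no `NA`).
#' @return the scaled statistic (a single number >= 0).
#' @export
ks_scaled <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop_input("empty sample")
  if (anyNA(x) || anyNA(y)) stop_input("NA values in sample")
  t <- sort(unique(c(x, y)))
  F1 <- findInterval(t, sort(x)) / length(x)
  F2 <- findInterval(t, sort(y)) / length(y)
  sqrt(length(x) * length(y) / (length(x) + length(y))) * max(abs(F1 - F2))
}

#' Exact multidimensional two-sample KS (Peacock) statistic
#'
#' Maximum over all `2^d` axis-orientation quadrants and all grid points
#' defined by the pooled per-axis sample coordinates of the empirical CDF
#' discrepancy `|F1 - F2|`, scaled by `sqrt(n1 n2 / (n1 + n2))` as in
#' [ks_scaled()]. Exact (full-enumeration-equivalent) evaluation; intended for
#' the d = 2 and d = 3 trait sets at comparative-data scale.
#'
#' @param x,y numeric matrices with the same number of columns (d = 2 or 3),
#'   one row per observation, no missing coordinates.
#' @return the scaled statistic.
#' @export
peacock_nd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d <- ncol(x)
  if (!d %in% c(2L, 3L)) stop_input("peacock_nd requires d = 2 or 3")
  if (ncol(y) != d) stop_input("samples must have the same dimension")
  if (nrow(x) < 1 || nrow(y) < 1) stop_input("empty sample")
  if (anyNA(x) || anyNA(y)) stop_input("NA coordinates in sample")
  if (d == 3L && nrow(x) + nrow(y) > 400)
    stop_input("exact trivariate statistic limited to 400 pooled points")
  n1 <- nrow(x); n2 <- nrow(y)
  sqrt(n1 * n2 / (n1 + n2)) * peacock_stat_cpp(x, y)
}

# scaled statistic dispatcher for 1-3 traits
clade_stat <- function(Yin, Yout) {
  if (ncol(Yin) == 1) ks_scaled(Yin[, 1], Yout[, 1]) else peacock_nd(Yin, Yout)
}

#' Iterative KSI search for distinctive clades
#'
#' At each rank, every internal node whose clade has at least `min_clade`
#' remaining species both inside and outside is scored by the scaled KS
#' (one trait) or exact Peacock (two or three traits) statistic between trait
#' values inside and outside the clade. The best-scoring node is reported, a
#' nodeset of near-equivalent neighbours along its ancestor/descendant chain
#' is recorded, the winning clade's species are removed, and the search
#' repeats — producing a series of clades of declining distinctiveness.
#' Species missing any trait in `trait_set` are excluded up front, and the
#' whole-tree "clade" (the root's complement) is never tested.
#'
#' @param tree a `"phylo"` object.
#' @param traits a [trait_matrix()] (logit scale by convention; the univariate
#'   statistic is invariant to monotone transforms).
#' @param trait_set character subset of `c("fat", "protein", "sugar")`.
#' @param n_ranks number of clades to extract.
#' @param min_clade minimum species inside and outside a tested clade.
#' @param nodeset_frac nodes on the winner's ancestor/descendant chain whose
#'   statistic is at least this fraction of the winner's are reported as
#'   near-equivalent.
#' @return a data frame of class `"ksi_result"`: `rank`, `node`, `label`,
#'   `statistic`, `ratio` (statistic / rank-1 statistic), `n_in`, `n_out`,
#'   `nodeset` (labels joined by "; "). Stops early with a warning when fewer
#'   than `2 * min_clade` species remain.
#' @export
ksi_search <- function(tree, traits, trait_set = c("fat", "protein", "sugar"),
                       n_ranks = 5, min_clade = 4, nodeset_frac = 0.95) {
  tree <- validate_phylogeny(tree)
  trait_set <- match.arg(trait_set, c("fat", "protein", "sugar"), several.ok = TRUE)
  if (min_clade > ape::Ntip(tree) / 2) stop_input("min_clade must be <= n/2")
  Y <- trait_values(traits, trait_set)
  Y <- Y[match(tree$tip.label, rownames(Y)), , drop = FALSE]
  rownames(Y) <- tree$tip.label
  ok <- complete.cases(Y)
  ntip <- ape::Ntip(tree)
  nodes <- ntip + seq_len(tree$Nnode)
  clades <- phangorn::Descendants(tree, nodes, type = "tips")
  labels <- node_labels(tree)
  remaining <- which(ok)
  rows <- list()
  max1 <- NA_real_
  for (rk in seq_len(n_ranks)) {
    if (length(remaining) < 2 * min_clade) {
      warning("KSI search stopped early at rank ", rk, ": only ",
              length(remaining), " species remain")
      break
    }
    stats <- rep(NA_real_, length(nodes))
    nin <- rep(NA_integer_, length(nodes))
    for (j in seq_along(nodes)) {
      inside <- intersect(clades[[j]], remaining)
      n_in <- length(inside); n_out <- length(remaining) - n_in
      if (n_in >= min_clade && n_out >= min_clade) {
        stats[j] <- clade_stat(Y[inside, , drop = FALSE],
                               Y[setdiff(remaining, inside), , drop = FALSE])
        nin[j] <- n_in
      }
    }
    if (all(is.na(stats))) {
      warning("no testable clade at rank ", rk)
      break
    }
    # ties (e.g. the two children of the root define the same split) resolve
    # to the smaller clade, the interpretable side of the split
    cand <- which(!is.na(stats) & stats >= max(stats, na.rm = TRUE) - 1e-12)
    best <- cand[order(nin[cand], nodes[cand])][1]
    best_node <- nodes[best]
    if (rk == 1) max1 <- stats[best]
    chain <- c(phangorn::Ancestors(tree, best_node, type = "all"),
               best_node,
               phangorn::Descendants(tree, best_node, type = "all"))
    near <- which(!is.na(stats) & stats >= nodeset_frac * stats[best] &
                    nodes %in% chain)
    near <- near[order(-stats[near])]
    inside <- intersect(clades[[best]], remaining)
    rows[[rk]] <- data.frame(
      rank = rk, node = best_node, label = labels[best],
      statistic = stats[best], ratio = stats[best] / max1,
      n_in = length(inside), n_out = length(remaining) - length(inside),
      nodeset = paste(labels[near], collapse = "; "),
      stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, inside)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(rank = integer(), node = integer(),
                                      label = character(), statistic = numeric(),
                                      ratio = numeric(), n_in = integer(),
                                      n_out = integer(), nodeset = character())
  structure(out, class = c("ksi_result", "data.frame"),
            trait_set = trait_set, n_species = sum(ok))
}

# display labels for internal nodes: node.label when present, else "nd<id>"
node_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- paste0("nd", ntip + seq_len(tree$Nnode))
  if (!is.null(tree$node.label)) {
    have <- !is.na(tree$node.label) & nzchar(tree$node.label)
    lab[have] <- tree$node.label[have]
  }
  lab
}

#' Run the KSI search over the standard trait-set menu
#'
#' The seven blocks: each single trait, each pair, and the full triple.
#' Species are dropped listwise within each trait set, so sets that avoid the
#' patchily measured trait retain more species.
#'
#' @inheritParams ksi_search
#' @return a named list of [ksi_search()] results.
#' @export
ksi_all_sets <- function(tree, traits, n_ranks = 5, min_clade = 4,
                         nodeset_frac = 0.95) {
  sets <- list(fat = "fat", protein = "protein", sugar = "sugar",
               `fat+protein` = c("fat", "protein"),
               `fat+sugar` = c("fat", "sugar"),
               `protein+sugar` = c("protein", "sugar"),
               `fat+protein+sugar` = c("fat", "protein", "sugar"))
  lapply(sets, function(s)
    ksi_search(tree, traits, s, n_ranks = n_ranks, min_clade = min_clade,
               nodeset_frac = nodeset_frac))
}

#' Stack KSI results into one table
#'
#' One block per trait set, mirroring the layout of published KSI summaries:
#' columns traits, rank, node label, KSI, KSI/max, nodeset.
#'
#' @param results a list of [ksi_search()] results (typically from
#'   [ksi_all_sets()]).
#' @return a data frame.
#' @export
ksi_table <- function(results) {
  if (length(results) == 0)
    return(data.frame(traits = character(), rank = integer(), node = character(),
                      KSI = numeric(), KSI_max = numeric(), nodesets = character()))
  blocks <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    nm <- names(results)[i] %||% paste(attr(r, "trait_set"), collapse = "+")
    if (nrow(r) == 0)
      return(data.frame(traits = character(), rank = integer(), node = character(),
                        KSI = numeric(), KSI_max = numeric(), nodesets = character()))
    data.frame(traits = nm, rank = r$rank, node = r$label, KSI = r$statistic,
               KSI_max = r$ratio, nodesets = r$nodeset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
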