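# Ancestral-state reconstruction and the two descriptive displays:
# phylomorphospace (tree edges drawn through reconstructed ancestors in
# trait-trait space) and the right-angle nutritional-geometry mixture plot.

#' Ancestral states under Brownian motion
#'
#' Maximum-likelihood (equivalently GLS) ancestral values for each internal
#' node, computed independently per trait by the standard two-pass pruning
#' reconstruction (via \code{phytools::fastAnc}). Tip rows hold the observed
#' values. Missing values are refused: impute (e.g. from a shift-model fit) or
#' drop those species first.
#'
#' @param tree a `"phylo"` object.
#' @param traits a [trait_matrix()] or numeric matrix with species rownames.
#' @param trait_set columns to reconstruct.
#' @return a data frame of class `"ancestral_states"`: `node` (1..Ntip are
#'   tips in tree order, then internal nodes), `type`, one column per trait.
#' @export
ancestral_bm <- function(tree, traits, trait_set = c("fat", "protein", "sugar")) {
  tree <- validate_phylogeny(tree)
  Y <- if (inherits(traits, "trait_matrix")) trait_values(traits, trait_set)
       else as.matrix(traits)[, trait_set, drop = FALSE]
  Y <- Y[match(tree$tip.label, rownames(Y)), , drop = FALSE]
  if (anyNA(Y))
    stop_input("missing trait values; impute (see fit_shifts_em) or drop species first")
  ntip <- ape::Ntip(tree)
  anc <- vapply(seq_len(ncol(Y)), function(j) {
    as.numeric(phytools::fastAnc(tree, setNames(Y[, j], tree$tip.label)))
  }, numeric(tree$Nnode))
  anc <- matrix(anc, tree$Nnode, ncol(Y))
  out <- data.frame(node = seq_len(ntip + tree$Nnode),
                    type = rep(c("tip", "internal"), c(ntip, tree$Nnode)))
  vals <- rbind(Y, anc)
  for (j in seq_len(ncol(Y))) out[[colnames(Y)[j]]] <- vals[, j]
  structure(out, class = c("ancestral_states", "data.frame"), method = "BM-GLS")
}

open_device <- function(file, width, height) {
  if (is.null(file)) return(FALSE)
  if (grepl("\\.svg$", file, ignore.case = TRUE))
    grDevices::svg(file, width = width, height = height)
  else grDevices::png(file, width = width * 100, height = height * 100, res = 100)
  TRUE
}

#' Phylomorphospace plot
#'
#' Species scattered in a plane of two traits with the tree's edges drawn
#' between each node's and its parent's (reconstructed) position, showing how
#' lineages fill trait space. Marker shape can encode an ecological category
#' (e.g. triangles for aquatic species).
#'
#' @param tree a `"phylo"` object.
#' @param traits a [trait_matrix()] or matrix with species rownames (no
#'   missing values among the plotted traits).
#' @param states optional [ancestral_bm()] result (computed if `NULL`).
#' @param pair the two traits to plot (x, y).
#' @param groups optional logical/factor named by species; `TRUE` / the second
#'   level is drawn as a triangle.
#' @param file optional output path (`.png` or `.svg`); plots to the current
#'   device when `NULL`.
#' @param width,height device size in inches.
#' @return invisibly, a list with `coords` (node positions) and `segments`
#'   (one row per tree edge).
#' @export
plot_phylomorphospace <- function(tree, traits, states = NULL,
                                  pair = c("fat", "protein"), groups = NULL,
                                  file = NULL, width = 7, height = 7) {
  if (is.null(states)) states <- ancestral_bm(tree, traits, trait_set = pair)
  coords <- cbind(states[[pair[1]]], states[[pair[2]]])
  seg <- cbind(coords[tree$edge[, 1], , drop = FALSE],
               coords[tree$edge[, 2], , drop = FALSE])
  colnames(seg) <- c("x0", "y0", "x1", "y1")
  opened <- open_device(file, width, height)
  if (opened) on.exit(grDevices::dev.off(), add = TRUE)
  ntip <- ape::Ntip(tree)
  pch <- rep(16L, ntip)
  if (!is.null(groups)) {
    g <- groups[tree$tip.label]
    pch[which(as.logical(as.integer(as.factor(g)) > 1 | g == TRUE))] <- 17L
  }
  graphics::plot(coords[seq_len(ntip), 1], coords[seq_len(ntip), 2],
                 xlab = pair[1], ylab = pair[2], pch = pch,
                 xlim = range(coords[, 1]), ylim = range(coords[, 2]))
  graphics::segments(seg[, 1], seg[, 2], seg[, 3], seg[, 4], col = "grey60")
  graphics::points(coords[seq_len(ntip), 1], coords[seq_len(ntip), 2], pch = pch)
  graphics::points(coords[-seq_len(ntip), 1], coords[-seq_len(ntip), 2],
                   pch = 1, cex = 0.5, col = "grey40")
  invisible(list(coords = coords, segments = seg, file = file))
}

#' Right-angle mixture (nutritional geometry) plot
#'
#' Fat against protein after the three macronutrients are renormalized to sum
#' to 100, so the third component (sugar) appears as diagonal isoclines
#' `fat + protein = 100 - sugar`, drawn at a fixed spacing. All renormalized
#' points fall inside the right triangle bounded by the axes and the
#' sugar = 0 isocline.
#'
#' @param traits a raw-scale [trait_matrix()]; renormalized internally if the
#'   components do not already sum to 100.
#' @param isocline_every spacing of the sugar isoclines in percent.
#' @inheritParams plot_phylomorphospace
#' @return invisibly, a list with `points` (renormalized protein/fat) and
#'   `isoclines` (sugar levels drawn).
#' @export
plot_mixture_triangle <- function(traits, isocline_every = 25, file = NULL,
                                  width = 7, height = 7) {
  comp <- cbind(traits$fat, traits$protein, traits$sugar)
  sums <- rowSums(comp)
  if (any(abs(sums[complete.cases(comp)] - 100) > 1e-9))
    traits <- renormalize_composition(traits)
  keep <- complete.cases(cbind(traits$fat, traits$protein, traits$sugar))
  pts <- data.frame(species = traits$species[keep], protein = traits$protein[keep],
                    fat = traits$fat[keep])
  levels <- seq(0, 100 - isocline_every, by = isocline_every)
  opened <- open_device(file, width, height)
  if (opened) on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot(pts$protein, pts$fat, xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "protein (% of macronutrients)",
                 ylab = "fat (% of macronutrients)", pch = 16)
  for (s in levels)
    graphics::segments(0, 100 - s, 100 - s, 0, lty = 3, col = "grey50")
  invisible(list(points = pts, isoclines = levels, file = file))
}
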