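#' Normalize species names
#'
#' Exact-match plumbing used everywhere species labels are compared: trims
#' surrounding whitespace and converts internal whitespace to underscores, so
#' `"Castor fiber "` and `"Castor_fiber"` match. No fuzzy taxonomy matching is
#' attempted.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species_names <- function(x) {
  gsub("[ \t]+", "_", trimws(as.character(x)))
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation this package relies on:
#' branch lengths present and non-negative, unique tip labels, positive tree
#' height. Polytomies and zero-length internal branches are allowed.
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string, used instead of `path`.
#' @return an object of class `"phylo"` with normalized tip labels.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop_input("could not parse Newick input")
  validate_phylogeny(tree)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("not a 'phylo' object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop_input("tree must have branch lengths on every edge")
  if (any(tree$edge.length < 0)) stop_input("negative branch lengths are not allowed")
  tree$tip.label <- normalize_species_names(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop_input("duplicate tip labels: ",
               paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (tree_height(tree) <= 0) stop_input("tree height must be > 0")
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree a `"phylo"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Total height of a rooted tree
#'
#' Maximum root-to-tip path length.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return a single number.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Rescale a tree to unit height
#'
#' Divides all branch lengths by the tree height so the maximum root-to-tip
#' distance is 1. Used so that the selection strength alpha and phylogenetic
#' (co)variances are expressed per unit of total tree depth, making
#' heritability and half-life scale-free.
#'
#' @param tree a `"phylo"` object.
#' @return a `"phylo"` object with height 1 (within 1e-10).
#' @export
scale_tree_height <- function(tree) {
  h <- tree_height(tree)
  if (h <= 0) stop_input("cannot rescale a zero-height tree")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Phylogenetic covariance matrix under Brownian motion
#'
#' The standard shared-branch-length matrix: entry (i, j) is the summed branch
#' length from the root to the most recent common ancestor of tips i and j,
#' and the diagonal holds root-to-tip distances. Symmetric positive
#' semi-definite by construction; rows/columns follow the tree tip order.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return an n x n matrix with dimnames equal to the tip labels.
#' @export
phylo_covariance <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Milk trait table
#'
#' Species-level concentrations of fat, protein and sugar, plus optional dry
#' matter, all in g/100 g on the raw scale. Concentrations of exactly zero
#' (e.g. sugar reported below detection limits) cannot be logit-transformed;
#' by default they are mapped to missing with a warning.
#'
#' @param species character vector of species names.
#' @param fat,protein,sugar numeric concentrations in g/100 g; `NA` allowed.
#' @param dry_matter optional numeric, g/100 g.
#' @param scale `"raw"` (g/100 g) or `"logit"` (logit of the proportion).
#' @param zero_to_na if `TRUE` (default), raw values of exactly 0 become `NA`
#'   with a warning rather than failing the logit transform later.
#' @return a data frame of class `"trait_matrix"` with a `"scale"` attribute.
#' @export
trait_matrix <- function(species, fat, protein, sugar, dry_matter = NULL,
                         scale = c("raw", "logit"), zero_to_na = TRUE) {
  scale <- match.arg(scale)
  species <- normalize_species_names(species)
  if (anyDuplicated(species))
    stop_input("duplicate species in trait table: ",
               paste(unique(species[duplicated(species)]), collapse = ", "))
  df <- data.frame(species = species, fat = as.numeric(fat),
                   protein = as.numeric(protein), sugar = as.numeric(sugar),
                   stringsAsFactors = FALSE)
  df$dry_matter <- if (is.null(dry_matter)) NA_real_ else as.numeric(dry_matter)
  if (scale == "raw") {
    comp <- c("fat", "protein", "sugar")
    if (zero_to_na) {
      nzero <- sum(vapply(comp, function(k) sum(df[[k]] == 0, na.rm = TRUE), 0L))
      if (nzero > 0) {
        warning(nzero, " zero concentration value(s) treated as missing (below detection)")
        for (k in comp) df[[k]][!is.na(df[[k]]) & df[[k]] == 0] <- NA_real_
      }
    }
    for (k in comp) {
      bad <- !is.na(df[[k]]) & (df[[k]] <= 0 | df[[k]] >= 100)
      if (any(bad))
        stop_input(k, " must be strictly in (0, 100) g/100 g; offending species: ",
                   paste(df$species[bad], collapse = ", "))
    }
  }
  structure(df, class = c("trait_matrix", "data.frame"), scale = scale)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Milk trait table:", nrow(x), "species, scale =", attr(x, "scale"), "\n")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Scale of a trait table
#' @param traits a `trait_matrix`.
#' @return `"raw"` or `"logit"`.
#' @export
trait_scale <- function(traits) attr(traits, "scale")

#' Read a milk trait table from delimited text
#'
#' @param path CSV (or TSV, by extension) file with a species-name column and
#'   columns `fat`, `protein`, `sugar`, optionally `dry_matter`.
#' @param species_col name of the species column.
#' @param scale scale of the stored concentrations, `"raw"` by default.
#' @return a [trait_matrix()].
#' @export
read_traits <- function(path, species_col = "species", scale = "raw") {
  df <- read_delim_auto(path)
  if (!species_col %in% names(df)) stop_input("no column '", species_col, "' in ", path)
  for (k in c("fat", "protein", "sugar"))
    if (!k %in% names(df)) stop_input("no column '", k, "' in ", path)
  trait_matrix(df[[species_col]], df$fat, df$protein, df$sugar,
               dry_matter = if ("dry_matter" %in% names(df)) df$dry_matter else NULL,
               scale = scale)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Ecological covariate table
#'
#' The eight predictors used in the milk mixed model, with the codings the
#' analysis expects: `arid` binary 0/1; `aquatic` ordinal 0-3 (see
#' [encode_aquatic()]); `diet` a factor with levels herbivore, omnivore,
#' carnivore (herbivore is the regression reference level); `female_mass`,
#' `rep_output` and `lactation_length` continuous (log10-transformed and
#' mean-centered by [center_log_predictors()]); `precociality` ordinal.
#'
#' @param species character vector of species names.
#' @param arid integer 0/1.
#' @param aquatic integer 0-3, or character labels accepted by
#'   [encode_aquatic()].
#' @param diet character or factor: herbivore, omnivore or carnivore.
#' @param female_mass,rep_output,lactation_length numeric.
#' @param precociality ordinal integer.
#' @param centered logical: have the continuous columns already been
#'   log10-transformed and centered?
#' @return a data frame of class `"covariate_table"`.
#' @export
covariate_table <- function(species, arid, aquatic, diet, female_mass,
                            rep_output, lactation_length, precociality,
                            centered = FALSE) {
  species <- normalize_species_names(species)
  if (anyDuplicated(species)) stop_input("duplicate species in covariate table")
  if (is.character(aquatic) || is.factor(aquatic)) aquatic <- encode_aquatic(aquatic)
  aquatic <- as.integer(aquatic)
  if (any(!is.na(aquatic) & (aquatic < 0 | aquatic > 3)))
    stop_input("aquatic must be an ordinal in 0..3")
  arid <- as.integer(arid)
  if (any(!is.na(arid) & !arid %in% 0:1)) stop_input("arid must be 0/1")
  diet <- as.character(diet)
  ok <- is.na(diet) | diet %in% diet_levels()
  if (!all(ok))
    stop_input("unknown diet level(s): ", paste(unique(diet[!ok]), collapse = ", "))
  df <- data.frame(species = species, arid = arid, aquatic = aquatic,
                   diet = factor(diet, levels = diet_levels()),
                   female_mass = as.numeric(female_mass),
                   rep_output = as.numeric(rep_output),
                   lactation_length = as.numeric(lactation_length),
                   precociality = as.integer(precociality),
                   stringsAsFactors = FALSE)
  structure(df, class = c("covariate_table", "data.frame"), centered = isTRUE(centered))
}

diet_levels <- function() c("herbivore", "omnivore", "carnivore")

#' Read an ecological covariate table from delimited text
#'
#' @inheritParams read_traits
#' @param centered whether the continuous columns are already log10-centered.
#' @return a [covariate_table()].
#' @export
read_covariates <- function(path, species_col = "species", centered = FALSE) {
  df <- read_delim_auto(path)
  need <- c(species_col, "arid", "aquatic", "diet", "female_mass", "rep_output",
            "lactation_length", "precociality")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  covariate_table(df[[species_col]], df$arid, df$aquatic, df$diet, df$female_mass,
                  df$rep_output, df$lactation_length, df$precociality,
                  centered = centered)
}

#' Align a tree, trait table and covariate table on a common species set
#'
#' Tips without trait data are pruned from the tree; trait/covariate rows for
#' species absent from the tree are dropped with a warning. The surviving
#' tables are reordered to the pruned tree's tip order, so downstream code can
#' index all three by position. Species missing covariates are retained here
#' (the clade tests and shift models need traits only) and are excluded at the
#' mixed-model stage. Species missing all three milk traits are dropped.
#'
#' @param tree a `"phylo"` object.
#' @param traits a [trait_matrix()].
#' @param covariates an optional [covariate_table()]; rows are `NA`-padded for
#'   species without covariate data.
#' @return a list of class `"aligned_dataset"` with elements `tree`, `traits`,
#'   `covariates` (possibly `NULL`) and `species`.
#' @export
trim_and_align <- function(tree, traits, covariates = NULL) {
  tree <- validate_phylogeny(tree)
  if (!inherits(traits, "trait_matrix")) stop_input("traits must be a trait_matrix")
  all_missing <- is.na(traits$fat) & is.na(traits$protein) & is.na(traits$sugar)
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " species with all three milk traits missing")
    traits <- traits[!all_missing, , drop = FALSE]
  }
  common <- intersect(tree$tip.label, traits$species)
  if (length(common) < 3)
    stop_input("fewer than 3 species shared between tree and trait table")
  extra_rows <- setdiff(traits$species, tree$tip.label)
  if (length(extra_rows))
    warning("dropping ", length(extra_rows), " species not in the tree: ",
            paste(head(extra_rows, 5), collapse = ", "),
            if (length(extra_rows) > 5) ", ..." else "")
  drop_tips <- setdiff(tree$tip.label, common)
  if (length(drop_tips)) tree <- ape::drop.tip(tree, drop_tips)
  ord <- tree$tip.label
  traits <- traits[match(ord, traits$species), , drop = FALSE]
  rownames(traits) <- NULL
  covs <- NULL
  if (!is.null(covariates)) {
    if (!inherits(covariates, "covariate_table"))
      stop_input("covariates must be a covariate_table")
    idx <- match(ord, covariates$species)
    covs <- covariates[ifelse(is.na(idx), NA_integer_, idx), , drop = FALSE]
    covs$species <- ord
    rownames(covs) <- NULL
    class(covs) <- class(covariates)
    attr(covs, "centered") <- attr(covariates, "centered")
  }
  structure(list(tree = tree, traits = traits, covariates = covs, species = ord),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Aligned dataset:", length(x$species), "species; traits on",
      trait_scale(x$traits), "scale;",
      if (is.null(x$covariates)) "no covariates" else "with covariates", "\n")
  invisible(x)
}

# trait values as a plain numeric matrix (species x trait), rownames = species
trait_values <- function(traits, cols = c("fat", "protein", "sugar")) {
  m <- as.matrix(as.data.frame(traits)[, cols, drop = FALSE])
  rownames(m) <- traits$species
  m
}
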