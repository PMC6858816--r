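#' Logit and inverse-logit transforms
#'
#' Concentrations are proportions of the whole milk, so they are modeled on
#' the logit scale, which maps (0, 1) onto the real line and respects the
#' boundaries that log or identity scales ignore. `logit()` refuses values at
#' or beyond the boundaries rather than clamping; zeros in raw data should be
#' treated as missing upstream (see [trait_matrix()]).
#'
#' @param p proportions strictly in (0, 1); `NA` passes through.
#' @param x real numbers; `NA` passes through.
#' @return numeric vector.
#' @export
logit <- function(p) {
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad)) stop_input("logit requires 0 < p < 1; got ",
                           paste(format(p[bad][seq_len(min(3, sum(bad)))]), collapse = ", "))
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Transform a trait table between raw and logit scales
#'
#' Raw g/100 g concentrations are divided by 100 to become proportions before
#' the logit; dry matter is left untouched. `raw_traits()` is the inverse.
#'
#' @param traits a [trait_matrix()].
#' @return a `trait_matrix` on the other scale.
#' @export
logit_traits <- function(traits) {
  if (trait_scale(traits) == "logit") return(traits)
  out <- traits
  for (k in c("fat", "protein", "sugar")) out[[k]] <- logit(traits[[k]] / 100)
  attr(out, "scale") <- "logit"
  out
}

#' @rdname logit_traits
#' @export
raw_traits <- function(traits) {
  if (trait_scale(traits) == "raw") return(traits)
  out <- traits
  for (k in c("fat", "protein", "sugar")) out[[k]] <- 100 * inv_logit(traits[[k]])
  attr(out, "scale") <- "raw"
  out
}

#' Dry-matter consistency check
#'
#' A quality screen for compiled milk data: dry matter should be close to a
#' linear function of the summed macronutrient concentrations, so species that
#' fall far from the regression of dry matter on fat + protein (+ sugar) are
#' candidates for transcription or assay errors. The check is advisory: it
#' reports and flags, it never deletes.
#'
#' @param traits a [trait_matrix()] on the raw scale.
#' @param use_sugar include sugar in the component sum (species missing sugar
#'   are then excluded from the regression).
#' @param threshold flag species with |studentized residual| above this value.
#' @return a data frame of class `"qc_report"`, sorted by |residual|
#'   descending, with attributes `intercept`, `slope`, `r_squared`.
#' @export
dry_matter_check <- function(traits, use_sugar = TRUE, threshold = 3) {
  if (trait_scale(traits) != "raw") stop_input("dry_matter_check needs raw-scale traits")
  comp <- traits$fat + traits$protein + if (use_sugar) traits$sugar else 0
  keep <- !is.na(traits$dry_matter) & !is.na(comp)
  if (!any(keep)) {
    warning("no species with dry matter and required components; empty QC report")
    rep <- data.frame(species = character(), component_sum = numeric(),
                      dry_matter = numeric(), fitted = numeric(),
                      residual = numeric(), studentized = numeric(),
                      flagged = logical())
    return(structure(rep, class = c("qc_report", "data.frame")))
  }
  if (sum(keep) < 10)
    stop_input("need at least 10 species with dry matter and components; have ", sum(keep))
  dm <- traits$dry_matter[keep]
  cs <- comp[keep]
  fit <- lm(dm ~ cs)
  sm <- suppressWarnings(summary(fit))
  stud <- suppressWarnings(rstudent(fit))
  # an (almost) exact fit has no meaningful studentized residuals
  if (sm$sigma < 1e-10 * max(sd(dm), 1)) stud[] <- 0
  rep <- data.frame(species = traits$species[keep],
                    component_sum = cs, dry_matter = dm,
                    fitted = unname(fitted(fit)), residual = unname(resid(fit)),
                    studentized = unname(stud),
                    flagged = abs(unname(stud)) > threshold,
                    stringsAsFactors = FALSE)
  rep <- rep[order(-abs(rep$residual)), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, class = c("qc_report", "data.frame"),
            intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
            r_squared = sm$r.squared, threshold = threshold)
}

#' Ordinal coding of aquatic adaptation
#'
#' Four-level ordinal scale intended to capture aquatic lifestyle more finely
#' than a binary code: terrestrial = 0, partly aquatic = 1 (e.g. mink, beaver,
#' moose), mostly aquatic = 2 (platypus, true seals, fur seals/sea lions),
#' completely aquatic = 3 (cetaceans).
#'
#' @param category character vector with values among `"terrestrial"`,
#'   `"partly"`, `"mostly"`, `"completely"` (case-insensitive).
#' @return integer vector in 0..3.
#' @export
encode_aquatic <- function(category) {
  map <- c(terrestrial = 0L, partly = 1L, mostly = 2L, completely = 3L)
  key <- tolower(trimws(as.character(category)))
  out <- map[key]
  bad <- is.na(out) & !is.na(key)
  if (any(bad)) stop_input("unknown aquatic category: ",
                           paste(unique(key[bad]), collapse = ", "))
  unname(out)
}

#' Log10-transform and center continuous predictors
#'
#' Female mass, reproductive output and relative lactation length are
#' log10-transformed to reduce skew, then mean-centered so regression
#' intercepts refer to an average mammal. Guarded by the table's `centered`
#' flag so it cannot be applied twice.
#'
#' @param covariates a [covariate_table()] with `centered = FALSE`.
#' @param columns continuous columns to transform.
#' @return a `covariate_table` with `centered = TRUE`.
#' @export
center_log_predictors <- function(covariates,
                                  columns = c("female_mass", "rep_output",
                                              "lactation_length")) {
  if (isTRUE(attr(covariates, "centered")))
    stop_input("covariates are already log10-centered")
  out <- covariates
  for (k in columns) {
    v <- covariates[[k]]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop_input("non-positive value in '", k, "' for species: ",
                 paste(covariates$species[bad], collapse = ", "))
    lv <- log10(v)
    out[[k]] <- lv - mean(lv, na.rm = TRUE)
  }
  attr(out, "centered") <- TRUE
  out
}

#' Renormalize fat, protein and sugar to sum to 100
#'
#' The closure used by right-angle mixture (nutritional geometry) plots: each
#' macronutrient is expressed as a percentage of the fat + protein + sugar
#' total. Species with any of the three missing are left `NA` with a warning.
#'
#' @param traits a [trait_matrix()] on the raw scale.
#' @return a `trait_matrix` whose three components sum to 100 per species.
#' @export
renormalize_composition <- function(traits) {
  if (trait_scale(traits) != "raw") stop_input("renormalize_composition needs raw-scale traits")
  comp <- cbind(traits$fat, traits$protein, traits$sugar)
  complete <- complete.cases(comp)
  if (any(!complete))
    warning(sum(!complete), " species with incomplete composition left NA")
  s <- rowSums(comp)
  if (any(complete & s == 0)) stop_input("zero composition sum")
  out <- traits
  fac <- ifelse(complete, 100 / s, NA_real_)
  out$fat <- traits$fat * fac
  out$protein <- traits$protein * fac
  out$sugar <- traits$sugar * fac
  out
}
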