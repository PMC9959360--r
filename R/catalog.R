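#' Covariate catalogue for DHS-style stunting surveys
#'
#' The catalogue declares, for every determinant retained in the final
#' stunting model, its category labels (reference level first), the default
#' marginal distribution used by the synthetic survey generator, and the
#' default true conditional log-odds attached to each non-reference level.
#' Marginals follow the unweighted category counts of a national DHS-scale
#' survey of 12,627 under-5 children; effect sizes follow the adjusted
#' odds ratios of the corresponding geospatial logistic model, so that
#' synthetic surveys carry a realistic covariate-risk structure.
#'
#' Covariates are of two kinds: `child` covariates vary child-by-child
#' (illness, maternal, household and health-service factors), while
#' `cluster` covariates are climatic/urbanisation classes shared by every
#' child of a survey cluster and normally obtained by raster extraction.
#'
#' @return A named list; each element has fields `levels`, `probs`,
#'   `beta` (log-odds, one per non-reference level) and `kind`.
#' @export
covariate_catalog <- function() {
  list(
    diarrhoea = list(
      levels = c("no", "yes"),
      probs  = c(10242, 1473) / 11715,
      beta   = log(1.35),
      kind   = "child"
    ),
    ari = list(
      levels = c("no", "yes"),
      probs  = c(12112, 702) / 12814,
      beta   = log(0.99),
      kind   = "child"
    ),
    maternal_nutrition = list(
      levels = c("normal", "underweight", "overweight", "obese"),
      probs  = c(7063, 1080, 2246, 1112) / 11501,
      beta   = log(c(1.14, 0.79, 0.63)),
      kind   = "child"
    ),
    maternal_education = list(
      levels = c("no_schooling", "primary", "secondary_plus"),
      probs  = c(4546, 1864, 5308) / 11718,
      beta   = log(c(0.92, 0.69)),
      kind   = "child"
    ),
    wealth = list(
      levels = c("poor", "middle", "rich"),
      probs  = c(4433, 2427, 4858) / 11718,
      beta   = log(c(0.94, 0.75)),
      kind   = "child"
    ),
    anc_visits = list(
      levels = c("none", "1-3", "4plus"),
      probs  = c(1621, 1238, 4889) / 7748,
      beta   = log(c(1.08, 1.04)),
      kind   = "child"
    ),
    place_of_birth = list(
      levels = c("home", "facility"),
      probs  = c(6384, 5334) / 11718,
      beta   = log(0.86),
      kind   = "child"
    ),
    birth_size = list(
      levels = c("very_large", "larger", "average", "smaller", "very_small"),
      probs  = c(1061, 2845, 6367, 1156, 289) / 11718,
      beta   = log(c(1.27, 1.32, 1.64, 2.39)),
      kind   = "child"
    ),
    cooking_fuel = list(
      levels = c("not_clean", "clean"),
      probs  = c(8742, 2976) / 11718,
      beta   = log(0.79),
      kind   = "child"
    ),
    water_source = list(
      levels = c("not_protected", "protected"),
      probs  = c(6673, 6141) / 12814,
      beta   = log(0.97),
      kind   = "child"
    ),
    toilet = list(
      levels = c("not_improved", "improved"),
      probs  = c(5272, 6446) / 11718,
      beta   = log(1.04),
      kind   = "child"
    ),
    dlst = list(
      levels = c("lt30", "30to34.9", "ge35"),
      probs  = c(3471, 6366, 2676) / 12513,
      beta   = log(c(1.01, 1.11)),
      kind   = "cluster"
    ),
    rainfall = list(
      levels = c("low", "medium", "high"),
      probs  = c(7823, 4518, 474) / 12815,
      beta   = log(c(0.78, 0.77)),
      kind   = "cluster"
    ),
    aridity = list(
      levels = c("wet", "semi_arid", "arid"),
      probs  = c(1920, 4267, 6727) / 12914,
      beta   = log(c(1.16, 1.50)),
      kind   = "cluster"
    ),
    urbanization = list(
      levels = c("rural_villages", "urban_clusters", "urban_centres"),
      probs  = c(8163, 605, 4047) / 12815,
      beta   = log(c(0.83, 0.69)),
      kind   = "cluster"
    )
  )
}

#' Default log-odds (betas) implied by the covariate catalogue
#'
#' Flattens [covariate_catalog()] into the named-vector format used by
#' [sim_config()]: names are `covariate:level` for every non-reference level.
#'
#' @param covariates character vector of catalogue entries to include.
#' @return named numeric vector of log-odds.
#' @export
catalog_betas <- function(covariates = names(covariate_catalog())) {
  cat <- covariate_catalog()
  unlist(lapply(covariates, function(v) {
    entry <- cat[[v]]
    setNames(entry$beta, paste0(v, ":", entry$levels[-1]))
  }))
}
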