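## Survey descriptives: outcome derivation from HAZ, crude and
## survey-weighted prevalence cross-tabulations (Horvitz-Thompson ratio
## estimation with stratified Taylor-linearised standard errors).

#' Classify stunting from height-for-age z-scores
#'
#' A child is stunted when HAZ < -2.0 (strict inequality). Biologically
#' implausible scores (|HAZ| beyond `flag_limit`, WHO flagging convention)
#' and missing scores yield NA and drop out of prevalence denominators.
#'
#' @param haz numeric height-for-age z-scores.
#' @param flag_limit implausibility cutoff in |z| units (default 6).
#' @return integer vector of 0/1/NA.
#' @export
classify_stunting <- function(haz, flag_limit = 6) {
  out <- ifelse(haz < -2.0, 1L, 0L)
  out[!is.finite(haz) | abs(haz) > flag_limit] <- NA_integer_
  out
}

#' Half-up rounding for report output
#'
#' Published survey tables round half up to one decimal; base `round()`
#' is half-to-even. Computations carry full precision and only reports
#' use this.
#'
#' @param x numeric; `digits` decimals kept.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Survey design descriptor
#'
#' Names the stratum, primary-sampling-unit (cluster) and weight columns
#' of a child-level table, in the spirit of a `svydesign` declaration.
#'
#' @param stratum,cluster,weight column names.
#' @return a `survey_design` object.
#' @export
survey_design <- function(stratum = "stratum_id", cluster = "cluster_id",
                          weight = "weight") {
  structure(list(stratum = stratum, cluster = cluster, weight = weight),
            class = "survey_design")
}

check_design <- function(table, design) {
  for (v in unlist(design[c("stratum", "cluster", "weight")]))
    if (!v %in% names(table)) stop("design column missing from table: ", v)
  w <- table[[design$weight]]
  if (any(!is.finite(w) | w <= 0))
    stop("weights must be strictly positive")
  invisible(TRUE)
}

#' Crude (unweighted) prevalence by covariate category
#'
#' One row per category: total count and column percentage, stunted and
#' not-stunted counts with row percentages (`stunted_pct` +
#' `not_stunted_pct` = 100 before rounding). Records missing the outcome
#' or the covariate are excluded from that covariate's denominators;
#' empty categories yield n = 0 with NA percentages rather than an error.
#' Percentages are reported unrounded; use [format_prevalence()] for the
#' 1-decimal report convention.
#'
#' @param table child-level data.frame with an outcome column.
#' @param covariate covariate column name.
#' @param outcome outcome column name (0/1).
#' @return data.frame of prevalence rows.
#' @export
crude_prevalence <- function(table, covariate, outcome = "stunted") {
  if (!covariate %in% names(table)) stop("no such covariate column: ", covariate)
  x <- table[[covariate]]
  y <- table[[outcome]]
  keep <- !is.na(x) & !is.na(y)
  x <- factor(x[keep], levels = if (is.factor(x)) levels(x) else sort(unique(x[keep])))
  y <- y[keep]
  tot <- length(y)
  rows <- lapply(levels(x), function(lv) {
    sel <- x == lv
    n <- sum(sel)
    s <- sum(y[sel] == 1)
    ns <- n - s
    data.frame(covariate = covariate, category = lv,
               n = n, pct = if (tot > 0) 100 * n / tot else NA_real_,
               stunted_n = s,
               stunted_pct = if (n > 0) 100 * s / n else NA_real_,
               not_stunted_n = ns,
               not_stunted_pct = if (n > 0) 100 * ns / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Survey-weighted prevalence by covariate category
#'
#' Horvitz-Thompson ratio estimator p = sum(w y) / sum(w) per category,
#' with Taylor-linearised standard errors honouring stratification and
#' PSU clustering: the influence values z_i = w_i (y_i - p) / W are
#' totalled per PSU and their between-PSU variance accumulated per
#' stratum with the n_h/(n_h - 1) factor. A stratum contributing a single
#' PSU is treated as a certainty unit (zero variance contribution) with
#' a warning.
#'
#' @param table child-level data.frame.
#' @param design a [survey_design()].
#' @param covariate covariate column name.
#' @param outcome outcome column name (0/1).
#' @return data.frame like [crude_prevalence()] plus `stunted_pct_wt` and
#'   `se` (percentage points).
#' @export
weighted_prevalence <- function(table, design, covariate, outcome = "stunted") {
  check_design(table, design)
  crude <- crude_prevalence(table, covariate, outcome)
  x <- table[[covariate]]
  y <- table[[outcome]]
  keep <- !is.na(x) & !is.na(y)
  dat <- data.frame(
    x = x[keep], y = y[keep],
    w = table[[design$weight]][keep],
    stratum = as.character(table[[design$stratum]][keep]),
    psu = as.character(table[[design$cluster]][keep]),
    stringsAsFactors = FALSE)
  single_warned <- FALSE
  est <- lapply(crude$category, function(lv) {
    d <- dat[dat$x == lv, , drop = FALSE]
    if (nrow(d) == 0) return(c(NA_real_, NA_real_))
    W <- sum(d$w)
    p <- sum(d$w * d$y) / W
    # linearised influence per record, totalled by PSU within stratum
    z <- d$w * (d$y - p) / W
    ztot <- tapply(z, paste(d$stratum, d$psu, sep = "\r"), sum)
    zstr <- sub("\r.*$", "", names(ztot))
    v <- 0
    for (h in unique(zstr)) {
      zh <- ztot[zstr == h]
      nh <- length(zh)
      if (nh < 2) {
        if (!single_warned) {
          warning("stratum '", h, "' has a single PSU for category '", lv,
                  "'; treated as a certainty unit (zero variance contribution)")
          single_warned <<- TRUE
        }
        next
      }
      v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
    }
    c(100 * p, 100 * sqrt(v))
  })
  est <- do.call(rbind, est)
  crude$stunted_pct_wt <- est[, 1]
  crude$se <- est[, 2]
  crude
}

#' Format a prevalence table for reporting
#'
#' Applies the 1-decimal half-up rounding convention of published DHS
#' tables; computations upstream carry full precision.
#'
#' @param prev output of [crude_prevalence()] / [weighted_prevalence()].
#' @param digits decimals kept.
#' @export
format_prevalence <- function(prev, digits = 1) {
  for (cl in intersect(c("pct", "stunted_pct", "not_stunted_pct",
                         "stunted_pct_wt", "se"), names(prev)))
    prev[[cl]] <- round_half_up(prev[[cl]], digits)
  prev
}

#' Read and validate a child-level survey table
#'
#' Expects the schema written by [write_survey()]: one row per child with
#' `cluster_id`, `stratum_id`, `weight`, `haz` and/or `stunted`, and
#' covariate columns. Category labels are validated against
#' [covariate_catalog()]; `stunted` is derived from `haz` via
#' [classify_stunting()] when absent; non-positive weights are rejected
#' naming the offending rows. A row-count/missingness report is attached
#' as attribute `"report"`.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_child_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (v in c("cluster_id", "weight"))
    if (!v %in% names(df)) stop("schema error: missing column '", v, "'")
  if (!"stunted" %in% names(df)) {
    if (!"haz" %in% names(df))
      stop("schema error: need a 'stunted' or 'haz' column")
    df$stunted <- classify_stunting(df$haz)
  }
  bad_w <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad_w))
    stop("schema error: non-positive weight at row(s) ",
         paste(head(bad_w, 5), collapse = ", "))
  cat <- covariate_catalog()
  for (v in intersect(names(cat), names(df))) {
    vals <- unique(df[[v]][!is.na(df[[v]])])
    bad <- setdiff(vals, cat[[v]]$levels)
    if (length(bad))
      stop("schema error: unknown category in column '", v, "': ",
           paste(bad, collapse = ", "))
    df[[v]] <- factor(df[[v]], levels = cat[[v]]$levels)
  }
  attr(df, "report") <- list(
    n_rows = nrow(df),
    n_missing_outcome = sum(is.na(df$stunted)),
    missing_by_column = vapply(df, function(cl) sum(is.na(cl)), integer(1)))
  df
}

#' Write a synthetic survey to disk
#'
#' Emits the plain-text artifact set of the generator: `children.csv`,
#' `clusters.csv`, `admin1.geojson`, `admin2.geojson`,
#' `covariates/<name>.asc` and `truth.json` (all simulation parameters).
#'
#' @param sim result of [simulate_survey()].
#' @param dir output directory (created if needed).
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$children, file.path(dir, "children.csv"), row.names = FALSE)
  write.csv(sim$clusters, file.path(dir, "clusters.csv"), row.names = FALSE)
  write_admin_geojson(sim$admin_map, file.path(dir, "admin1.geojson"), level = 1)
  write_admin_geojson(sim$admin_map, file.path(dir, "admin2.geojson"), level = 2)
  if (length(sim$rasters)) {
    dir.create(file.path(dir, "covariates"), showWarnings = FALSE)
    for (nm in names(sim$rasters))
      write_asc(sim$rasters[[nm]], file.path(dir, "covariates", paste0(nm, ".asc")))
  }
  truth <- sim$config
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
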