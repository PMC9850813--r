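# Indirect age-sex standardization and descriptive statistics: country-level
# stratum rates applied to each area's population structure give expected
# counts E_i; relative risk is the standardized incidence ratio Y_i / E_i.

#' Canonical age-sex stratum labels
#'
#' Four strata: females 0-74, females 75+, males 0-74, males 75+.
#' @export
STRATUM_LEVELS <- c("F0_74", "F75p", "M0_74", "M75p")

validate_strata <- function(strata) {
  need <- c("area_id", "stratum", "population", "cases")
  miss <- setdiff(need, names(strata))
  if (length(miss)) {
    stop("strata table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(strata$population < 0)) stop("stratum populations must be >= 0")
  if (any(strata$cases < 0)) stop("stratum case counts must be >= 0")
  if (any(strata$cases > 0 & strata$population == 0)) {
    stop("cases observed in a stratum with zero population")
  }
  invisible(strata)
}

#' Reference (country-level) disease rates per age-sex stratum
#'
#' Pools cases and person counts over all areas within each stratum:
#' \eqn{r_s = \sum_i C_{is} / \sum_i P_{is}}.
#'
#' @param strata Data frame with columns `area_id`, `stratum`, `population`,
#'   `cases` (one row per area-stratum).
#' @return Named numeric vector of rates, one per stratum present.
#' @examples
#' st <- data.frame(area_id = c("a", "b"), stratum = "F0_74",
#'                  population = c(100, 100), cases = c(2, 3))
#' stratum_rates(st)  # 0.025
#' @export
stratum_rates <- function(strata) {
  validate_strata(strata)
  pop <- tapply(strata$population, strata$stratum, sum)
  cas <- tapply(strata$cases, strata$stratum, sum)
  if (any(pop <= 0)) {
    stop("zero total population in stratum(s): ",
         paste(names(pop)[pop <= 0], collapse = ", "))
  }
  rates <- as.numeric(cas / pop)
  names(rates) <- names(pop)
  rates
}

#' Expected counts by indirect standardization
#'
#' Applies reference stratum rates to each area's population structure:
#' \eqn{E_i = \sum_s r_s P_{is}}. When the rates are the internally computed
#' [stratum_rates()] of the same table, the calibration identity
#' \eqn{\sum_i E_i = \sum_{i,s} C_{is}} holds to numerical precision.
#'
#' @param strata Strata table as in [stratum_rates()].
#' @param rates Named per-stratum rates; defaults to the table's own pooled
#'   rates.
#' @param area_order Optional character vector fixing the output ordering;
#'   defaults to first appearance in `strata`.
#' @return Named numeric vector of expected counts per area.
#' @export
expected_counts <- function(strata, rates = stratum_rates(strata),
                            area_order = NULL) {
  validate_strata(strata)
  if (any(rates < 0)) stop("stratum rates must be nonnegative")
  miss <- setdiff(unique(as.character(strata$stratum)), names(rates))
  if (length(miss)) {
    stop("no rate supplied for stratum(s): ", paste(miss, collapse = ", "))
  }
  contrib <- strata$population * rates[as.character(strata$stratum)]
  E <- tapply(contrib, strata$area_id, sum)
  if (is.null(area_order)) area_order <- unique(as.character(strata$area_id))
  out <- as.numeric(E[area_order])
  names(out) <- area_order
  out
}

#' Relative risk (standardized incidence ratio)
#'
#' \eqn{RR_i = Y_i / E_i}: 1 means the area observed exactly the cases
#' expected from its age-sex structure; above 1, more; below 1, fewer.
#'
#' @param y Observed counts.
#' @param expected Expected counts, all strictly positive.
#' @return Numeric vector of relative risks.
#' @export
relative_risk <- function(y, expected) {
  stopifnot(length(y) == length(expected))
  bad <- which(expected <= 0)
  if (length(bad)) {
    stop("expected count must be > 0; offending area index(es): ",
         paste(bad, collapse = ", "))
  }
  as.numeric(y / expected)
}

#' Aggregated relative risk by exposure quartile
#'
#' Splits areas at the sample quartiles of an exposure column (linear
#' interpolation quantiles; values tied with a cutpoint fall in the lower
#' group) and reports the pooled relative risk
#' \eqn{\sum Y_i / \sum E_i} per group.
#'
#' @param areas Area table with columns `y_late`, `expected`, and the exposure
#'   column.
#' @param exposure Name of the exposure column (default `"exposure"`).
#' @return Data frame with one row per quartile group: `quartile`, `n_areas`,
#'   `observed`, `expected`, `rr`.
#' @export
quartile_aggregate <- function(areas, exposure = "exposure") {
  stopifnot(all(c("y_late", "expected", exposure) %in% names(areas)))
  if (nrow(areas) < 4L) stop("quartile aggregation needs at least 4 areas")
  x <- areas[[exposure]]
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  breaks <- unique(q)
  if (length(breaks) == 0L || all(x == x[1L])) {
    warning("all exposures identical; returning a single group")
    grp <- factor(rep("Q1", nrow(areas)))
  } else {
    cuts <- c(-Inf, breaks, Inf)
    grp <- cut(x, breaks = cuts, labels = paste0("Q", seq_len(length(cuts) - 1L)),
               right = TRUE)
    if (length(breaks) < 3L) {
      warning("tied quartile cutpoints; fewer than 4 groups returned")
    }
  }
  obs <- tapply(areas$y_late, grp, sum)
  exp_ <- tapply(areas$expected, grp, sum)
  keep <- !is.na(obs)
  data.frame(quartile = names(obs)[keep],
             n_areas = as.integer(table(grp)[keep]),
             observed = as.numeric(obs[keep]),
             expected = as.numeric(exp_[keep]),
             rr = as.numeric(obs[keep] / exp_[keep]),
             row.names = NULL)
}

#' Round half away from zero
#'
#' Decimal rounding with halves away from zero (so 78.45 -> 78.5), matching
#' the convention used for printed one-decimal percentages, unlike base R's
#' round-half-even.
#'
#' @param x Numeric.
#' @param digits Number of decimal places.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stage percentages by patient group
#'
#' From early/late stage counts per group (e.g. total, men, women, 75+),
#' computes the percentage of each stage with one-decimal
#' half-away-from-zero rounding, as such tables are conventionally printed.
#'
#' @param stage_table Data frame with columns `group`, `early`, `late`
#'   (counts).
#' @return Data frame with columns `group`, `early`, `late`, `total`,
#'   `early_pct`, `late_pct`.
#' @examples
#' stage_proportions(data.frame(group = "total", early = 7758, late = 28328))
#' @export
stage_proportions <- function(stage_table) {
  stopifnot(all(c("group", "early", "late") %in% names(stage_table)))
  total <- stage_table$early + stage_table$late
  if (any(total <= 0)) {
    stop("zero total count in group(s): ",
         paste(stage_table$group[total <= 0], collapse = ", "))
  }
  data.frame(group = stage_table$group,
             early = stage_table$early,
             late = stage_table$late,
             total = total,
             early_pct = round_half_away(100 * stage_table$early / total, 1L),
             late_pct = round_half_away(100 * stage_table$late / total, 1L))
}

#' Physician density per population unit
#'
#' @param count Number of physicians.
#' @param population Population size (> 0).
#' @param per Population unit, default 10,000.
#' @return Physicians per `per` people.
#' @examples
#' physician_density(5, 10000)        # 5
#' physician_density(17, 100000)      # 1.7 per 10,000
#' @export
physician_density <- function(count, population, per = 10000) {
  if (any(population <= 0)) stop("population must be > 0")
  per * count / population
}

#' Read an area table from CSV
#'
#' Expected columns: `area_id`, `y_late`, `expected`, `exposure`, and optional
#' covariates prefixed `z_`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_area_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "y_late", "expected", "exposure")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("area table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Read a strata table from CSV
#'
#' Expected columns: `area_id`, `stratum`, `population`, `cases`.
#' @param path CSV path.
#' @return Data frame (validated).
#' @export
read_strata_table <- function(path) {
  validate_strata(read.csv(path, stringsAsFactors = FALSE))
}

#' Build an area table from strata counts
#'
#' Convenience assembling the modelling table: per-area observed late-stage
#' counts (summed over strata), internally standardized expected counts, and
#' any supplied exposure/covariate columns.
#'
#' @param strata Strata table.
#' @param exposure Named numeric vector of exposures (names = area ids), or
#'   `NULL`.
#' @param covariates Optional data frame of covariate columns (rownames or
#'   `area_id` column matching area ids).
#' @return Area table data frame.
#' @export
build_area_table <- function(strata, exposure = NULL, covariates = NULL) {
  validate_strata(strata)
  ids <- unique(as.character(strata$area_id))
  y <- tapply(strata$cases, strata$area_id, sum)[ids]
  E <- expected_counts(strata, area_order = ids)
  out <- data.frame(area_id = ids, y_late = as.integer(y),
                    expected = as.numeric(E), row.names = NULL)
  if (!is.null(exposure)) out$exposure <- as.numeric(exposure[ids])
  if (!is.null(covariates)) {
    if ("area_id" %in% names(covariates)) {
      rownames(covariates) <- covariates$area_id
      covariates$area_id <- NULL
    }
    out <- cbind(out, covariates[ids, , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}
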