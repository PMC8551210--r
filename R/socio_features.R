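#' Pooled income per capita of a territory
#'
#' Ratio of the summed declared income totals to the summed declarant counts
#' over the member municipalities (the pooled ratio, not the mean of ratios).
#'
#' @param income_totals municipal declared-income totals.
#' @param declarants municipal declarant counts.
#' @return Scalar income per capita; `NA` (flagged missing) when there are no
#'   declarants.
#' @export
income_per_capita <- function(income_totals, declarants) {
  td <- sum(declarants)
  if (!is.finite(td) || td <= 0) return(NA_real_)
  sum(income_totals) / td
}

#' Mean/median inequality ratio
#'
#' The ratio of the mean to the median of an income distribution; above 1 for
#' right-skewed distributions, which is the typical shape of declared income.
#'
#' @param x numeric income values.
#' @return Scalar mean/median ratio; `NA` when the median is not positive.
#' @export
inequality_ratio <- function(x) {
  if (length(x) == 0) return(NA_real_)
  med <- stats::median(x)
  if (!is.finite(med) || med <= 0) return(NA_real_)
  mean(x) / med
}

#' Herfindahl-Hirschman concentration of sector revenues
#'
#' \deqn{HHI = \sum_j (r_j / R)^2} with `R` the total revenue; 1 when a single
#' sector holds all revenue, `1/S` when `S` sectors share it equally.
#'
#' @param revenues per-sector revenues of one territory.
#' @return Scalar HHI in `(0, 1]`; `NA` when all revenues are zero.
#' @export
revenue_concentration <- function(revenues) {
  R <- sum(revenues)
  if (!is.finite(R) || R <= 0) return(NA_real_)
  sum((revenues / R)^2)
}

#' Remote-work and essential-sector employment shares
#'
#' The remote share is the employment-weighted mean of per-sector remote-work
#' shares; the essential share is the fraction of employees in sectors
#' flagged essential.
#'
#' @param employees named per-sector employee counts.
#' @param sector_meta data.table with `sector`, `remote_share`, `essential`.
#' @return Named numeric vector `c(remote_share, essential_share)`; `NA`s
#'   when total employment is zero.
#' @export
worker_shares <- function(employees, sector_meta) {
  sector_meta <- data.table::as.data.table(sector_meta)
  idx <- match(names(employees), sector_meta$sector)
  if (anyNA(idx)) stop("unknown sectors: ",
                       paste(names(employees)[is.na(idx)], collapse = ", "))
  tot <- sum(employees)
  if (!is.finite(tot) || tot <= 0) {
    return(c(remote_share = NA_real_, essential_share = NA_real_))
  }
  c(remote_share = sum(employees * sector_meta$remote_share[idx]) / tot,
    essential_share = sum(employees[sector_meta$essential[idx]]) / tot)
}

#' Redistribute province-by-sector quantities to territories
#'
#' Bridges province-level tables to the territorial (LLM) level: within each
#' province and sector, the municipal share of province employees is the
#' partition coefficient; province quantities are split to municipalities
#' proportionally and then summed into the territory each municipality
#' belongs to. Conservation is exact: per province and sector, the
#' redistributed employees and revenues sum back to the province totals
#' (provinces with zero employees in a sector leave nothing to distribute;
#' a nonzero revenue in such a cell is reported with a warning).
#'
#' @param province_sector data.table with `province_id`, `sector`,
#'   `employees`, `revenues`.
#' @param municipal data.table with `municipality_id`, `llm_id`,
#'   `province_id` and per-sector municipal employee columns `emp_<sector>`.
#' @return data.table with `llm_id`, `sector`, `employees`, `revenues`.
#' @export
province_to_llm <- function(province_sector, municipal) {
  ps <- data.table::as.data.table(province_sector)
  mu <- data.table::as.data.table(municipal)
  sectors <- sort(unique(ps$sector))
  emp_cols <- paste0("emp_", sectors)
  missing_cols <- setdiff(emp_cols, names(mu))
  if (length(missing_cols)) {
    stop("municipal table lacks employee columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- mu[is.na(mu$province_id) | is.na(mu$llm_id)]
  if (nrow(bad)) {
    stop("municipalities with unknown province/LLM: ",
         paste(bad$municipality_id, collapse = ", "))
  }
  long <- data.table::melt(
    mu[, c("municipality_id", "llm_id", "province_id", emp_cols), with = FALSE],
    id.vars = c("municipality_id", "llm_id", "province_id"),
    variable.name = "sector", value.name = "m_emp",
    variable.factor = FALSE)
  long[, sector := sub("^emp_", "", sector)]
  long <- merge(long, ps, by = c("province_id", "sector"), all.x = TRUE)
  long[, p_emp := sum(m_emp), by = c("province_id", "sector")]
  zero_rev <- long[p_emp == 0 & revenues > 0]
  if (nrow(zero_rev)) {
    warning("province/sector cells with revenue but no employees: ",
            "revenue left undistributed for ",
            length(unique(paste(zero_rev$province_id, zero_rev$sector))),
            " cells")
  }
  long[, share := ifelse(p_emp > 0, m_emp / p_emp, 0)]
  out <- long[, list(employees = sum(share * employees),
                     revenues = sum(share * revenues)),
              by = c("llm_id", "sector")]
  data.table::setorder(out, llm_id, sector)
  out[]
}

#' Assemble the per-territory socioeconomic feature table
#'
#' Builds the 38 numeric features per territory from the municipal,
#' province-by-sector and sector metadata tables: income per capita,
#' mean/median income inequality, population density (3 socioeconomic);
#' remote-work and essential-sector employment shares (2 intervention);
#' per-sector employees and revenues per employee (2 x 16 sectoral); and the
#' Herfindahl-Hirschman revenue concentration (1). The macroarea is carried
#' as a categorical column. Territories covered by the labels table but
#' absent from a component table are dropped (the intersection is used).
#'
#' Income per capita uses the pooled municipal ratio; the territory median
#' income is the declarant-weighted mean of municipal medians, so inequality
#' is pooled mean over pooled median. A sector with zero redistributed
#' employees gets revenue-per-employee 0 and is recorded in the
#' `zero_employee_cells` attribute.
#'
#' @param scenario a `mobility_scenario`, or a list with `municipal`,
#'   `province_sector`, `sector_meta`, `labels` tables in the synthetic
#'   dialect.
#' @return An object of class `feature_table`: data.table with `llm_id`,
#'   `macroarea` and 38 numeric feature columns; the feature column names are
#'   in the `feature_cols` attribute.
#' @export
assemble_features <- function(scenario) {
  mu <- data.table::as.data.table(scenario$municipal)
  ps <- data.table::as.data.table(scenario$province_sector)
  sm <- data.table::as.data.table(scenario$sector_meta)
  lb <- data.table::as.data.table(scenario$labels)
  sectors <- sort(unique(sm$sector))

  base <- mu[, list(
    income_per_capita = income_per_capita(income_total, declarants),
    income_median_w = sum(declarants * income_median) / sum(declarants),
    population = sum(population),
    area_km2 = sum(area_km2)), by = "llm_id"]
  base[, inequality := income_per_capita / income_median_w]
  base[, density := population / area_km2]

  red <- province_to_llm(ps, mu)
  red[, rpe := ifelse(employees > 0, revenues / employees, 0)]
  zero_cells <- red[employees <= 0, c("llm_id", "sector"), with = FALSE]
  emp_w <- data.table::dcast(red, llm_id ~ sector, value.var = "employees")
  data.table::setnames(emp_w, sectors, paste0("emp_", sectors))
  rpe_w <- data.table::dcast(red, llm_id ~ sector, value.var = "rpe")
  data.table::setnames(rpe_w, sectors, paste0("rpe_", sectors))
  hhi <- red[, list(revenue_concentration = revenue_concentration(revenues)),
             by = "llm_id"]
  shares <- red[, {
    e <- employees
    names(e) <- sector
    as.list(worker_shares(e, sm))
  }, by = "llm_id"]

  ft <- Reduce(function(a, b) merge(a, b, by = "llm_id"),
               list(base[, c("llm_id", "income_per_capita", "inequality",
                             "density"), with = FALSE],
                    hhi, shares, emp_w, rpe_w))
  ft <- merge(lb[, c("llm_id", "macroarea"), with = FALSE], ft, by = "llm_id")
  dropped <- setdiff(lb$llm_id, ft$llm_id)
  if (length(dropped)) {
    mf_log("assemble_features: %d territories dropped (incomplete coverage)",
           length(dropped))
  }
  feature_cols <- c("income_per_capita", "inequality", "density",
                    "revenue_concentration", "essential_share", "remote_share",
                    paste0("emp_", sectors), paste0("rpe_", sectors))
  data.table::setcolorder(ft, c("llm_id", "macroarea", feature_cols))
  data.table::setattr(ft, "feature_cols", feature_cols)
  data.table::setattr(ft, "sectors", sectors)
  data.table::setattr(ft, "zero_employee_cells", zero_cells)
  data.table::setattr(ft, "class", c("feature_table", class(ft)))
  ft[]
}

#' Standardize a feature table
#'
#' Centers and scales every feature column to mean 0, SD 1; the fitted
#' centers and scales are stored so downstream modules (clustering,
#' classification, regression) all see identical scales and the transform
#' can be inverted.
#'
#' @param features a `feature_table` from [assemble_features()].
#' @return list with `std` (standardized copy of the table), `center`,
#'   `scale` (named vectors), and `feature_cols`.
#' @export
standardize_features <- function(features) {
  cols <- attr(features, "feature_cols")
  stopifnot(!is.null(cols))
  X <- as.matrix(features[, cols, with = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr, `-`), 2, scl, `/`)
  std <- data.table::copy(features)
  for (j in seq_along(cols)) data.table::set(std, j = cols[j],
                                             value = Xs[, j])
  list(std = std, center = ctr, scale = scl, feature_cols = cols)
}
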