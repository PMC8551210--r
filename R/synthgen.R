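#' Configure a synthetic mobility-and-economy scenario
#'
#' Describes a study system of territorial units (local labour markets, LLMs)
#' laid out on an abstract planar grid, with a baseline gravity-model mobility
#' network, class-specific recovery curves that rescale flows window by window,
#' and municipal/province socioeconomic tables whose class structure is
#' controlled by explicit effect sizes.
#'
#' Defaults describe the study conditions the pipeline is designed around:
#' 200 LLMs observed over sixteen 14-day windows starting 2020-02-24, flows
#' recorded on an 8-hour grid (42 bins per window), a privacy floor of 10
#' travellers, 16 economic sectors, and three latent territory classes
#' ("most", "least", "rest" affected) with a V-shaped recovery for the least
#' affected class and a U-shaped one for the most affected class, separated by
#' 0.4 in the flow multiplier during the two lockdown windows.
#'
#' @param n_llms number of territorial units (network nodes).
#' @param municipalities_per_llm integer range (min, max) of municipalities
#'   composing each LLM.
#' @param n_provinces number of provinces (spatially contiguous LLM blocks).
#' @param n_sectors number of economic sectors.
#' @param n_windows number of consecutive 14-day observation windows.
#' @param window_length_days length of one window in days.
#' @param start_date first day of window 0.
#' @param bins_per_window number of equal sub-window time bins each window's
#'   flow is split into (42 bins of 8 hours for a 14-day window).
#' @param class_fractions named proportions (most, least, rest); must sum to 1.
#' @param recovery_shapes 3 x n_windows matrix of per-class flow multipliers
#'   (rows "most", "least", "rest"), each with value 1 in the baseline window.
#'   Defaults to [default_recovery_shapes()].
#' @param gravity_exponent exponent of distance in the gravity rule.
#' @param baseline_flow_scale multiplicative scale of baseline flows.
#' @param privacy_floor window-level flows below this count are dropped,
#'   mirroring privacy-preserving suppression of small flows; set 0 to disable.
#' @param covariate_effects named vector of mean shifts, in within-class
#'   standard-deviation units, between the "least" and "most" classes
#'   (least minus most) for socioeconomic covariates. Recognized names:
#'   `income_per_capita`, `inequality`, `density` (log scale).
#' @param noise_sd standard deviation of the multiplicative lognormal noise
#'   applied to window flows (0 gives deterministic flows).
#' @param tiles_per_llm integer range of abstract map tiles owned by each LLM.
#' @param seed integer seed; the whole scenario is deterministic given it.
#'
#' @return An object of class `scenario_config`.
#' @seealso [generate_scenario()], [default_recovery_shapes()]
#' @export
scenario_config <- function(n_llms = 200L,
                            municipalities_per_llm = c(2L, 5L),
                            n_provinces = 20L,
                            n_sectors = 16L,
                            n_windows = 16L,
                            window_length_days = 14L,
                            start_date = as.Date("2020-02-24"),
                            bins_per_window = 42L,
                            class_fractions = c(most = 0.3, least = 0.3, rest = 0.4),
                            recovery_shapes = NULL,
                            gravity_exponent = 2,
                            baseline_flow_scale = 5,
                            privacy_floor = 10,
                            covariate_effects = c(income_per_capita = 1.5,
                                                  inequality = -1.0),
                            noise_sd = 0.05,
                            tiles_per_llm = c(1L, 3L),
                            seed = 1L) {
  if (is.null(recovery_shapes)) {
    recovery_shapes <- default_recovery_shapes(n_windows)
  }
  cfg <- structure(
    list(n_llms = as.integer(n_llms),
         municipalities_per_llm = as.integer(municipalities_per_llm),
         n_provinces = as.integer(n_provinces),
         n_sectors = as.integer(n_sectors),
         n_windows = as.integer(n_windows),
         window_length_days = as.integer(window_length_days),
         start_date = as.Date(start_date),
         bins_per_window = as.integer(bins_per_window),
         class_fractions = class_fractions,
         recovery_shapes = recovery_shapes,
         gravity_exponent = gravity_exponent,
         baseline_flow_scale = baseline_flow_scale,
         privacy_floor = privacy_floor,
         covariate_effects = covariate_effects,
         noise_sd = noise_sd,
         tiles_per_llm = as.integer(tiles_per_llm),
         seed = as.integer(seed)),
    class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  f <- cfg$class_fractions
  if (!all(c("most", "least", "rest") %in% names(f))) {
    stop_config("class_fractions must be named most/least/rest")
  }
  if (abs(sum(f) - 1) > 1e-8 || any(f < 0)) {
    stop_config("class_fractions must be nonnegative and sum to 1 (got sum %g)", sum(f))
  }
  if (cfg$n_llms < 2) stop_config("n_llms must be >= 2")
  if (cfg$gravity_exponent <= 0) stop_config("gravity_exponent must be positive")
  if (cfg$baseline_flow_scale <= 0) stop_config("baseline_flow_scale must be positive")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be nonnegative")
  if (cfg$privacy_floor < 0) stop_config("privacy_floor must be nonnegative")
  rs <- cfg$recovery_shapes
  if (!is.matrix(rs) || nrow(rs) != 3 ||
      !all(c("most", "least", "rest") %in% rownames(rs))) {
    stop_config("recovery_shapes must be a 3 x n_windows matrix with rows most/least/rest")
  }
  if (ncol(rs) != cfg$n_windows) {
    stop_config("recovery_shapes has %d columns but n_windows is %d",
                ncol(rs), cfg$n_windows)
  }
  if (any(abs(rs[, 1] - 1) > 1e-12)) {
    stop_config("recovery_shapes must equal 1 in the baseline window (column 1)")
  }
  if (any(rs < 0) || any(rs > 1 + 1e-12)) {
    stop_config("recovery multipliers must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Default V/U-shaped per-class recovery multiplier curves
#'
#' The least affected class dips to 0.85 of baseline flow during the two
#' lockdown windows and rebounds to baseline within three further windows
#' (V shape); the most affected class drops to 0.45 and climbs back slowly,
#' still 10% below baseline at the end of a 16-window study (U shape); the
#' remaining territories follow the midpoint of the two curves. The 0.40
#' multiplier gap in the lockdown windows is the class separation the
#' downstream indicator analysis is designed to detect.
#'
#' @param n_windows number of 14-day windows.
#' @return 3 x n_windows matrix with rows `most`, `least`, `rest`.
#' @export
default_recovery_shapes <- function(n_windows = 16L) {
  w <- seq_len(n_windows) - 1L
  least <- ifelse(w == 0, 1, pmin(1, 0.85 + 0.05 * pmax(0, w - 2)))
  most <- ifelse(w == 0, 1, pmin(0.90, 0.45 + 0.045 * pmax(0, w - 2)))
  rest <- (least + most) / 2
  rest[1] <- 1
  rbind(most = most, least = least, rest = rest)
}

#' Generate a synthetic scenario
#'
#' Draws the whole synthetic study system deterministically from the seed in
#' `config`: LLM geography and latent territory classes, the municipal and
#' province-by-sector socioeconomic tables, per-sector remote-work shares and
#' essential flags, and the origin-destination mobility records over all
#' windows. Baseline flows follow a gravity rule
#' `flow_ij = scale * pop_i * pop_j / dist_ij^gamma` (rounded to integers);
#' the flow of window w leaving a territory of class c is the baseline flow
#' times the class multiplier `m_c(w)` times multiplicative lognormal noise,
#' floored at the privacy threshold and split evenly over the sub-window bins.
#'
#' Class structure of the covariates: the configured effect sizes are realized
#' exactly as mean shifts (in within-class SD units) between the least and the
#' most affected class. Classes are assigned along the south-north axis of the
#' grid and a latent development factor, proportional to the configured income
#' shift, also loads on population density, the sectoral employment mix (hence
#' the remote-work share) and province-level productivity, emulating the
#' strong covariance between income and economic structure that real
#' territorial data exhibit. In a null scenario (all effects 0) the latent
#' factor carries no class signal.
#'
#' @param config a [scenario_config()].
#' @param components character subset of `c("mobility", "socioeconomic")`;
#'   generating only the socioeconomic tables skips the (much larger)
#'   origin-destination record set.
#' @return An object of class `mobility_scenario`: a list with elements
#'   `config`, `od_records`, `tile_map`, `municipal`, `province_sector`,
#'   `sector_meta`, `labels`, and `llm_attributes`.
#' @export
generate_scenario <- function(config,
                              components = c("mobility", "socioeconomic")) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  components <- match.arg(components, several.ok = TRUE)
  set.seed(config$seed)
  n <- config$n_llms
  S <- config$n_sectors
  sectors <- sprintf("S%02d", seq_len(S))

  ## geography and latent classes ------------------------------------------
  llm_id <- sprintf("L%03d", seq_len(n))
  x <- runif(n, 0, 100)
  y <- runif(n, 0, 100)
  pop <- rlnorm(n, meanlog = log(30), sdlog = 0.5) # thousands of residents

  # south (low y) -> more affected; the spatial clustering of the affectedness
  # classes is part of the socioeconomic gradient, so its strength scales with
  # the configured class signal: a null configuration assigns classes at
  # random, removing any alignment between classes and province blocks
  eff0 <- function(nm) {
    v <- config$covariate_effects
    if (!is.null(names(v)) && nm %in% names(v)) unname(v[[nm]]) else 0
  }
  w_sp <- pmin(1, abs(eff0("income_per_capita")) / 1.5)
  score <- w_sp * (-as.numeric(scale(y))) + (1.05 - w_sp) * rnorm(n)
  fr <- config$class_fractions
  n_most <- round(fr[["most"]] * n)
  n_least <- round(fr[["least"]] * n)
  ord <- order(score, decreasing = TRUE)
  true_class <- rep("rest", n)
  true_class[ord[seq_len(n_most)]] <- "most"
  true_class[ord[n - seq_len(n_least) + 1L]] <- "least"

  # five contiguous macroarea strips south -> north
  area_levels <- c("islands", "south", "center", "north_east", "north_west")
  strip <- cut(rank(y, ties.method = "first"), breaks = 5, labels = FALSE)
  macroarea <- area_levels[strip]

  # latent development factor: class separation proportional to the
  # configured income shift (exactly zero under a null configuration)
  eff <- function(nm) {
    v <- config$covariate_effects
    if (!is.null(names(v)) && nm %in% names(v)) unname(v[[nm]]) else 0
  }
  delta_g <- eff("income_per_capita") / 1.5
  ccode <- c(most = -0.5, rest = 0, least = 0.5)[true_class]
  g <- ccode * 2 * (delta_g / 2) + rnorm(n) # within-class SD 1

  # feature z-scores: latent loading a plus direct class remainder so the
  # realized least-minus-most shift equals the configured effect exactly
  # features with a configured effect get a direct class term pinning the
  # realized shift to the configured value exactly; unconfigured features
  # inherit the latent shift a * delta_g as emergent structure
  named_eff <- function(nm) !is.null(names(config$covariate_effects)) &&
    nm %in% names(config$covariate_effects)
  mk_z <- function(a, nm) {
    direct <- if (named_eff(nm)) eff(nm) - a * delta_g else 0
    a * g + ccode * direct + sqrt(max(0, 1 - a^2)) * rnorm(n)
  }
  income_z <- mk_z(0.5, "income_per_capita")
  ineq_z <- mk_z(-0.5, "inequality")
  dens_z <- mk_z(0.7, "density")

  income_pc <- 20000 + 3000 * income_z        # EUR per declarant
  ineq_ratio <- 1.30 + 0.15 * ineq_z          # mean/median income ratio
  density <- exp(log(150) + 0.8 * dens_z)     # persons per km^2
  area_km2 <- pop * 1000 / density

  ## sectors ----------------------------------------------------------------
  remote_share <- rbeta(S, 2, 3)
  essential <- seq_len(S) %in% sample.int(S, max(1L, round(0.3 * S)))
  sector_w <- rgamma(S, shape = 2)
  sector_w <- sector_w / sum(sector_w)
  t_s <- as.numeric(scale(remote_share))

  sector_meta <- data.table::data.table(sector = sectors,
                                        remote_share = remote_share,
                                        essential = essential)

  ## provinces: contiguous spatial blocks of LLMs ---------------------------
  n_prov <- min(config$n_provinces, n)
  prov_rank <- rank(y * 10 + x / 100, ties.method = "first")
  prov_idx_llm <- ceiling(prov_rank / (n / n_prov))

  ## municipalities ---------------------------------------------------------
  mr <- config$municipalities_per_llm
  n_mun_i <- sample(seq(mr[1], mr[2]), n, replace = TRUE)
  mun_llm_idx <- rep(seq_len(n), n_mun_i)
  n_mun <- length(mun_llm_idx)
  municipality_id <- sprintf("M%05d", seq_len(n_mun))

  # labour-market areas straddle administrative province boundaries, so a
  # municipality may belong to a neighbouring province of its LLM's block;
  # this keeps the province-to-LLM bridge a genuine many-to-many mapping
  prov_shift <- sample(c(-1L, 0L, 1L), n_mun, replace = TRUE,
                       prob = c(0.2, 0.6, 0.2))
  province_of_mun <- sprintf("P%02d", pmin(pmax(prov_idx_llm[mun_llm_idx] +
                                                  prov_shift, 1L), n_prov))

  w_pop <- rgamma(n_mun, shape = 2)
  w_area <- rgamma(n_mun, shape = 2)
  split_by <- function(w, idx) w / rep(tapply(w, idx, sum)[as.character(seq_len(n))],
                                       n_mun_i)
  pop_m <- pmax(200L, as.integer(round(pop[mun_llm_idx] * 1000 *
                                         split_by(w_pop, mun_llm_idx))))
  area_m <- area_km2[mun_llm_idx] * split_by(w_area, mun_llm_idx)
  declarants_m <- pmax(50L, as.integer(round(0.6 * pop_m * runif(n_mun, 0.9, 1.1))))

  # municipal mean incomes vary around the LLM target with declarant-weighted
  # mean exactly equal to the target, so the pooled LLM income per capita has
  # within-class SD equal to the configured structural scale
  dev <- rnorm(n_mun, 0, 1500)
  wmean_dev <- tapply(dev * declarants_m, mun_llm_idx, sum) /
    tapply(declarants_m, mun_llm_idx, sum)
  y_m <- pmax(2000, income_pc[mun_llm_idx] + dev -
                as.numeric(wmean_dev)[mun_llm_idx])
  income_total_m <- round(declarants_m * y_m)
  income_mean_m <- income_total_m / declarants_m
  income_median_m <- income_mean_m / ineq_ratio[mun_llm_idx]

  # municipal employment by sector: LLM-level sector mix tilted by the latent
  # development factor towards remote-intensive sectors
  mix <- outer(g, t_s, function(gi, ts) exp(1.0 * gi * ts)) *
    matrix(sector_w, n, S, byrow = TRUE)
  mix <- mix / rowSums(mix)
  emp_m <- matrix(0L, n_mun, S)
  base_emp <- 0.4 * pop_m
  noise_emp <- matrix(rlnorm(n_mun * S, -0.15^2 / 2, 0.15), n_mun, S)
  emp_m <- matrix(as.integer(round(base_emp * mix[mun_llm_idx, , drop = FALSE] *
                                     noise_emp)), n_mun, S)
  colnames(emp_m) <- paste0("emp_", sectors)

  municipal <- data.table::data.table(
    municipality_id = municipality_id,
    llm_id = llm_id[mun_llm_idx],
    province_id = province_of_mun,
    population = pop_m,
    area_km2 = area_m,
    declarants = declarants_m,
    income_total = income_total_m,
    income_mean = income_mean_m,
    income_median = income_median_m)
  municipal <- cbind(municipal, data.table::as.data.table(emp_m))

  ## province x sector table (employees conserved exactly by construction) --
  prov_emp <- rowsum(emp_m, municipal$province_id)
  prov_ids <- rownames(prov_emp)
  g_p <- tapply(g[mun_llm_idx], municipal$province_id, mean)[prov_ids]
  rpe_base <- rlnorm(S, log(60), 0.3) # thousand EUR per employee
  rpe <- outer(as.numeric(g_p), rpe_base, function(gp, rb) rb * exp(0.5 * gp)) *
    matrix(rlnorm(length(prov_ids) * S, -0.15^2 / 2, 0.15),
           length(prov_ids), S)
  province_sector <- data.table::data.table(
    province_id = rep(prov_ids, each = S),
    sector = rep(sectors, times = length(prov_ids)),
    employees = as.integer(t(prov_emp)),
    revenues = as.numeric(t(prov_emp * rpe)))

  labels <- data.table::data.table(llm_id = llm_id,
                                   true_class = true_class,
                                   macroarea = macroarea)
  llm_attributes <- data.table::data.table(llm_id = llm_id, x = x, y = y,
                                           population = pop * 1000,
                                           latent = g)

  ## mobility ---------------------------------------------------------------
  od_records <- NULL
  tile_map <- NULL
  if ("mobility" %in% components) {
    tr <- config$tiles_per_llm
    n_tiles_i <- sample(seq(tr[1], tr[2]), n, replace = TRUE)
    tile_llm_idx <- rep(seq_len(n), n_tiles_i)
    tile_id <- sprintf("T%05d", seq_along(tile_llm_idx))
    tile_map <- data.table::data.table(tile_id = tile_id,
                                       llm_id = llm_id[tile_llm_idx])

    dmat <- as.matrix(stats::dist(cbind(x, y)))
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    B <- round(config$baseline_flow_scale * pop[pr[, 1]] * pop[pr[, 2]] /
                 pmax(dmat[pr], 1e-6)^config$gravity_exponent)
    keep <- B >= 1
    ei <- pr[keep, 1]; ej <- pr[keep, 2]; B <- B[keep]
    # directed edges, multiplier of the origin node's class
    oi <- c(ei, ej); di <- c(ej, ei); Bd <- c(B, B)
    ne <- length(oi)
    # fixed tile endpoints per directed edge
    pick_tile <- function(idx) {
      first <- match(seq_len(n), tile_llm_idx)
      off <- floor(runif(length(idx)) * n_tiles_i[idx])
      tile_id[first[idx] + as.integer(off)]
    }
    o_tile <- pick_tile(oi)
    d_tile <- pick_tile(di)

    W <- config$n_windows
    m_class <- config$recovery_shapes[true_class[oi], , drop = FALSE] # ne x W
    flow <- matrix(rep(Bd, W), ne, W) * m_class
    if (config$noise_sd > 0) {
      flow <- flow * matrix(rlnorm(ne * W, -config$noise_sd^2 / 2,
                                   config$noise_sd), ne, W)
    }
    flow <- round(flow)
    flow[flow < max(1, config$privacy_floor)] <- 0

    ew <- data.table::data.table(
      origin_tile = rep(o_tile, W),
      destination_tile = rep(d_tile, W),
      window = rep(seq_len(W) - 1L, each = ne),
      total = as.integer(flow))
    ew <- ew[ew$total > 0L]

    nb <- config$bins_per_window
    base <- ew$total %/% nb
    rem <- ew$total %% nb
    nrec <- nrow(ew)
    # rows with total >= nb contribute all bins; smaller totals only `total`
    bins_per_row <- pmin(ew$total, nb)
    ridx <- rep(seq_len(nrec), bins_per_row)
    bin <- sequence(bins_per_row) - 1L
    cnt <- base[ridx] + (bin < rem[ridx])
    # when total < nb the first `total` bins get 1 traveller each
    small <- ew$total[ridx] < nb
    cnt[small] <- 1L
    sec_per_bin <- config$window_length_days * 86400 / nb
    t0 <- as.POSIXct(paste0(format(config$start_date), " 00:00:00"), tz = "UTC")
    od_records <- data.table::data.table(
      origin_tile = ew$origin_tile[ridx],
      destination_tile = ew$destination_tile[ridx],
      datetime_bin = t0 + (as.numeric(ew$window[ridx]) * nb + bin) * sec_per_bin,
      n_travelers = as.integer(cnt))
    data.table::setorder(od_records, datetime_bin, origin_tile, destination_tile)
  }

  structure(list(config = config,
                 od_records = od_records,
                 tile_map = tile_map,
                 municipal = municipal,
                 province_sector = province_sector,
                 sector_meta = sector_meta,
                 labels = labels,
                 llm_attributes = llm_attributes),
            class = "mobility_scenario")
}

#' @export
print.mobility_scenario <- function(x, ...) {
  cat("<mobility_scenario>\n")
  cat(sprintf("  LLMs: %d | municipalities: %d | sectors: %d | windows: %d\n",
              x$config$n_llms, nrow(x$municipal), x$config$n_sectors,
              x$config$n_windows))
  if (!is.null(x$od_records)) {
    cat(sprintf("  OD records: %d (%d tiles)\n", nrow(x$od_records),
                nrow(x$tile_map)))
  } else {
    cat("  OD records: not generated (socioeconomic components only)\n")
  }
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$labels$true_class)),
                            table(x$labels$true_class)), collapse = " ")))
  invisible(x)
}

#' Write a scenario to disk as plain CSV/JSON tables
#'
#' Emits `od_records.csv`, `tile_map.csv`, `municipal.csv`,
#' `province_sector.csv`, `sector_meta.csv`, `labels.csv` and a `scenario.json`
#' configuration echo. Reading the directory back with [read_scenario()]
#' reproduces the tables.
#'
#' @param scenario a `mobility_scenario`.
#' @param directory output directory (created if missing).
#' @return Invisibly, a named character vector mapping table names to the
#'   files written (the manifest).
#' @export
write_scenario <- function(scenario, directory) {
  stopifnot(inherits(scenario, "mobility_scenario"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  manifest <- c()
  wr <- function(dt, name) {
    path <- file.path(directory, paste0(name, ".csv"))
    if (is.null(dt)) {
      dt <- data.table::data.table()
    }
    data.table::fwrite(dt, path, dateTimeAs = "ISO")
    manifest[[name]] <<- path
  }
  od <- scenario$od_records
  if (is.null(od)) {
    od <- data.table::data.table(origin_tile = character(),
                                 destination_tile = character(),
                                 datetime_bin = as.POSIXct(character(), tz = "UTC"),
                                 n_travelers = integer())
  }
  wr(od, "od_records")
  tm <- scenario$tile_map
  if (is.null(tm)) tm <- data.table::data.table(tile_id = character(),
                                                llm_id = character())
  wr(tm, "tile_map")
  wr(scenario$municipal, "municipal")
  wr(scenario$province_sector, "province_sector")
  wr(scenario$sector_meta, "sector_meta")
  wr(scenario$labels, "labels")
  cfg <- scenario$config
  cfg_json <- unclass(cfg)
  cfg_json$start_date <- format(cfg$start_date)
  # named atomic vectors must become lists to keep their names in JSON
  cfg_json$class_fractions <- as.list(cfg$class_fractions)
  cfg_json$covariate_effects <- as.list(cfg$covariate_effects)
  cfg_json$recovery_shapes <- as.data.frame(t(cfg$recovery_shapes))
  path_json <- file.path(directory, "scenario.json")
  jsonlite::write_json(cfg_json, path_json, auto_unbox = TRUE, digits = NA)
  manifest[["scenario"]] <- path_json
  invisible(unlist(manifest))
}

#' Read a scenario directory written by [write_scenario()]
#'
#' @param directory path written by [write_scenario()].
#' @return A `mobility_scenario` (without the internal `llm_attributes`
#'   table, which is not part of the on-disk interface).
#' @export
read_scenario <- function(directory) {
  rd <- function(name, ...) {
    path <- file.path(directory, paste0(name, ".csv"))
    if (!file.exists(path)) return(NULL)
    data.table::fread(path, ...)
  }
  od <- rd("od_records")
  if (!is.null(od) && nrow(od) > 0) {
    od[, datetime_bin := as.POSIXct(datetime_bin, tz = "UTC")]
    od[, n_travelers := as.integer(n_travelers)]
  }
  cfg_raw <- jsonlite::read_json(file.path(directory, "scenario.json"),
                                 simplifyVector = TRUE)
  rs <- unname(t(as.matrix(cfg_raw$recovery_shapes)))
  rownames(rs) <- names(cfg_raw$recovery_shapes)
  cfg <- scenario_config(
    n_llms = cfg_raw$n_llms,
    municipalities_per_llm = cfg_raw$municipalities_per_llm,
    n_provinces = cfg_raw$n_provinces,
    n_sectors = cfg_raw$n_sectors,
    n_windows = cfg_raw$n_windows,
    window_length_days = cfg_raw$window_length_days,
    start_date = as.Date(cfg_raw$start_date),
    bins_per_window = cfg_raw$bins_per_window,
    class_fractions = unlist(cfg_raw$class_fractions),
    recovery_shapes = rs,
    gravity_exponent = cfg_raw$gravity_exponent,
    baseline_flow_scale = cfg_raw$baseline_flow_scale,
    privacy_floor = cfg_raw$privacy_floor,
    covariate_effects = unlist(cfg_raw$covariate_effects),
    noise_sd = cfg_raw$noise_sd,
    tiles_per_llm = cfg_raw$tiles_per_llm,
    seed = cfg_raw$seed)
  structure(list(config = cfg,
                 od_records = od,
                 tile_map = rd("tile_map"),
                 municipal = rd("municipal"),
                 province_sector = rd("province_sector"),
                 sector_meta = rd("sector_meta"),
                 labels = rd("labels"),
                 llm_attributes = NULL),
            class = "mobility_scenario")
}

#' Simulate an indicator from a known linear model on standardized features
#'
#' Convenience generator for parameter-recovery studies: draws a response
#' `y = X_std beta + noise` from a standardized feature table, with all
#' unnamed coefficients equal to zero.
#'
#' @param features_std standardized feature table (see
#'   [standardize_features()]): a data.table with `llm_id` plus numeric
#'   feature columns.
#' @param coefficients named numeric vector of true coefficients (names must
#'   be feature columns).
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return data.table with `llm_id` and `indicator`.
#' @export
simulate_linear_indicator <- function(features_std, coefficients,
                                      noise_sd = 0.5, seed = 1L) {
  stopifnot(all(names(coefficients) %in% names(features_std)))
  set.seed(seed)
  X <- as.matrix(features_std[, names(coefficients), with = FALSE])
  y <- as.numeric(X %*% coefficients) + rnorm(nrow(X), 0, noise_sd)
  data.table::data.table(llm_id = features_std$llm_id, indicator = y)
}
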