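test_that("configuration invariants are enforced", {
  expect_error(scenario_config(class_fractions = c(most = 0.5, least = 0.5, rest = 0.2)),
               "sum to 1")
  expect_error(scenario_config(baseline_flow_scale = -1), "positive")
  expect_error(scenario_config(noise_sd = -0.1), "nonnegative")
  rs <- default_recovery_shapes(8)
  rs["most", 1] <- 0.9
  expect_error(scenario_config(n_windows = 8, recovery_shapes = rs),
               "baseline window")
  expect_error(scenario_config(n_windows = 4,
                               recovery_shapes = default_recovery_shapes(6)),
               "n_windows")
})

test_that("identical seeds reproduce the scenario, different seeds do not", {
  s1 <- generate_scenario(tiny_config(seed = 11))
  s2 <- generate_scenario(tiny_config(seed = 11))
  s3 <- generate_scenario(tiny_config(seed = 12))
  expect_identical(s1$od_records, s2$od_records)
  expect_identical(s1$municipal, s2$municipal)
  expect_identical(s1$labels, s2$labels)
  expect_false(isTRUE(all.equal(s1$od_records, s3$od_records)))
})

test_that("class multipliers scale each territory's outflow exactly when noise is off", {
  rs <- rbind(most = c(1, 0.8, 0.6), least = c(1, 1, 1), rest = c(1, 0.9, 0.8))
  cfg <- scenario_config(n_llms = 25L, n_provinces = 5L, n_windows = 3L,
                         bins_per_window = 6L, recovery_shapes = rs,
                         noise_sd = 0, privacy_floor = 0, seed = 3)
  sc <- generate_scenario(cfg)
  od <- merge(sc$od_records, sc$tile_map,
              by.x = "origin_tile", by.y = "tile_id")
  grid <- window_grid(cfg$start_date, cfg$n_windows, cfg$window_length_days)
  od <- assign_windows(od, grid)
  lab <- stats::setNames(sc$labels$true_class, sc$labels$llm_id)

  outflow <- od[, list(out = sum(n_travelers)), by = c("llm_id", "window")]
  wide <- data.table::dcast(outflow, llm_id ~ window, value.var = "out", fill = 0)
  least_ids <- names(lab)[lab == "least"]
  least_ids <- intersect(least_ids, wide$llm_id)
  expect_true(length(least_ids) > 0)
  expect_equal(wide[wide$llm_id %in% least_ids][["2"]],
               wide[wide$llm_id %in% least_ids][["0"]])

  # per-edge: window-2 flow of a most-class origin is round(0.6 * baseline)
  edge <- od[, list(f = sum(n_travelers)),
             by = c("origin_tile", "destination_tile", "window", "llm_id")]
  ew <- data.table::dcast(edge, origin_tile + destination_tile + llm_id ~ window,
                          value.var = "f", fill = 0)
  most_edges <- ew[lab[ew$llm_id] == "most"]
  expect_true(nrow(most_edges) > 0)
  expect_equal(most_edges[["2"]], round(0.6 * most_edges[["0"]]))
})

test_that("configured covariate shifts are realized in every generated scenario", {
  for (seed in 1:3) {
    sc <- generate_scenario(scenario_config(n_llms = 120, seed = seed),
                            components = "socioeconomic")
    ft <- assemble_features(sc)
    m <- merge(ft, sc$labels, by = "llm_id")
    inc_least <- mean(m$income_per_capita[m$true_class == "least"])
    inc_most <- mean(m$income_per_capita[m$true_class == "most"])
    expect_gt(inc_least, inc_most)
    ineq_least <- mean(m$inequality[m$true_class == "least"])
    ineq_most <- mean(m$inequality[m$true_class == "most"])
    expect_lt(ineq_least, ineq_most)
  }
})

test_that("mean covariate shifts match the configured effect sizes across seeds", {
  diffs <- vapply(1:50, function(s) {
    sc <- generate_scenario(scenario_config(n_llms = 120, seed = s),
                            components = "socioeconomic")
    ft <- merge(assemble_features(sc), sc$labels, by = "llm_id")
    a <- ft[ft$true_class == "least"]
    b <- ft[ft$true_class == "most"]
    sd_pool <- function(col) sqrt(mean(c(stats::var(a[[col]]), stats::var(b[[col]]))))
    c((mean(a$income_per_capita) - mean(b$income_per_capita)) /
        sd_pool("income_per_capita"),
      (mean(a$inequality) - mean(b$inequality)) / sd_pool("inequality"))
  }, numeric(2))
  mc_se <- apply(diffs, 1, stats::sd) / sqrt(ncol(diffs))
  expect_lt(abs(mean(diffs[1, ]) - 1.5), 2 * mc_se[1])
  expect_lt(abs(mean(diffs[2, ]) - (-1.0)), 2 * mc_se[2])
})

test_that("province employee totals equal the sum over member municipalities", {
  sc <- generate_scenario(tiny_config(seed = 5))
  sectors <- sc$sector_meta$sector
  mu_long <- data.table::melt(
    sc$municipal[, c("province_id", paste0("emp_", sectors)), with = FALSE],
    id.vars = "province_id", variable.name = "sector", value.name = "emp",
    variable.factor = FALSE)
  mu_long[, sector := sub("^emp_", "", sector)]
  sums <- mu_long[, list(emp = sum(emp)), by = c("province_id", "sector")]
  chk <- merge(sums, sc$province_sector, by = c("province_id", "sector"))
  expect_identical(as.integer(chk$emp), as.integer(chk$employees))
})

test_that("no noise and flat multipliers reproduce the baseline network in every window", {
  rs <- matrix(1, 3, 4, dimnames = list(c("most", "least", "rest"), NULL))
  cfg <- scenario_config(n_llms = 20L, n_provinces = 4L, n_windows = 4L,
                         bins_per_window = 6L, recovery_shapes = rs,
                         noise_sd = 0, privacy_floor = 0, seed = 2)
  sc <- generate_scenario(cfg)
  grid <- window_grid(cfg$start_date, cfg$n_windows, cfg$window_length_days)
  nets <- build_networks(sc$od_records, grid, sc$tile_map)
  for (w in 2:4) {
    expect_equal(nets[[w]]$edges, nets[[1]]$edges, ignore_attr = TRUE)
  }
})

test_that("scenarios round-trip through the on-disk CSV/JSON dialect", {
  sc <- generate_scenario(tiny_config(seed = 8))
  dir <- withr::local_tempdir()
  manifest <- write_scenario(sc, dir)
  expect_setequal(names(manifest),
                  c("od_records", "tile_map", "municipal", "province_sector",
                    "sector_meta", "labels", "scenario"))
  expect_true(all(file.exists(manifest)))
  rt <- read_scenario(dir)
  expect_equal(rt$od_records, sc$od_records, ignore_attr = TRUE)
  expect_equal(rt$tile_map, sc$tile_map, ignore_attr = TRUE)
  expect_equal(as.data.frame(rt$municipal), as.data.frame(sc$municipal),
               tolerance = 1e-9)
  expect_equal(as.data.frame(rt$province_sector),
               as.data.frame(sc$province_sector), tolerance = 1e-9)
  expect_equal(rt$labels, sc$labels, ignore_attr = TRUE)
  expect_equal(rt$config$recovery_shapes, sc$config$recovery_shapes)
  expect_equal(rt$config$seed, sc$config$seed)
})

test_that("a scenario without mobility records writes a header-only flow file", {
  sc <- generate_scenario(tiny_config(seed = 8), components = "socioeconomic")
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  od <- data.table::fread(file.path(dir, "od_records.csv"))
  expect_identical(nrow(od), 0L)
  rt <- read_scenario(dir)
  expect_identical(nrow(rt$od_records), 0L)
})
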