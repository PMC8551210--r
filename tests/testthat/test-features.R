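test_that("income per capita is the pooled ratio over municipalities", {
  expect_equal(income_per_capita(c(100, 200), c(10, 10)), 15)
  expect_equal(income_per_capita(100, 10), 10)
  # pooled value lies between the member ratios (mediant inequality)
  r <- income_per_capita(c(100, 300), c(10, 10))
  expect_true(r >= 10 && r <= 30)
  expect_true(is.na(income_per_capita(c(100), c(0))))
})

test_that("inequality is the mean/median ratio", {
  expect_equal(inequality_ratio(c(1, 1, 1, 1, 6)), 2)
  expect_equal(inequality_ratio(c(1, 2, 3, 4, 5)), 1)
  expect_equal(inequality_ratio(c(1, 2, 3, 4, 90)), 20 / 3)
  expect_true(is.na(inequality_ratio(numeric())))
  expect_true(is.na(inequality_ratio(c(-1, 0, 1))))
})

test_that("right-skewed income distributions give inequality above one", {
  set.seed(3)
  for (i in 1:20) expect_gt(inequality_ratio(stats::rlnorm(500, 3, 0.8)), 1)
})

test_that("revenue concentration is the Herfindahl-Hirschman index", {
  expect_equal(revenue_concentration(c(10, 0, 0)), 1)
  expect_equal(revenue_concentration(c(5, 5)), 0.5)
  expect_equal(revenue_concentration(c(0.5, 0.3, 0.2)), 0.38)
  expect_true(is.na(revenue_concentration(c(0, 0))))
})

test_that("worker shares are employment-weighted", {
  sm <- data.table::data.table(sector = c("S01", "S02"),
                               remote_share = c(0.5, 0),
                               essential = c(TRUE, TRUE))
  ws <- worker_shares(c(S01 = 80, S02 = 20), sm)
  expect_equal(unname(ws["remote_share"]), 0.4)
  expect_equal(unname(ws["essential_share"]), 1)
  sm$essential <- c(FALSE, FALSE)
  expect_equal(unname(worker_shares(c(S01 = 80, S02 = 20), sm)["essential_share"]), 0)
  expect_true(all(is.na(worker_shares(c(S01 = 0, S02 = 0), sm))))
})

test_that("province quantities split by municipal employee shares and conserve totals", {
  ps <- data.table::data.table(province_id = "P1", sector = "S01",
                               employees = 100L, revenues = 200)
  mu <- data.table::data.table(municipality_id = c("M1", "M2"),
                               llm_id = c("L1", "L1"),
                               province_id = "P1",
                               emp_S01 = c(60L, 40L))
  out <- province_to_llm(ps, mu)
  expect_equal(out$revenues, 200)
  mu2 <- data.table::data.table(municipality_id = c("M1", "M2"),
                                llm_id = c("L1", "L2"),
                                province_id = "P1",
                                emp_S01 = c(60L, 40L))
  out2 <- province_to_llm(ps, mu2)
  expect_equal(out2$revenues[out2$llm_id == "L1"], 120)
  expect_equal(out2$revenues[out2$llm_id == "L2"], 80)
  mu3 <- rbind(mu2, data.table::data.table(municipality_id = "M3",
                                           llm_id = "L3", province_id = "P1",
                                           emp_S01 = 0L))
  out3 <- province_to_llm(ps, mu3)
  expect_equal(out3$revenues[out3$llm_id == "L3"], 0)
  mu_bad <- data.table::copy(mu2)
  mu_bad$llm_id[1] <- NA
  expect_error(province_to_llm(ps, mu_bad), "M1")
})

test_that("redistribution conserves every province-by-sector total on synthetic data", {
  sc <- generate_scenario(tiny_config(seed = 6), components = "socioeconomic")
  red <- province_to_llm(sc$province_sector, sc$municipal)
  tot <- red[, list(employees = sum(employees), revenues = sum(revenues)),
             by = "sector"]
  ref <- sc$province_sector[, list(employees = sum(employees),
                                   revenues = sum(revenues)), by = "sector"]
  chk <- merge(tot, ref, by = "sector")
  expect_lt(max(abs(chk$employees.x - chk$employees.y) /
                  pmax(chk$employees.y, 1)), 1e-9)
  expect_lt(max(abs(chk$revenues.x - chk$revenues.y) /
                  pmax(chk$revenues.y, 1)), 1e-9)
})

test_that("the assembled feature table has the 38 documented features", {
  sc <- generate_scenario(tiny_config(seed = 2), components = "socioeconomic")
  ft <- assemble_features(sc)
  cols <- attr(ft, "feature_cols")
  expect_identical(length(cols), 38L)
  expect_identical(ncol(ft), 40L) # llm_id + macroarea + 38
  expect_true(all(ft$revenue_concentration >= 1 / 16 - 1e-12 &
                    ft$revenue_concentration <= 1))
  expect_true(all(ft$remote_share >= 0 & ft$remote_share <= 1))
  expect_true(all(ft$essential_share >= 0 & ft$essential_share <= 1))

  std <- standardize_features(ft)
  X <- as.matrix(std$std[, cols, with = FALSE])
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_equal(unname(apply(X, 2, stats::sd)), rep(1, 38))
  # inverse transform recovers the raw table
  back <- sweep(sweep(X, 2, std$scale, `*`), 2, std$center, `+`)
  expect_equal(unname(back), unname(as.matrix(ft[, cols, with = FALSE])))
})

test_that("inequality aggregates to the generator's target ratio", {
  sc <- generate_scenario(tiny_config(seed = 2), components = "socioeconomic")
  ft <- assemble_features(sc)
  # the generator builds municipal medians as mean/g with one g per LLM, so
  # the assembled LLM inequality equals that g up to income rounding
  mu <- sc$municipal
  g_hat <- mu[, list(g = (sum(income_total) / sum(declarants)) /
                       (sum(declarants * income_median) / sum(declarants))),
              by = "llm_id"]
  m <- merge(ft, g_hat, by = "llm_id")
  expect_equal(m$inequality, m$g, tolerance = 1e-12)
})
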