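test_that("unit conversions follow the carcass arithmetic", {
  expect_equal(shrunk_body_weight(0), 0)
  expect_equal(shrunk_body_weight(500), 480)
  expect_equal(shrunk_body_weight(100), 96)
  expect_error(shrunk_body_weight(-1), "non-negative")

  expect_equal(accumulated_arroba(0, 58.55), 0)
  expect_equal(accumulated_arroba(480, 58.55), 480 * 0.5855 / 15)
  expect_equal(accumulated_arroba(480, 58.55), 18.736, tolerance = 1e-4)
  expect_equal(accumulated_arroba(15, 99.999999), 1.0, tolerance = 1e-6)
  expect_error(accumulated_arroba(15, 0), "dressing")
  expect_error(accumulated_arroba(15, 100), "dressing")
})

test_that("arroba gain telescopes exactly", {
  expect_equal(arroba_gain_series(c(5, 5, 5))$total, 0)
  expect_true(all(arroba_gain_series(c(5, 5, 5))$daily == 0))
  g <- arroba_gain_series(c(10, 11, 13))
  expect_equal(g$daily, c(0, 1, 2))
  expect_equal(g$total, 3)
  set.seed(1)
  acc <- cumsum(rnorm(50, 0.2, 0.3))
  g <- arroba_gain_series(acc)
  expect_equal(sum(g$daily), g$total, tolerance = 1e-12)
  expect_equal(g$total, acc[50] - acc[1], tolerance = 1e-12)
  expect_error(arroba_gain_series(5), "two days")
})

test_that("daily cost and revenue follow the price structure", {
  cfg <- econ_config(diet_price_kg = 0.50, feedlot_daily_overhead = 2.00,
                     arroba_price = 300)
  expect_equal(daily_cost(0, econ_config(diet_price_kg = 1,
                                         feedlot_daily_overhead = 0)), 0)
  expect_equal(daily_cost(8.06, cfg), 6.03)
  expect_error(daily_cost(-1, cfg), "non-negative")
  expect_equal(daily_revenue(0, cfg), 0)
  expect_equal(daily_revenue(0.2, cfg), 60)
  expect_equal(daily_revenue(-0.1, cfg), -30)
})

test_that("two-day toy log matches the spreadsheet-style hand oracle", {
  # weights 400 -> 415 kg, dmi 8 both days, diet 0.5 $/kg, overhead 1 $,
  # arroba 300 $, entire male: every equation evaluated independently
  cfg <- econ_config(diet_price_kg = 0.5, feedlot_daily_overhead = 1,
                     arroba_price = 300)
  sbw1 <- 0.96 * 400; sbw2 <- 0.96 * 415
  acc1 <- sbw1 * 58.55 / 100 / 15; acc2 <- sbw2 * 58.55 / 100 / 15
  gain2 <- acc2 - acc1
  rev <- c(0, 300 * gain2)
  cost <- c(8 * 0.5 + 1, 8 * 0.5 + 1)
  afp_hand <- sum(rev - cost)
  r <- profit_series(day = 1:2, weight_kg = c(400, 415), dmi_kg = c(8, 8),
                     sex = "male", cfg = cfg)
  expect_equal(r$afp, afp_hand, tolerance = 1e-12)
  expect_equal(r$total_arroba_gain, gain2, tolerance = 1e-12)
  expect_equal(r$daily$revenue, rev, tolerance = 1e-12)
  expect_equal(r$daily$cost, cost, tolerance = 1e-12)
  # explicit numeric value of the hand computation
  expect_equal(afp_hand, 300 * 0.96 * 15 * 0.5855 / 15 - 10, tolerance = 1e-9)
})

test_that("profit accounting identities hold on simulated logs", {
  log <- simulate_feedlot_log(paste0("a", 1:25), n_days = 40, seed = 2)
  meta <- data.frame(animal = paste0("a", 1:25),
                     sex = rep(c("male", "female"), length.out = 25))
  cfg <- econ_config()
  for (id in c("a1", "a13")) {
    li <- log[log$animal == id, ]
    r <- profit_series(li$day, li$weight_kg, li$dmi_kg,
                       meta$sex[meta$animal == id], cfg)
    expect_equal(r$afp, r$total_revenue - r$total_cost, tolerance = 1e-9)
    expect_equal(r$afp, sum(r$daily$profit), tolerance = 1e-9)
    expect_equal(sum(r$daily$arroba_gain),
                 r$daily$arroba[nrow(r$daily)] - r$daily$arroba[1],
                 tolerance = 1e-12)
  }
  # zero prices -> zero AFP
  z <- profit_series(1:3, c(400, 405, 410), c(8, 8, 8), "male",
                     econ_config(diet_price_kg = 0, feedlot_daily_overhead = 0,
                                 arroba_price = 0))
  expect_equal(z$afp, 0)
  expect_error(profit_series(1:2, c(400, 405), c(8, 8), "steer"), "sex")
})

test_that("AFP responds monotonically to prices and dressing drives the sex gap", {
  li <- simulate_feedlot_log("a1", n_days = 30, seed = 3)
  base <- econ_config()
  afp <- function(cfg, sex = "male")
    profit_series(li$day, li$weight_kg, li$dmi_kg, sex, cfg)$afp
  expect_lt(afp(econ_config(diet_price_kg = base$diet_price_kg + 0.5)),
            afp(base))
  expect_lt(afp(econ_config(feedlot_daily_overhead = base$feedlot_daily_overhead + 1)),
            afp(base))
  expect_gt(afp(econ_config(arroba_price = base$arroba_price + 50)), afp(base))
  # identical log: male/female revenue ratio equals the dressing ratio
  rm_ <- profit_series(li$day, li$weight_kg, li$dmi_kg, "male", base)
  rf_ <- profit_series(li$day, li$weight_kg, li$dmi_kg, "female", base)
  expect_equal(rm_$total_revenue / rf_$total_revenue, 58.55 / 55.34,
               tolerance = 1e-9)
  expect_equal(rm_$total_cost, rf_$total_cost)
})

test_that("profit per gain handles signs and degenerate gain", {
  mk <- function(afp, gain) structure(list(afp = afp, pft = afp / gain,
                                           total_arroba_gain = gain),
                                      class = "profit_result")
  expect_equal(profit_per_gain(mk(0, 2)), 0)
  expect_equal(profit_per_gain(mk(150, 5)), 30)
  expect_equal(profit_per_gain(mk(150, 5), per_kg = TRUE), 2)
  expect_lt(profit_per_gain(mk(-20, 4)), 0)
  # zero gain -> missing phenotype, not an error
  r <- profit_series(1:2, c(400, 400), c(8, 8), "male", econ_config())
  expect_true(is.na(r$pft))
  expect_true(is.na(profit_per_gain(r)))
})

test_that("batch profit phenotypes line up with per-animal runs", {
  log <- simulate_feedlot_log(paste0("b", 1:6), n_days = 20, seed = 4)
  meta <- data.frame(animal = paste0("b", 1:6),
                     sex = rep(c("male", "female"), 3))
  out <- profit_phenotypes(log, meta)
  expect_equal(nrow(out), 6L)
  li <- log[log$animal == "b3", ]
  r <- profit_series(li$day, li$weight_kg, li$dmi_kg, "male", econ_config())
  expect_equal(out$afp[out$animal == "b3"], r$afp)
  expect_equal(out$pft[out$animal == "b3"], r$pft)
  # windowing restricts the evaluation period
  outw <- profit_phenotypes(log, meta, window = c(1, 10))
  expect_true(all(outw$n_days == 10))
})
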