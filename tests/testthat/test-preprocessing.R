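test_that("unit values are expenditure-weighted means of record prices", {
  config <- toy_config()
  # single record: 10 / 5 = 2
  p1 <- as_purchase_table(rbind(prow("h1", "ssb", 10, 5),
                                prow("h1", "other_foods", 1, 1)), config)
  uv1 <- compute_unit_values(p1)
  expect_equal(uv1$unit_value[uv1$category == "ssb"], 2.0)
  # two records (10, 5) and (10, 2): equal expenditure weights over unit
  # prices 2 and 5 give 3.5
  p2 <- as_purchase_table(rbind(prow("h1", "ssb", 10, 5),
                                prow("h1", "ssb", 10, 2),
                                prow("h1", "other_foods", 1, 1)), config)
  uv2 <- compute_unit_values(p2)
  expect_equal(uv2$unit_value[uv2$category == "ssb"], 3.5)
  # spreadsheet-style independent recomputation on uneven weights
  e <- c(3, 9); q <- c(2, 3)
  p3 <- as_purchase_table(rbind(prow("h1", "ssb", e[1], q[1]),
                                prow("h1", "ssb", e[2], q[2]),
                                prow("h1", "other_foods", 1, 1)), config)
  uv3 <- compute_unit_values(p3)
  expect_equal(uv3$unit_value[uv3$category == "ssb"],
               sum((e / sum(e)) * (e / q)))
})

test_that("cells without purchases are flagged for imputation", {
  uv <- compute_unit_values(toy_purchases())
  miss <- uv[uv$household_id == "h2" & uv$category == "ssb", ]
  expect_true(miss$imputed)
  expect_true(is.na(miss$unit_value))
  obs <- uv[!is.na(uv$unit_value), ]
  expect_true(all(obs$imputation_level == "observed"))
})

test_that("zero quantity with positive expenditure is a data error", {
  config <- toy_config()
  df <- rbind(prow("h1", "ssb", 10, 5), prow("h1", "other_foods", 1, 1))
  p <- as_purchase_table(df, config)
  p$quantity[1] <- 0  # corrupt after validation
  expect_error(compute_unit_values(p), "zero quantity")
})

test_that("imputation follows the state -> region -> national chain", {
  config <- toy_config()
  df <- rbind(
    # state S01 (region R1) observes ssb at 4.2
    prow("h1", "ssb", 8.4, 2, state = "S01", region = "R1"),
    prow("h1", "other_foods", 1, 1, state = "S01", region = "R1"),
    # h2 in S01 misses ssb -> state mean 4.2
    prow("h2", "other_foods", 1, 1, state = "S01", region = "R1"),
    # state S02 in R1 has no ssb observation; region mean is 4.2 too
    prow("h3", "other_foods", 1, 1, state = "S02", region = "R1"),
    # state S03 in region R2: no ssb anywhere in R2 -> national mean
    prow("h4", "other_foods", 1, 1, state = "S03", region = "R2"),
    # milk observed only for h4
    prow("h4", "milk", 3, 1, state = "S03", region = "R2"))
  p <- as_purchase_table(df, config)
  pr <- impute_prices(compute_unit_values(p))
  cell <- function(hh, cat) pr[pr$household_id == hh & pr$category == cat, ]
  expect_equal(cell("h2", "ssb")$unit_value, 4.2)
  expect_equal(cell("h2", "ssb")$imputation_level, "state")
  expect_equal(cell("h3", "ssb")$unit_value, 4.2)
  expect_equal(cell("h3", "ssb")$imputation_level, "region")
  expect_equal(cell("h4", "ssb")$imputation_level, "national")
  # observed values never change
  expect_equal(cell("h1", "ssb")$unit_value, 4.2)
  expect_equal(cell("h1", "ssb")$imputation_level, "observed")
  expect_true(all(pr$unit_value > 0))
})

test_that("a category never observed anywhere stops estimation", {
  config <- toy_config()
  df <- rbind(prow("h1", "milk", 2, 1), prow("h1", "other_foods", 1, 1))
  p <- as_purchase_table(df, config)
  expect_error(impute_prices(compute_unit_values(p)), "ssb")
})

test_that("a fully observed category has no imputed cells", {
  config <- toy_config(categories = c("milk", "other_foods"))
  df <- rbind(prow("h1", "milk", 2, 1), prow("h1", "other_foods", 1, 1),
              prow("h2", "milk", 4, 1), prow("h2", "other_foods", 1, 1))
  pr <- impute_prices(compute_unit_values(as_purchase_table(df, config)))
  expect_false(any(pr$imputed))
})

test_that("assembly produces shares, drops empty households, and keeps
          share rows summing to one", {
  config <- toy_config(categories = c("milk", "other_foods"))
  df <- rbind(prow("h1", "milk", 6, 2), prow("h1", "other_foods", 4, 2),
              prow("h2", "milk", 2, 2), prow("h2", "other_foods", 8, 2),
              prow("h3", "milk", 0, 0))  # recorded but empty household
  p <- as_purchase_table(df, config)
  pr <- impute_prices(compute_unit_values(p))
  expect_message(d <- assemble_system(p, pr, config), "dropped")
  expect_equal(d$n_dropped, 1L)
  expect_equal(nrow(d$w), 2L)
  expect_equal(unname(d$w[1, ]), c(0.6, 0.4))
  expect_equal(unname(d$mean_shares), c(0.4, 0.6))
  expect_equal(unname(rowSums(d$w)), rep(1, 2), tolerance = 1e-10)
})

test_that("both indices sit at their identity values at base prices", {
  # every household faces the same prices, whatever the shares
  config <- toy_config(categories = c("milk", "other_foods"))
  df <- rbind(prow("h1", "milk", 6, 3), prow("h1", "other_foods", 4, 1),
              prow("h2", "milk", 2, 1), prow("h2", "other_foods", 8, 2))
  p <- as_purchase_table(df, config)
  d <- assemble_system(p, impute_prices(compute_unit_values(p)), config)
  expect_equal(d$ln_a, rep(0, 2), tolerance = 1e-12)
  expect_equal(d$b, rep(1, 2), tolerance = 1e-12)
})

test_that("single-good price deviation gives the textbook index value", {
  d <- list(lnp = matrix(c(log(2), 0), 1, 2),
            w = matrix(c(0.5, 0.5), 1, 2),
            mean_shares = c(0.5, 0.5),
            base_log_prices = c(0, 0))
  expect_equal(tornqvist_index(d), 0.5 * log(2), tolerance = 1e-12)
})

test_that("the exact aggregator follows the Cobb-Douglas form", {
  d <- list(lnp = matrix(c(1, 0), 1, 2), w = matrix(c(0.5, 0.5), 1, 2),
            mean_shares = c(0.5, 0.5), base_log_prices = c(0, 0))
  expect_equal(matsuda_b_index(d, beta = c(0, 0), mode = "exact"), 1)
  expect_equal(log(matsuda_b_index(d, beta = c(0.1, -0.1),
                                   mode = "exact")), 0.1,
               tolerance = 1e-12)
  expect_error(matsuda_b_index(d, mode = "exact"), "beta")
})

test_that("indices match direct recomputation and are order-invariant", {
  set.seed(301)
  truth <- make_default_truth(5, seed = 301, price_household_sd = 0.05)
  d <- assembled_from_truth(truth, 400)
  # direct re-evaluation from the definitions
  dev <- sweep(d$lnp, 2, d$base_log_prices)
  la <- rowSums(0.5 * (d$w + matrix(d$mean_shares, nrow(d$w), 5,
                                    byrow = TRUE)) * dev)
  expect_equal(d$ln_a, la, tolerance = 1e-12)
  lb <- rowSums(0.5 * (d$w - matrix(d$mean_shares, nrow(d$w), 5,
                                    byrow = TRUE)) * dev)
  expect_equal(log(d$b), lb, tolerance = 1e-12)
  # permutation invariance in the category ordering
  perm <- c(3, 1, 5, 2, 4)
  dp <- d
  dp$lnp <- d$lnp[, perm]; dp$w <- d$w[, perm]
  dp$mean_shares <- d$mean_shares[perm]
  dp$base_log_prices <- d$base_log_prices[perm]
  expect_equal(tornqvist_index(dp), d$ln_a, tolerance = 1e-12)
  expect_equal(matsuda_b_index(dp), d$b, tolerance = 1e-12)
})
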