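test_that("labor converts monthly salary by omega times headcount", {
  expect_equal(labor_costs(data.frame(activity = "a", Sa = 4345,
                                      Nca = 2))$total, 2000)
  expect_equal(labor_costs(data.frame(activity = "a", Sa = 4345,
                                      Nca = 0))$total, 0)
  two <- data.frame(activity = c("a", "b"), Sa = c(4345, 2172.5), Nca = 1)
  expect_equal(labor_costs(two)$total, 1000 + 500)
})

test_that("utilities apply the apportionment share before omega", {
  u <- list(Pe = 0.869, Qe = 1000, Pt_phone = 100, Pi_internet = 117.25,
            share = 1)
  uc <- utility_costs(u)
  expect_equal(uc$CTE, 200)
  expect_equal(uc$CTTI, 217.25 / 4.345)
  u0 <- u; u0$share <- 0
  expect_equal(unlist(utility_costs(u0)), c(CTE = 0, CTTI = 0))
  uh <- u; uh$share <- 0.5
  expect_equal(utility_costs(uh)$CTE, 100)
})

test_that("fuel lines sum monthly and convert by omega", {
  f1 <- data.frame(fuel = "diesel", Pcx = 5, Qcx = 86.9, share = 1)
  expect_equal(fuel_costs(f1)$total, 100)
  expect_equal(fuel_costs(f1[0, ])$total, 0)
  expect_equal(fuel_costs(rbind(f1, f1))$total, 200)
  fh <- transform(f1, share = 0.5)
  expect_equal(fuel_costs(fh)$total, 50)
})

asset1 <- data.frame(label = "barn", class = "housing", Pc = 100000, Qc = 1,
                     txres = 0.1, vu = 10, txman = 0.02)

test_that("straight-line depreciation with residual value", {
  d <- depreciation_costs(asset1)
  expect_equal(d$lines$Vc, 100000)
  expect_equal(d$lines$Vres, 10000)
  expect_equal(d$annual, 9000)
  expect_equal(d$total, 9000 * 7 / 365)  # 172.6027
  # residual fraction approaching 1 drives depreciation to zero
  expect_equal(depreciation_costs(transform(asset1, txres = 0.999))$annual,
               100000 * 0.001 / 10)  # -> 0 as txres -> 1
  expect_equal(depreciation_costs(transform(asset1, Qc = 0))$total, 0)
  expect_error(depreciation_costs(transform(asset1, vu = 0)), "vu")
})

test_that("maintenance is a rate on asset value, prorated by phi", {
  m <- maintenance_costs(asset1)
  expect_equal(m$annual, 2000)
  expect_equal(m$total, 2000 * 7 / 365)  # 38.3562
  expect_equal(maintenance_costs(transform(asset1, txman = 0))$total, 0)
  expect_equal(maintenance_costs(transform(asset1, Pc = 200000))$total,
               2 * m$total)
})

test_that("fixed financial expenses and the CFOP sum", {
  expect_equal(fixed_financial(list(ITR = 730, Txf = 0, Otf = 0)), 14)
  CFOP <- total_fixed(2000, 200, 0, 100, 9000 * 7 / 365, 2000 * 7 / 365, 14)
  expect_equal(CFOP, 2314 + 11000 * 7 / 365)  # 2524.9589
  expect_equal(total_fixed(0, 0, 0, 0, 0, 0, 0), 0)
})

test_that("weekly x phi recovers annual depreciation/maintenance exactly", {
  cfg <- generate_farm(scenario_spec(seed = 9, size_class = "medium"))
  tb <- time_basis()
  d <- depreciation_costs(cfg$assets, tb)
  m <- maintenance_costs(cfg$assets, tb)
  expect_identical(d$total * tb$phi, d$annual)
  expect_identical(m$total * tb$phi, m$annual)
})

test_that("CFOP is invariant to splitting an asset line by value", {
  one <- asset1
  split <- rbind(transform(asset1, Pc = 60000), transform(asset1, Pc = 40000))
  cfg1 <- base_farm(assets = one)
  cfg2 <- base_farm(assets = split)
  s1 <- ledger_subtotals(compute_ledger(cfg1))
  s2 <- ledger_subtotals(compute_ledger(cfg2))
  expect_equal(s2$CFOP, s1$CFOP)
  expect_equal(s2$CT, s1$CT)
})
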