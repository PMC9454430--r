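test_that("operating and total cost are the two-stage sum", {
  tc <- total_cost(CV = 2495, CFOP = 2524.9589, CO = 212.4895)
  expect_equal(tc$COP, 5019.9589)
  expect_equal(tc$CT, 5232.4484)
  expect_equal(total_cost(10, 5, 0)$CT, total_cost(10, 5, 0)$COP)
  expect_equal(total_cost(0, 0, 0)$CT, 0)
})

test_that("unit costs per head, arroba and kg", {
  uc <- unit_costs(CT = 52500, Ntl = 100, kgcab = 115)
  expect_equal(uc$CTcab, 525)
  expect_equal(uc$CTkg, 52500 / 11500)          # 4.5652
  expect_equal(uc$CTarroba, 18.75 * 52500 / 11500)  # 85.5978
  expect_equal(unit_costs(0, 100, 115), list(CTcab = 0, CTarroba = 0,
                                             CTkg = 0))
  expect_error(unit_costs(100, 0, 115), "undefined")
})

test_that("arroba/kg unit-cost ratio is the arroba constant", {
  for (CT in c(1, 52500, 9e6)) {
    uc <- unit_costs(CT, Ntl = 137.5, kgcab = 118.3)
    expect_equal(uc$CTarroba / uc$CTkg, 18.75)
  }
})

test_that("revenue combines market pigs and culls", {
  cull <- 400 * 7 / 365 * 220  # 1687.671 kg/week of cull sows
  rv <- revenue(theta = 11500, cull_kg = cull,
                market = list(Pvc = 6, Pvd = 3.5), Ntl = 100)
  expect_equal(rv$Rs, 69000 + cull * 3.5)  # 74906.85
  expect_equal(rv$Rcab, rv$Rs / 100)
  expect_equal(rv$Rkg, rv$Rs / 11500)
  no_cull <- revenue(11500, 0, list(Pvc = 6, Pvd = 3.5), 100)
  expect_equal(no_cull$Rs, 69000)
  expect_equal(revenue(11500, cull, list(Pvc = 0, Pvd = 0), 100)$Rs, 0)
  expect_error(revenue(0, cull, list(Pvc = 6, Pvd = 3.5), 0), "undefined")
})

test_that("profit, leveling point, RBC and ROI", {
  cull <- 400 * 7 / 365 * 220
  Rs <- 69000 + cull * 3.5
  pf <- profitability(Rs, CT = 52500, Pvc = 6, kgcab = 115)
  expect_equal(pf$L, Rs - 52500)           # 22406.85
  expect_equal(pf$PN, 52500 / 690)         # 76.087 head
  expect_equal(pf$RBC, Rs / 52500)         # 1.4268
  expect_equal(pf$ROI, (Rs - 52500) / 52500)  # 0.4268 -> 42.68%
  # break-even
  be <- profitability(52500, 52500, 6, 115)
  expect_equal(be$L, 0)
  expect_equal(be$RBC, 1)
  expect_equal(be$ROI, 0)
  # inversion identity: producing PN head at Pvc and kgcab covers CT
  expect_equal(pf$PN * 6 * 115, 52500)
  expect_error(profitability(100, 0, 6, 115), "undefined")
})

test_that("producer income adds profit, opportunity cost and family labor", {
  CO <- (6000 + 79.8 + 5000) * 7 / 365
  expect_equal(producer_income(22406.85, CO, 1000),
               22406.85 + CO + 1000)  # 23619.34
  expect_equal(producer_income(-CO, CO, 0), 0)
  # beta enters producer income but never the cost ledger
  cfg <- generate_farm(scenario_spec(seed = 13, size_class = "small"))
  b1 <- compute_batch(cfg)
  cfg$market$beta <- cfg$market$beta + 500
  b2 <- compute_batch(cfg)
  expect_equal(b2$report$CT, b1$report$CT)
  expect_equal(b2$report$RTs, b1$report$RTs + 500)
})

test_that("compute_batch ties the indicator suite together coherently", {
  cfg <- generate_farm(scenario_spec(seed = 21, size_class = "medium"))
  r <- compute_batch(cfg)$report
  expect_equal(r$COP, r$CV + r$CFOP)
  expect_equal(r$CT, r$COP + r$CO)
  expect_equal(r$ROI, r$RBC - 1)
  expect_equal(r$L, r$Rs - r$CT)
  expect_equal(r$RTkg, r$RTs / r$theta)
  expect_equal(r$CTarroba / r$CTkg, 18.75)
})
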