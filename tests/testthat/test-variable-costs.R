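pop1 <- data.frame(category = "piglet", phase = "farrowing",
                   role = "growout", count = 5)

test_that("feed cost is price x period x daily amount x head", {
  diets <- data.frame(category = "piglet", phase = "farrowing",
                      Pa = 1.5, Ta = 10, Qa = 2)
  fc <- feed_costs(diets, pop1)
  expect_equal(fc$lines$Crun, 20)   # kg per animal in the phase
  expect_equal(fc$lines$Crs, 100)   # kg per week for the phase
  expect_equal(fc$total, 150)
  # zero intake, zero cost
  expect_equal(feed_costs(transform(diets, Qa = 0), pop1)$total, 0)
  # additivity over lines
  expect_equal(feed_costs(rbind(diets, diets), pop1)$total, 300)
  # unknown (category, phase) is a configuration error
  expect_error(feed_costs(transform(diets, phase = "nursery"), pop1),
               "unknown \\(category, phase\\)")
})

test_that("health cost is dose price x doses x head", {
  pop <- data.frame(category = "piglet", phase = "farrowing",
                    role = "growout", count = 114)
  lines <- data.frame(category = "piglet", phase = "farrowing",
                      Pd = 2.5, q = 2)
  hc <- health_costs(lines, pop)
  expect_equal(hc$lines$Qds, 228)
  expect_equal(hc$total, 570)
  expect_equal(health_costs(transform(lines, q = 0), pop)$total, 0)
  # unit price and single dose returns the head count itself
  expect_equal(health_costs(transform(lines, Pd = 1, q = 1), pop)$total, 114)
  expect_error(health_costs(transform(lines, category = "dam"), pop),
               "unknown")
})

test_that("reproduction inputs are consumed by the weekly sow group", {
  plan <- list(scenario = "purchased",
               lines = data.frame(category = "dam", phase = "gestation",
                                  source = "purchased", Pr = 20, q = 3))
  expect_equal(repro_costs(plan, GS = 10)$total, 600)
  empty <- list(scenario = "purchased",
                lines = plan$lines[0, ])
  expect_equal(repro_costs(empty, GS = 10)$total, 0)
  mixed <- list(scenario = "mixed", lines = rbind(
    plan$lines,
    data.frame(category = "boar", phase = "service", source = "on_farm",
               Pr = 5, q = 2)))
  expect_equal(repro_costs(mixed, GS = 10)$total, 600 + 100)
})

test_that("consumer goods convert monthly quantities by omega", {
  goods <- data.frame(item = "gloves", Pb = 10, Qb = 4.345)
  expect_equal(consumer_goods_costs(goods)$total, 10)
  expect_equal(consumer_goods_costs(transform(goods, Qb = 0))$total, 0)
  M <- 123.45  # any monthly spend
  expect_equal(consumer_goods_costs(
    data.frame(item = "x", Pb = 1, Qb = M))$total, M / 4.345)
})

test_that("raising subtotal and variable total are exact sums", {
  expect_equal(raising_subtotal(150, 570, 600, 10), 1330)
  expect_equal(raising_subtotal(0, 0, 0, 0), 0)
  expect_equal(raising_subtotal(570, 150, 10, 600), 1330)  # order-free
  expect_equal(total_variable(1330, 1158, 7), 2495)
  expect_gte(total_variable(1330, 1158, 7), 1330)
})

test_that("transport and batch insurance on invested capital", {
  ti <- transport_insurance(list(Pt = 8.5, Qt = 120, Txseg = 0.002),
                            Ntl = 100, kgcab = 115, Pvc = 6)
  expect_equal(ti$Cta, 1020)
  expect_equal(ti$Cminvest, 69000)
  expect_equal(ti$Cseg, 138)
  expect_equal(ti$total, 1158)
  no_ins <- transport_insurance(list(Pt = 8.5, Qt = 120, Txseg = 0),
                                100, 115, 6)
  expect_equal(no_ins$total, no_ins$Cta)
  expect_equal(transport_insurance(list(Pt = 8.5, Qt = 0, Txseg = 0),
                                   100, 115, 6)$total, 0)
})

test_that("variable taxes prorate annual amounts by phi", {
  t1 <- list(ICMS = 100, GTA = 100, FUN = 100, Otv = 65)
  expect_equal(variable_financial(t1), 7)
  expect_equal(variable_financial(list(ICMS = 0, GTA = 0, FUN = 0, Otv = 0)),
               0)
  t2 <- lapply(t1, `*`, 2)
  expect_equal(variable_financial(t2), 14)  # linear
})

test_that("CV is homogeneous of degree one in prices", {
  cfg <- generate_farm(scenario_spec(seed = 5, size_class = "small"))
  s1 <- ledger_subtotals(compute_ledger(cfg))
  s2 <- ledger_subtotals(compute_ledger(scale_prices(cfg, 3)))
  expect_equal(s2$CV, 3 * s1$CV)
  # ledger additivity: CV equals the sum of its A-group line items
  led <- compute_ledger(cfg)
  expect_equal(sum(led$value[led$group == "A"]), s1$CV)
})
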