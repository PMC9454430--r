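batch <- compute_batch(generate_farm(scenario_spec(seed = 4,
                                                   size_class = "small")))

test_that("csv report carries subtotals in A..E order at full precision", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(batch$report, batch$ledger, f, format = "csv")
  tab <- read.csv(f, stringsAsFactors = FALSE)
  s <- ledger_subtotals(batch$ledger)
  sub_rows <- tab[tab$section == "subtotal", ]
  expect_identical(sub_rows$group, c("A", "A", "B", "C", "D", "E"))
  expect_identical(tab$value[tab$item == "E - Total cost (CT = C + D)"],
                   s$CT)
  expect_identical(tab$value[tab$item == "C - Operating cost (COP = A + B)"],
                   s$COP)
  # line items sum to their printed group subtotals at full precision
  expect_equal(sum(tab$value[tab$group == "A" & tab$section != "subtotal"]),
               s$CV, tolerance = 1e-12)
  expect_equal(sum(tab$value[tab$group == "B" & tab$section != "subtotal"]),
               s$CFOP, tolerance = 1e-12)
  expect_equal(sum(tab$value[tab$group == "D" & tab$section != "subtotal"]),
               s$CO, tolerance = 1e-12)
})

test_that("json report round-trips every value exactly", {
  f <- withr::local_tempfile(fileext = ".json")
  write_report(batch$report, batch$ledger, f, format = "json")
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$subtotals, ledger_subtotals(batch$ledger))
  rep_in <- unclass(batch$report)
  expect_identical(sort(names(back$report)), sort(names(rep_in)))
  for (nm in names(rep_in))
    expect_equal(back$report[[nm]], rep_in[[nm]])
  expect_equal(back$lines$value, batch$ledger$value)
})

test_that("empty register groups appear as zero subtotals, not omissions", {
  zero <- compute_batch(base_farm())
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(zero$report, zero$ledger, f, format = "csv")
  tab <- read.csv(f, stringsAsFactors = FALSE)
  sub_rows <- tab[tab$section == "subtotal", ]
  expect_identical(nrow(sub_rows), 6L)
  expect_true(all(sub_rows$value == 0))
})

test_that("text report is human-readable and complete", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_report(batch$report, batch$ledger, f, format = "text")
  txt <- readLines(f)
  expect_true(any(grepl("E - Total cost", txt)))
  expect_true(any(grepl("Benefit-cost ratio", txt)))
  # rendered total matches the in-memory value at 2 decimals
  total_line <- grep("E - Total cost", txt, value = TRUE)
  shown <- as.numeric(sub(".* ", "", trimws(total_line)))
  expect_equal(shown, round(ledger_subtotals(batch$ledger)$CT, 2),
               tolerance = 0.005)
})
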