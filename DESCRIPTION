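Package: pigcost
Title: Production Cost Model and Economic Indicators for Full-Cycle Swine Farms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes the complete weekly cost ledger and economic indicator
    suite for a full-cycle swine farm. Costs are allocated according to the
    neoclassical scheme used in farm enterprise budgeting: variable costs
    (feed, health, reproduction, consumer goods, transport and insurance,
    variable taxes), fixed operating costs (labor, utilities, fuel,
    straight-line depreciation, maintenance, fixed taxes) and opportunity
    costs of fixed capital, working capital and land. From a structured farm
    configuration the package derives the weekly sow group, the batch flow of
    market pigs through the production phases with per-phase mortality, and
    the indicator suite: cost per head, per arroba (18.75 kg) and per
    kilogram, revenue, profit, leveling point, benefit-cost ratio, return on
    investment and producer total income. Includes a seeded synthetic-farm
    generator for testing and scenario work, an independent brute-force
    ledger oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
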