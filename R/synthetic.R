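# Seeded synthetic-farm generator.
#
# Produces complete, valid configurations for testing and scenario work.
# Parameter bounds are test scaffolding loosely calibrated to plausible
# Brazilian full-cycle farms (prices in BRL around 2022); they are arbitrary
# documented ranges, not survey data. Each register draws from its own named
# random stream so that adding a register never shifts the draws of the
# existing ones for a fixed seed.

.synth_sizes <- list(
  small  = c(50, 200),
  medium = c(200, 1000),
  large  = c(1000, 5000)
)

# Uniform-draw bounds per register (documented scaffolding, one place).
.synth_ranges <- list(
  herd = list(ppa = c(2.2, 2.5), txparto = c(0.85, 0.95), Nnv = c(12, 16),
              kgcab = c(110, 130)),
  mort = list(farrowing = c(0.06, 0.10), nursery = c(0.02, 0.04),
              growing = c(0.01, 0.03), finishing = c(0.005, 0.02)),
  culls = list(female_rate = c(0.35, 0.45), female_kg = c(200, 250),
               male_rate = c(0.25, 0.40), male_kg = c(250, 300)),
  diets = list(price = c(1.2, 2.5)),
  health = list(price = c(0.5, 5), doses = c(1, 3)),
  repro = list(semen = c(15, 35), supplies = c(1, 4), doses = c(2, 3)),
  goods = list(n = c(3, 6), price = c(1, 50), qty = c(1, 40)),
  transport = list(Pt = c(5, 12), Qt = c(30, 300), Txseg = c(0.001, 0.004)),
  vtaxes = list(ICMS = c(50, 150), GTA = c(2, 6), FUN = c(20, 60),
                Otv = c(0, 10)),   # per sow per year
  labor = list(sows_per_emp = c(70, 120), manager = c(4000, 7000),
               handler = c(1800, 3200)),
  utilities = list(Pe = c(0.6, 1.0), kwh_per_sow = c(8, 15),
                   phone = c(50, 150), internet = c(80, 200),
                   share = c(0.8, 1)),
  fuels = list(diesel = c(5.5, 7.5), diesel_l = c(0.3, 1.0),
               gasoline = c(6.0, 8.0), gasoline_l = c(0.1, 0.4),
               share = c(0.7, 1)),
  assets = list(housing_per_sow = c(2500, 4000), housing_res = c(0.10, 0.20),
                housing_vu = c(20, 25), machinery_per_sow = c(300, 600),
                machinery_res = c(0.05, 0.15), machinery_vu = c(8, 12),
                dam_price = c(1200, 2500), boar_price = c(3000, 6000),
                bio_res = c(0.30, 0.50), bio_vu = c(2.5, 3.5),
                txman = c(0.01, 0.03)),
  ftaxes = list(ITR = c(500, 5000), Txf = c(300, 1500), Otf = c(0, 1000)),
  opportunity = list(rate = c(0.02, 0.14), ha_per_sow = c(0.01, 0.03),
                     PATr = c(800, 2000)),
  market = list(Pvc = c(5.5, 7.5), Pvd = c(3.0, 4.5), beta = c(1000, 3000))
)

.stream_offsets <- c(herd = 1, mort = 2, culls = 3, diets = 4, health = 5,
                     repro = 6, goods = 7, transport = 8, vtaxes = 9,
                     labor = 10, utilities = 11, fuels = 12, assets = 13,
                     ftaxes = 14, opportunity = 15, market = 16)

.seed_stream <- function(seed, name) {
  off <- .stream_offsets[[name]]
  set.seed((abs(seed) %% 2000003L) * 1000L + off)
}

.draw <- function(range, digits = 4, n = 1) {
  round(stats::runif(n, range[1], range[2]), digits)
}

#' Scenario specification for the synthetic-farm generator
#'
#' @param seed integer seed; identical `(seed, size_class)` pairs yield
#'   identical configurations.
#' @param size_class `"small"` (50-200 sows), `"medium"` (200-1000) or
#'   `"large"` (1000-5000).
#' @return object of class `scenario_spec`.
#' @seealso [generate_farm()]
#' @export
scenario_spec <- function(seed, size_class = c("medium", "small", "large")) {
  size_class <- match.arg(size_class)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(seed = as.integer(seed), size_class = size_class,
                 sow_range = .synth_sizes[[size_class]],
                 ranges = .synth_ranges),
            class = "scenario_spec")
}

#' Generate a complete synthetic farm configuration
#'
#' Draws a full [farm_config] — herd, grow-out phases, breeding stock, cull
#' plan and every cost register — from the seeded uniform ranges of the
#' scenario specification. Every generated configuration passes
#' [validate_config()] with zero errors and has at least one line in each
#' register. All drawn values are rounded (at most 5 decimals) so that
#' YAML serialization round-trips exactly.
#'
#' @param spec a [scenario_spec()].
#' @return a valid [farm_config].
#' @examples
#' cfg <- generate_farm(scenario_spec(seed = 42, size_class = "medium"))
#' cfg$herd$N
#' @export
generate_farm <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  seed <- spec$seed
  rg <- spec$ranges

  .seed_stream(seed, "herd")
  N <- round(stats::runif(1, spec$sow_range[1], spec$sow_range[2]))
  ppa <- .draw(rg$herd$ppa, 2)
  txparto <- .draw(rg$herd$txparto, 3)
  Nnv <- .draw(rg$herd$Nnv, 1)
  kgcab <- .draw(rg$herd$kgcab, 1)
  gest_share <- .draw(c(0.75, 0.82), 3)
  gilt_share <- .draw(c(0.08, 0.12), 3)
  boar_share <- .draw(c(0.005, 0.015), 4)
  dams_gest <- round(N * gest_share)
  dams_lact <- N - dams_gest
  gilts <- round(N * gilt_share)
  boars <- max(1, round(N * boar_share))

  .seed_stream(seed, "mort")
  phases <- data.frame(
    category = c("piglet", "piglet", "grower", "finisher",
                 "dam", "dam", "gilt", "boar"),
    phase = c("farrowing", "nursery", "growing", "finishing",
              "gestation", "lactation", "acclimation", "service"),
    role = c(rep("growout", 4), rep("breeding", 4)),
    txmort = c(.draw(rg$mort$farrowing, 4), .draw(rg$mort$nursery, 4),
               .draw(rg$mort$growing, 4), .draw(rg$mort$finishing, 4),
               0, 0, 0, 0),
    stock = c(0, 0, 0, 0, dams_gest, dams_lact, gilts, boars),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "culls")
  culls <- data.frame(
    sex = c("female", "male"),
    Nherd = c(N, boars),
    txdesc = c(.draw(rg$culls$female_rate, 3), .draw(rg$culls$male_rate, 3)),
    Pdesc = c(.draw(rg$culls$female_kg, 1), .draw(rg$culls$male_kg, 1)),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "diets")
  # supply period (days/cycle) and kg/day typical of each phase
  feed_plan <- data.frame(
    category = phases$category, phase = phases$phase,
    Ta = c(24, 38, 45, 45, 7, 7, 7, 7),
    Qa = c(0.3, 0.8, 1.8, 2.8, 2.5, 6.0, 2.5, 2.5)
  )
  diets <- data.frame(
    category = feed_plan$category, phase = feed_plan$phase,
    Pa = .draw(rg$diets$price, 4, n = nrow(feed_plan)),
    Ta = feed_plan$Ta,
    Qa = round(feed_plan$Qa * stats::runif(nrow(feed_plan), 0.85, 1.15), 3),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "health")
  health <- data.frame(
    category = phases$category, phase = phases$phase,
    Pd = .draw(rg$health$price, 4, n = nrow(phases)),
    q = round(stats::runif(nrow(phases), rg$health$doses[1],
                           rg$health$doses[2])),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "repro")
  scenario <- c("on_farm", "purchased", "mixed")[1 + seed %% 3]
  semen <- data.frame(category = "dam", phase = "gestation",
                      source = "purchased",
                      Pr = .draw(rg$repro$semen, 2),
                      q = round(.draw(rg$repro$doses, 0)))
  onfarm <- data.frame(category = "boar", phase = "service",
                       source = "on_farm",
                       Pr = .draw(rg$repro$supplies, 2),
                       q = round(.draw(rg$repro$doses, 0)))
  supplies <- data.frame(category = "dam", phase = "gestation",
                         source = if (scenario == "on_farm") "on_farm" else "purchased",
                         Pr = .draw(rg$repro$supplies, 2),
                         q = round(.draw(rg$repro$doses, 0)))
  lines <- switch(scenario,
                  on_farm = rbind(onfarm, supplies),
                  purchased = rbind(semen, supplies),
                  mixed = rbind(semen, onfarm, supplies))
  repro <- list(scenario = scenario, lines = lines)

  .seed_stream(seed, "goods")
  n_goods <- round(.draw(rg$goods$n, 0))
  goods_pool <- c("gloves", "needles", "syringes", "marker sticks",
                  "rodent control", "fly control", "disinfectant",
                  "boots", "paper towels")
  consumer_goods <- data.frame(
    item = goods_pool[seq_len(n_goods)],
    Pb = .draw(rg$goods$price, 2, n = n_goods),
    Qb = .draw(rg$goods$qty, 1, n = n_goods),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "transport")
  transport <- list(Pt = .draw(rg$transport$Pt, 2),
                    Qt = round(.draw(rg$transport$Qt, 0)),
                    Txseg = .draw(rg$transport$Txseg, 5))

  .seed_stream(seed, "vtaxes")
  variable_taxes <- list(ICMS = round(N * .draw(rg$vtaxes$ICMS, 2), 2),
                         GTA = round(N * .draw(rg$vtaxes$GTA, 2), 2),
                         FUN = round(N * .draw(rg$vtaxes$FUN, 2), 2),
                         Otv = round(N * .draw(rg$vtaxes$Otv, 2), 2))

  .seed_stream(seed, "labor")
  n_emp <- max(1, round(N / .draw(rg$labor$sows_per_emp, 0)))
  labor <- data.frame(
    activity = c("management", "animal handling"),
    Sa = c(.draw(rg$labor$manager, 2), .draw(rg$labor$handler, 2)),
    Nca = c(1, max(0, n_emp - 1)),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "utilities")
  utilities <- list(Pe = .draw(rg$utilities$Pe, 4),
                    Qe = round(N * .draw(rg$utilities$kwh_per_sow, 2), 1),
                    Pt_phone = .draw(rg$utilities$phone, 2),
                    Pi_internet = .draw(rg$utilities$internet, 2),
                    share = .draw(rg$utilities$share, 2))

  .seed_stream(seed, "fuels")
  fuels <- data.frame(
    fuel = c("diesel", "gasoline"),
    Pcx = c(.draw(rg$fuels$diesel, 3), .draw(rg$fuels$gasoline, 3)),
    Qcx = c(round(N * .draw(rg$fuels$diesel_l, 3), 1),
            round(N * .draw(rg$fuels$gasoline_l, 3), 1)),
    share = .draw(rg$fuels$share, 2, n = 2),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "assets")
  assets <- data.frame(
    label = c("housing and facilities", "machinery and implements",
              "dams (biological)", "boars (biological)"),
    class = c("housing", "machinery", "biological", "biological"),
    Pc = c(round(N * .draw(rg$assets$housing_per_sow, 2), 2),
           round(N * .draw(rg$assets$machinery_per_sow, 2), 2),
           .draw(rg$assets$dam_price, 2), .draw(rg$assets$boar_price, 2)),
    Qc = c(1, 1, N, boars),
    txres = c(.draw(rg$assets$housing_res, 3), .draw(rg$assets$machinery_res, 3),
              .draw(rg$assets$bio_res, 3), .draw(rg$assets$bio_res, 3)),
    vu = c(round(.draw(rg$assets$housing_vu, 0)),
           round(.draw(rg$assets$machinery_vu, 0)),
           .draw(rg$assets$bio_vu, 1), .draw(rg$assets$bio_vu, 1)),
    txman = .draw(rg$assets$txman, 4, n = 4),
    stringsAsFactors = FALSE
  )

  .seed_stream(seed, "ftaxes")
  fixed_taxes <- list(ITR = .draw(rg$ftaxes$ITR, 2),
                      Txf = .draw(rg$ftaxes$Txf, 2),
                      Otf = .draw(rg$ftaxes$Otf, 2))

  .seed_stream(seed, "opportunity")
  opportunity <- list(trci = .draw(rg$opportunity$rate, 4),
                      trcg = .draw(rg$opportunity$rate, 4),
                      arr = round(N * .draw(rg$opportunity$ha_per_sow, 4), 2),
                      PATr = .draw(rg$opportunity$PATr, 2))

  .seed_stream(seed, "market")
  market <- list(Pvc = .draw(rg$market$Pvc, 2),
                 Pvd = .draw(rg$market$Pvd, 2),
                 beta = .draw(rg$market$beta, 2))

  farm_config(
    herd = list(N = N, ppa = ppa, txparto = txparto, Nnv = Nnv,
                kgcab = kgcab, phases = phases, culls = culls),
    diets = diets, health = health, repro = repro,
    consumer_goods = consumer_goods, transport = transport,
    variable_taxes = variable_taxes, labor = labor, utilities = utilities,
    fuels = fuels, assets = assets, fixed_taxes = fixed_taxes,
    opportunity = opportunity, market = market
  )
}
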