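# Farm configuration: construction, coercion from YAML/JSON + CSV registers,
# validation, serialization.

# Register column specifications: name -> c(type), "c" = character, "n" = numeric.
.register_cols <- list(
  phases         = c(category = "c", phase = "c", role = "c", txmort = "n", stock = "n"),
  culls          = c(sex = "c", Nherd = "n", txdesc = "n", Pdesc = "n"),
  diets          = c(category = "c", phase = "c", Pa = "n", Ta = "n", Qa = "n"),
  health         = c(category = "c", phase = "c", Pd = "n", q = "n"),
  repro_lines    = c(category = "c", phase = "c", source = "c", Pr = "n", q = "n"),
  consumer_goods = c(item = "c", Pb = "n", Qb = "n"),
  labor          = c(activity = "c", Sa = "n", Nca = "n"),
  fuels          = c(fuel = "c", Pcx = "n", Qcx = "n", share = "n"),
  assets         = c(label = "c", class = "c", Pc = "n", Qc = "n",
                     txres = "n", vu = "n", txman = "n")
)

.register_defaults <- list(
  phases = list(role = "growout", stock = 0, txmort = 0),
  fuels  = list(share = 1)
)

.empty_register <- function(name) {
  spec <- .register_cols[[name]]
  cols <- lapply(spec, function(t) if (t == "c") character(0) else numeric(0))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# Coerce a register given as a data.frame, a list of row-records, or a CSV
# file path (relative to `dir`) into a typed data.frame.
.as_register <- function(x, name, dir = ".", path = name) {
  spec <- .register_cols[[name]]
  if (is.null(x) || (is.list(x) && length(x) == 0L)) return(.empty_register(name))
  if (is.character(x) && length(x) == 1L && !is.null(dir)) {
    file <- if (file.exists(x)) x else file.path(dir, x)
    if (!file.exists(file))
      stop(sprintf("%s: register file not found: %s", path, x), call. = FALSE)
    x <- utils::read.csv(file, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) {
    # list of row-records (from YAML/JSON)
    rows <- lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE))
    x <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  defaults <- .register_defaults[[name]]
  for (col in names(spec)) {
    if (!col %in% names(x)) {
      if (!is.null(defaults) && col %in% names(defaults)) {
        x[[col]] <- defaults[[col]]
      } else {
        stop(sprintf("%s: missing required column '%s'", path, col), call. = FALSE)
      }
    }
    x[[col]] <- if (spec[[col]] == "c") as.character(x[[col]]) else as.numeric(x[[col]])
  }
  x[names(spec)]
}

.scalar_block <- function(x, fields, path) {
  out <- fields  # named list of defaults
  if (!is.null(x)) {
    bad <- setdiff(names(x), names(fields))
    if (length(bad))
      stop(sprintf("%s: unknown field(s): %s", path, paste(bad, collapse = ", ")),
           call. = FALSE)
    for (nm in names(x)) out[[nm]] <- as.numeric(x[[nm]])
  }
  out
}

#' Construct a farm configuration
#'
#' Assembles and type-checks the complete description of one full-cycle swine
#' farm: the herd (sows in production, farrowing performance, grow-out phases
#' with mortality, cull plan), the cost registers (diets, health, reproduction,
#' consumer goods, labor, fuels, capital assets), scalar cost blocks
#' (transport/insurance, taxes, utilities, opportunity rates) and market
#' prices. All registers may be empty; omitted scalar fields default to zero
#' (apportionment shares default to 1).
#'
#' Monetary values are in one undeclared currency unit, labelled by
#' `currency`; the engine is currency-agnostic.
#'
#' @param herd list with numeric `N` (sows in production), `ppa` (farrowings
#'   per sow per year), `txparto` (farrowing rate, fraction), `Nnv` (piglets
#'   born alive per farrowing), `kgcab` (live weight per finished pig, kg),
#'   `phases` (data.frame: `category`, `phase`, `role` in
#'   `"growout"`/`"breeding"`, `txmort`, `stock`) and `culls` (data.frame:
#'   `sex`, `Nherd`, `txdesc` annual rate, `Pdesc` cull weight kg).
#'   Grow-out phases are traversed in row order.
#' @param diets data.frame `category, phase, Pa, Ta, Qa`: diet price
#'   (currency/kg), supply period (days/cycle), amount fed (kg/day).
#' @param health data.frame `category, phase, Pd, q`: dose price, doses per
#'   animal per phase.
#' @param repro list with `scenario` (`"on_farm"`, `"purchased"` or
#'   `"mixed"`) and `lines` (data.frame `category, phase, source, Pr, q`):
#'   reproduction inputs consumed per female of the weekly group.
#' @param consumer_goods data.frame `item, Pb, Qb`: unit price and average
#'   monthly quantity.
#' @param transport list `Pt` (currency/km), `Qt` (km to slaughterhouse),
#'   `Txseg` (insurance rate on invested capital, fraction per batch).
#' @param variable_taxes list of annual amounts `ICMS, GTA, FUN, Otv`.
#' @param labor data.frame `activity, Sa, Nca`: monthly salary with charges,
#'   employee count.
#' @param utilities list `Pe` (currency/kWh), `Qe` (kWh/month), `Pt_phone`,
#'   `Pi_internet` (currency/month), `share` (swine-activity apportionment
#'   fraction, default 1).
#' @param fuels data.frame `fuel, Pcx, Qcx, share`: price per liter, liters
#'   per month, apportionment share (default 1).
#' @param assets data.frame `label, class, Pc, Qc, txres, vu, txman`: unit
#'   price, quantity, residual-value fraction, useful life (years), annual
#'   maintenance fraction. `class` is one of `housing`, `machinery`,
#'   `biological`.
#' @param fixed_taxes list of annual amounts `ITR, Txf, Otf`.
#' @param opportunity list `trci`, `trcg` (annual remuneration rates on fixed
#'   and working capital, fractions), `arr` (hectares used), `PATr` (lease
#'   price, currency/ha/year).
#' @param market list `Pvc` (market-pig price, currency/kg live), `Pvd`
#'   (cull price, currency/kg live), `beta` (producer/family labor
#'   remuneration, currency/week).
#' @param currency currency label (default `"BRL"`); informational only.
#' @return An object of class `farm_config`.
#' @seealso [load_farm_config()], [validate_config()], [compute_batch()],
#'   [generate_farm()]
#' @examples
#' cfg <- farm_config(
#'   herd = list(N = 100, ppa = 2.4, txparto = 0.9, Nnv = 12, kgcab = 115,
#'               phases = data.frame(category = "piglet", phase = "farrowing",
#'                                   role = "growout", txmort = 0.08, stock = 0),
#'               culls = data.frame(sex = "female", Nherd = 100,
#'                                  txdesc = 0.4, Pdesc = 220)),
#'   market = list(Pvc = 6, Pvd = 3.5, beta = 0))
#' cfg$herd$N
#' @export
farm_config <- function(herd,
                        diets = NULL, health = NULL, repro = NULL,
                        consumer_goods = NULL, transport = NULL,
                        variable_taxes = NULL, labor = NULL, utilities = NULL,
                        fuels = NULL, assets = NULL, fixed_taxes = NULL,
                        opportunity = NULL, market = NULL,
                        currency = "BRL") {
  if (missing(herd) || is.null(herd)) stop("herd: required", call. = FALSE)
  for (f in c("N", "ppa", "txparto", "Nnv", "kgcab"))
    if (is.null(herd[[f]])) stop(sprintf("herd.%s: required", f), call. = FALSE)
  h <- list(
    N = as.numeric(herd$N), ppa = as.numeric(herd$ppa),
    txparto = as.numeric(herd$txparto), Nnv = as.numeric(herd$Nnv),
    kgcab = as.numeric(herd$kgcab),
    phases = .as_register(herd$phases, "phases", dir = NULL, path = "herd.phases"),
    culls  = .as_register(herd$culls, "culls", dir = NULL, path = "herd.culls")
  )
  rp <- list(scenario = "purchased", lines = .empty_register("repro_lines"))
  if (!is.null(repro)) {
    if (!is.null(repro$scenario)) rp$scenario <- as.character(repro$scenario)
    rp$lines <- .as_register(repro$lines, "repro_lines", dir = NULL,
                             path = "repro.lines")
  }
  cfg <- structure(list(
    currency = as.character(currency),
    herd = h,
    diets = .as_register(diets, "diets", dir = NULL, path = "diets"),
    health = .as_register(health, "health", dir = NULL, path = "health"),
    repro = rp,
    consumer_goods = .as_register(consumer_goods, "consumer_goods", dir = NULL,
                                  path = "consumer_goods"),
    transport = .scalar_block(transport, list(Pt = 0, Qt = 0, Txseg = 0),
                              "transport"),
    variable_taxes = .scalar_block(variable_taxes,
                                   list(ICMS = 0, GTA = 0, FUN = 0, Otv = 0),
                                   "variable_taxes"),
    labor = .as_register(labor, "labor", dir = NULL, path = "labor"),
    utilities = .scalar_block(utilities,
                              list(Pe = 0, Qe = 0, Pt_phone = 0,
                                   Pi_internet = 0, share = 1),
                              "utilities"),
    fuels = .as_register(fuels, "fuels", dir = NULL, path = "fuels"),
    assets = .as_register(assets, "assets", dir = NULL, path = "assets"),
    fixed_taxes = .scalar_block(fixed_taxes, list(ITR = 0, Txf = 0, Otf = 0),
                                "fixed_taxes"),
    opportunity = .scalar_block(opportunity,
                                list(trci = 0, trcg = 0, arr = 0, PATr = 0),
                                "opportunity"),
    market = .scalar_block(market, list(Pvc = 0, Pvd = 0, beta = 0), "market")
  ), class = "farm_config")
  cfg
}

#' Load a farm configuration from a YAML or JSON file
#'
#' Reads a structured configuration file, resolves any tabular registers given
#' as CSV file paths (relative to the configuration file), applies defaults,
#' and validates. Validation errors (not warnings) abort the load with a
#' message naming the offending key path.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated [farm_config] object.
#' @seealso [write_farm_config()] for the inverse; [validate_config()].
#' @export
load_farm_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported configuration format: .", ext,
         " (expected .yaml, .yml or .json)", call. = FALSE)
  )
  cfg <- .raw_to_config(raw, dir = dirname(path))
  findings <- validate_config(cfg)
  errs <- findings[findings$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("invalid farm configuration:\n",
         paste0("  ", errs$path, ": ", errs$message, collapse = "\n"),
         call. = FALSE)
  cfg
}

# Build a farm_config from a raw parsed list, resolving CSV register paths.
.raw_to_config <- function(raw, dir = ".") {
  resolve <- function(x, name, path) .as_register(x, name, dir = dir, path = path)
  herd <- raw$herd
  if (is.null(herd)) stop("herd: required", call. = FALSE)
  herd$phases <- resolve(herd$phases, "phases", "herd.phases")
  herd$culls <- resolve(herd$culls, "culls", "herd.culls")
  repro <- raw$repro
  if (!is.null(repro))
    repro$lines <- resolve(repro$lines, "repro_lines", "repro.lines")
  farm_config(
    herd = herd,
    diets = resolve(raw$diets, "diets", "diets"),
    health = resolve(raw$health, "health", "health"),
    repro = repro,
    consumer_goods = resolve(raw$consumer_goods, "consumer_goods", "consumer_goods"),
    transport = raw$transport,
    variable_taxes = raw$variable_taxes,
    labor = resolve(raw$labor, "labor", "labor"),
    utilities = raw$utilities,
    fuels = resolve(raw$fuels, "fuels", "fuels"),
    assets = resolve(raw$assets, "assets", "assets"),
    fixed_taxes = raw$fixed_taxes,
    opportunity = raw$opportunity,
    market = raw$market,
    currency = if (is.null(raw$currency)) "BRL" else raw$currency
  )
}

.df_to_records <- function(df) {
  if (nrow(df) == 0L) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Serialize a farm configuration to YAML or JSON
#'
#' Writes the configuration as a single self-contained file with inline
#' registers, at 15 significant digits so that a load/write/load cycle
#' reproduces the configuration field-by-field.
#'
#' @param cfg a [farm_config].
#' @param path output file path; extension selects the format unless `format`
#'   is given.
#' @param format `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_farm_config <- function(cfg, path,
                              format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "yaml"
  }
  raw <- list(
    currency = cfg$currency,
    herd = list(N = cfg$herd$N, ppa = cfg$herd$ppa, txparto = cfg$herd$txparto,
                Nnv = cfg$herd$Nnv, kgcab = cfg$herd$kgcab,
                phases = .df_to_records(cfg$herd$phases),
                culls = .df_to_records(cfg$herd$culls)),
    diets = .df_to_records(cfg$diets),
    health = .df_to_records(cfg$health),
    repro = list(scenario = cfg$repro$scenario,
                 lines = .df_to_records(cfg$repro$lines)),
    consumer_goods = .df_to_records(cfg$consumer_goods),
    transport = cfg$transport,
    variable_taxes = cfg$variable_taxes,
    labor = .df_to_records(cfg$labor),
    utilities = cfg$utilities,
    fuels = .df_to_records(cfg$fuels),
    assets = .df_to_records(cfg$assets),
    fixed_taxes = cfg$fixed_taxes,
    opportunity = cfg$opportunity,
    market = cfg$market
  )
  if (format == "yaml") {
    writeLines(yaml::as.yaml(raw, precision = 15), path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.farm_config <- function(x, ...) {
  cat("Full-cycle farm configuration (", x$currency, ")\n", sep = "")
  cat(sprintf("  herd: %g sows, %g farrowings/sow/yr, farrowing rate %g, %g born alive, %g kg/finished pig\n",
              x$herd$N, x$herd$ppa, x$herd$txparto, x$herd$Nnv, x$herd$kgcab))
  cat(sprintf("  phases: %d (%d grow-out) | culls: %d | diets: %d | health: %d | repro (%s): %d\n",
              nrow(x$herd$phases),
              sum(x$herd$phases$role == "growout"),
              nrow(x$herd$culls), nrow(x$diets), nrow(x$health),
              x$repro$scenario, nrow(x$repro$lines)))
  cat(sprintf("  consumer goods: %d | labor: %d | fuels: %d | assets: %d\n",
              nrow(x$consumer_goods), nrow(x$labor), nrow(x$fuels),
              nrow(x$assets)))
  cat(sprintf("  market: %g/kg live (culls %g/kg); opportunity rates %g / %g per yr\n",
              x$market$Pvc, x$market$Pvd, x$opportunity$trci, x$opportunity$trcg))
  invisible(x)
}

.finding <- function(path, severity, message) {
  data.frame(path = path, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a farm configuration
#'
#' Checks all model invariants and returns a data.frame of findings rather
#' than raising conditions: monetary values and quantities must be
#' non-negative; mortality, farrowing, culling, residual-value and
#' apportionment fractions must lie in `[0, 1]`; asset useful lives must be
#' positive; every diet and health line must reference a `(category, phase)`
#' pair present in the herd; reproduction lines must be consistent with the
#' declared scenario. Annual capital remuneration rates above 1 (100 %/yr)
#' are flagged as warnings, not errors.
#'
#' @param cfg a [farm_config].
#' @return data.frame with columns `path`, `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows when the configuration is valid.
#' @export
validate_config <- function(cfg) {
  out <- list()
  add <- function(path, severity, message)
    out[[length(out) + 1L]] <<- .finding(path, severity, message)

  chk_nonneg <- function(value, path) {
    if (any(!is.finite(value)))
      add(path, "error", "must be a finite number")
    else if (any(value < 0))
      add(path, "error", sprintf("must be >= 0 (got %g)", min(value)))
  }
  chk_frac <- function(value, path, open_top = FALSE) {
    if (any(!is.finite(value))) {
      add(path, "error", "must be a finite number")
    } else if (any(value < 0) || any(value > 1) ||
               (open_top && any(value >= 1))) {
      add(path, "error",
          sprintf("must be a fraction in [0, 1%s] (got %g)",
                  if (open_top) ")" else "", value[which.max(abs(value - 0.5))]))
    }
  }

  h <- cfg$herd
  chk_nonneg(h$N, "herd.N")
  if (!is.finite(h$ppa) || h$ppa <= 0) add("herd.ppa", "error", "must be > 0")
  if (!is.finite(h$txparto) || h$txparto <= 0 || h$txparto > 1)
    add("herd.txparto", "error", "farrowing rate must be in (0, 1]")
  chk_nonneg(h$Nnv, "herd.Nnv")
  if (!is.finite(h$kgcab) || h$kgcab <= 0)
    add("herd.kgcab", "error", "finished-pig weight must be > 0")

  ph <- h$phases
  if (nrow(ph) > 0L) {
    key <- paste(ph$category, ph$phase, sep = "/")
    if (anyDuplicated(key))
      add("herd.phases", "error",
          sprintf("duplicate (category, phase): %s", key[duplicated(key)][1L]))
    for (i in seq_len(nrow(ph))) {
      chk_frac(ph$txmort[i], sprintf("herd.phases[%d].txmort", i),
               open_top = TRUE)
      chk_nonneg(ph$stock[i], sprintf("herd.phases[%d].stock", i))
      if (!ph$role[i] %in% c("growout", "breeding"))
        add(sprintf("herd.phases[%d].role", i), "error",
            "must be 'growout' or 'breeding'")
    }
  }
  cu <- h$culls
  for (i in seq_len(nrow(cu))) {
    if (!cu$sex[i] %in% c("female", "male"))
      add(sprintf("herd.culls[%d].sex", i), "error", "must be 'female' or 'male'")
    chk_nonneg(cu$Nherd[i], sprintf("herd.culls[%d].Nherd", i))
    chk_frac(cu$txdesc[i], sprintf("herd.culls[%d].txdesc", i))
    if (!is.finite(cu$Pdesc[i]) || cu$Pdesc[i] <= 0)
      add(sprintf("herd.culls[%d].Pdesc", i), "error",
          "cull weight must be > 0")
  }

  herd_key <- paste(ph$category, ph$phase, sep = "/")
  chk_ref <- function(df, reg) {
    if (nrow(df) == 0L) return()
    key <- paste(df$category, df$phase, sep = "/")
    bad <- which(!key %in% herd_key)
    for (i in bad)
      add(sprintf("%s[%d]", reg, i), "error",
          sprintf("references unknown (category, phase): %s", key[i]))
  }
  chk_ref(cfg$diets, "diets")
  chk_ref(cfg$health, "health")
  for (i in seq_len(nrow(cfg$diets))) {
    chk_nonneg(cfg$diets$Pa[i], sprintf("diets[%d].Pa", i))
    chk_nonneg(cfg$diets$Ta[i], sprintf("diets[%d].Ta", i))
    chk_nonneg(cfg$diets$Qa[i], sprintf("diets[%d].Qa", i))
  }
  for (i in seq_len(nrow(cfg$health))) {
    chk_nonneg(cfg$health$Pd[i], sprintf("health[%d].Pd", i))
    chk_nonneg(cfg$health$q[i], sprintf("health[%d].q", i))
  }

  rp <- cfg$repro
  if (!rp$scenario %in% c("on_farm", "purchased", "mixed"))
    add("repro.scenario", "error",
        "must be 'on_farm', 'purchased' or 'mixed'")
  for (i in seq_len(nrow(rp$lines))) {
    src <- rp$lines$source[i]
    if (!src %in% c("on_farm", "purchased"))
      add(sprintf("repro.lines[%d].source", i), "error",
          "must be 'on_farm' or 'purchased'")
    else if (rp$scenario != "mixed" && src != rp$scenario)
      add(sprintf("repro.lines[%d].source", i), "error",
          sprintf("scenario is '%s' but line source is '%s'",
                  rp$scenario, src))
    chk_nonneg(rp$lines$Pr[i], sprintf("repro.lines[%d].Pr", i))
    chk_nonneg(rp$lines$q[i], sprintf("repro.lines[%d].q", i))
  }

  for (i in seq_len(nrow(cfg$consumer_goods))) {
    chk_nonneg(cfg$consumer_goods$Pb[i], sprintf("consumer_goods[%d].Pb", i))
    chk_nonneg(cfg$consumer_goods$Qb[i], sprintf("consumer_goods[%d].Qb", i))
  }
  chk_nonneg(cfg$transport$Pt, "transport.Pt")
  chk_nonneg(cfg$transport$Qt, "transport.Qt")
  chk_frac(cfg$transport$Txseg, "transport.Txseg")
  for (f in names(cfg$variable_taxes))
    chk_nonneg(cfg$variable_taxes[[f]], paste0("variable_taxes.", f))
  for (i in seq_len(nrow(cfg$labor))) {
    chk_nonneg(cfg$labor$Sa[i], sprintf("labor[%d].Sa", i))
    chk_nonneg(cfg$labor$Nca[i], sprintf("labor[%d].Nca", i))
  }
  chk_nonneg(cfg$utilities$Pe, "utilities.Pe")
  chk_nonneg(cfg$utilities$Qe, "utilities.Qe")
  chk_nonneg(cfg$utilities$Pt_phone, "utilities.Pt_phone")
  chk_nonneg(cfg$utilities$Pi_internet, "utilities.Pi_internet")
  chk_frac(cfg$utilities$share, "utilities.share")
  for (i in seq_len(nrow(cfg$fuels))) {
    chk_nonneg(cfg$fuels$Pcx[i], sprintf("fuels[%d].Pcx", i))
    chk_nonneg(cfg$fuels$Qcx[i], sprintf("fuels[%d].Qcx", i))
    chk_frac(cfg$fuels$share[i], sprintf("fuels[%d].share", i))
  }
  for (i in seq_len(nrow(cfg$assets))) {
    chk_nonneg(cfg$assets$Pc[i], sprintf("assets[%d].Pc", i))
    chk_nonneg(cfg$assets$Qc[i], sprintf("assets[%d].Qc", i))
    chk_frac(cfg$assets$txres[i], sprintf("assets[%d].txres", i),
             open_top = TRUE)
    if (!is.finite(cfg$assets$vu[i]) || cfg$assets$vu[i] <= 0)
      add(sprintf("assets[%d].vu", i), "error",
          "useful life must be > 0 years")
    chk_nonneg(cfg$assets$txman[i], sprintf("assets[%d].txman", i))
  }
  for (f in names(cfg$fixed_taxes))
    chk_nonneg(cfg$fixed_taxes[[f]], paste0("fixed_taxes.", f))
  op <- cfg$opportunity
  chk_nonneg(op$trci, "opportunity.trci")
  chk_nonneg(op$trcg, "opportunity.trcg")
  chk_nonneg(op$arr, "opportunity.arr")
  chk_nonneg(op$PATr, "opportunity.PATr")
  if (is.finite(op$trci) && op$trci > 1)
    add("opportunity.trci", "warning",
        "annual rate exceeds 1 (100%/yr); check units")
  if (is.finite(op$trcg) && op$trcg > 1)
    add("opportunity.trcg", "warning",
        "annual rate exceeds 1 (100%/yr); check units")
  chk_nonneg(cfg$market$Pvc, "market.Pvc")
  chk_nonneg(cfg$market$Pvd, "market.Pvd")
  chk_nonneg(cfg$market$beta, "market.beta")

  if (length(out) == 0L)
    return(.finding(character(0), character(0), character(0))[0, ])
  do.call(rbind, out)
}

#' Scale every monetary value in a configuration
#'
#' Multiplies all prices, salaries, tax amounts, lease price and the producer
#' remuneration by `k`, leaving quantities, rates and the herd untouched.
#' Because every cost line is linear in exactly one monetary input, the whole
#' ledger (CV, CFOP, CO, CT) scales by the same factor — useful for currency
#' re-basing and sensitivity sweeps.
#'
#' @param cfg a [farm_config].
#' @param k non-negative scale factor.
#' @return A new `farm_config`.
#' @export
scale_prices <- function(cfg, k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  cfg$diets$Pa <- cfg$diets$Pa * k
  cfg$health$Pd <- cfg$health$Pd * k
  cfg$repro$lines$Pr <- cfg$repro$lines$Pr * k
  cfg$consumer_goods$Pb <- cfg$consumer_goods$Pb * k
  cfg$transport$Pt <- cfg$transport$Pt * k
  for (f in names(cfg$variable_taxes))
    cfg$variable_taxes[[f]] <- cfg$variable_taxes[[f]] * k
  cfg$labor$Sa <- cfg$labor$Sa * k
  cfg$utilities$Pe <- cfg$utilities$Pe * k
  cfg$utilities$Pt_phone <- cfg$utilities$Pt_phone * k
  cfg$utilities$Pi_internet <- cfg$utilities$Pi_internet * k
  cfg$fuels$Pcx <- cfg$fuels$Pcx * k
  cfg$assets$Pc <- cfg$assets$Pc * k
  for (f in names(cfg$fixed_taxes))
    cfg$fixed_taxes[[f]] <- cfg$fixed_taxes[[f]] * k
  cfg$opportunity$PATr <- cfg$opportunity$PATr * k
  cfg$market$Pvc <- cfg$market$Pvc * k
  cfg$market$Pvd <- cfg$market$Pvd * k
  cfg$market$beta <- cfg$market$beta * k
  cfg
}
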