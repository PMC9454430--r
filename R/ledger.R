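# Ledger assembly: every cost line item in the allocation order
# A (variable) / B (fixed operating) / C (operating = A + B) /
# D (opportunity) / E (total = C + D), plus the batch report.

.ledger_row <- function(group, section, item, value) {
  data.frame(group = group, section = section, item = item, value = value,
             stringsAsFactors = FALSE)
}

#' Compute the weekly cost ledger for a farm
#'
#' Runs every cost module against the batch flow and assembles the
#' hierarchical ledger: individual line items tagged with their allocation
#' group (`A` variable, `B` fixed operating, `D` opportunity) and section,
#' plus the full set of named subtotals (CTA, CTS, CTR, CTB, CTC, CTtaseg,
#' CTdfv, CV; CTMO, CTE, CTTI, CTG, CTDep, CTMan, CTdff, CFOP; RCI, RCG,
#' RCT, CO; COP, CT).
#'
#' @param cfg a [farm_config].
#' @param flow optional [compute_batch_flow()] result (recomputed if NULL).
#' @param tb [time_basis()].
#' @return object of class `cost_ledger`: a data.frame of line items
#'   (`group`, `section`, `item`, `value`) with a `subtotals` attribute
#'   (named list).
#' @export
compute_ledger <- function(cfg, flow = NULL, tb = time_basis()) {
  if (is.null(flow)) flow <- compute_batch_flow(cfg, tb)

  feed <- feed_costs(cfg$diets, flow$pop)
  health <- health_costs(cfg$health, flow$pop)
  repro <- repro_costs(cfg$repro, flow$GS)
  goods <- consumer_goods_costs(cfg$consumer_goods, tb)
  CTC <- raising_subtotal(feed$total, health$total, repro$total, goods$total)
  taseg <- transport_insurance(cfg$transport, flow$Ntl, cfg$herd$kgcab,
                               cfg$market$Pvc)
  CTdfv <- variable_financial(cfg$variable_taxes, tb)
  CV <- total_variable(CTC, taseg$total, CTdfv)

  labor <- labor_costs(cfg$labor, tb)
  util <- utility_costs(cfg$utilities, tb)
  fuel <- fuel_costs(cfg$fuels, tb)
  dep <- depreciation_costs(cfg$assets, tb)
  man <- maintenance_costs(cfg$assets, tb)
  CTdff <- fixed_financial(cfg$fixed_taxes, tb)
  CFOP <- total_fixed(labor$total, util$CTE, util$CTTI, fuel$total,
                      dep$total, man$total, CTdff)

  RCI <- fixed_capital_remuneration(cfg$assets, cfg$opportunity$trci, tb)
  RCG <- working_capital_remuneration(CTC, cfg$opportunity$trcg, tb)
  RCT <- land_remuneration(cfg$opportunity$arr, cfg$opportunity$PATr, tb)
  CO <- total_opportunity(RCI, RCG, RCT)

  tot <- total_cost(CV, CFOP, CO)

  vt <- cfg$variable_taxes
  ft <- cfg$fixed_taxes
  rows <- rbind(
    if (nrow(feed$lines))
      .ledger_row("A", "Feed", paste0("Feed ", feed$lines$category, "/",
                                      feed$lines$phase), feed$lines$CCA),
    if (nrow(health$lines))
      .ledger_row("A", "Veterinary", paste0("Health ", health$lines$category,
                                            "/", health$lines$phase),
                  health$lines$CS),
    if (nrow(repro$lines))
      .ledger_row("A", "Reproduction",
                  paste0("Repro [", repro$lines$source, "] ",
                         repro$lines$category, "/", repro$lines$phase),
                  repro$lines$CR),
    if (nrow(goods$lines))
      .ledger_row("A", "Consumer goods", goods$lines$item, goods$lines$CB),
    .ledger_row("A", "Transport and insurance", "Transport to slaughterhouse",
                taseg$Cta),
    .ledger_row("A", "Transport and insurance", "Batch insurance", taseg$Cseg),
    .ledger_row("A", "Variable taxes and fees",
                c("ICMS", "GTA", "Funrural", "Other variable"),
                c(vt$ICMS, vt$GTA, vt$FUN, vt$Otv) / tb$phi),
    if (nrow(labor$lines))
      .ledger_row("B", "Manpower", labor$lines$activity, labor$lines$CMO),
    .ledger_row("B", "Utilities", c("Telephone and internet", "Electricity"),
                c(util$CTTI, util$CTE)),
    if (nrow(fuel$lines))
      .ledger_row("B", "Fuel", fuel$lines$fuel, fuel$lines$CC / tb$omega),
    if (nrow(dep$lines))
      .ledger_row("B", "Depreciation",
                  paste0("Depreciation ", dep$lines$label),
                  dep$lines$CDep / tb$phi),
    if (nrow(man$lines))
      .ledger_row("B", "Maintenance",
                  paste0("Maintenance ", man$lines$label),
                  man$lines$Cman / tb$phi),
    .ledger_row("B", "Fixed taxes and fees",
                c("ITR", "Fixed fees", "Other fixed"),
                c(ft$ITR, ft$Txf, ft$Otf) / tb$phi),
    .ledger_row("D", "Opportunity cost of capital and land",
                c("Remuneration on fixed capital",
                  "Remuneration on working capital",
                  "Opportunity cost of land lease"),
                c(RCI, RCG, RCT))
  )
  structure(rows, class = c("cost_ledger", "data.frame"),
            subtotals = list(
              CTA = feed$total, CTS = health$total, CTR = repro$total,
              CTB = goods$total, CTC = CTC,
              Cta = taseg$Cta, Cseg = taseg$Cseg, CTtaseg = taseg$total,
              CTdfv = CTdfv, CV = CV,
              CTMO = labor$total, CTE = util$CTE, CTTI = util$CTTI,
              CTG = fuel$total, CTDep = dep$total, CTMan = man$total,
              CTdff = CTdff, CFOP = CFOP,
              RCI = RCI, RCG = RCG, RCT = RCT, CO = CO,
              COP = tot$COP, CT = tot$CT))
}

#' Named subtotals of a cost ledger
#'
#' @param ledger a [compute_ledger()] result.
#' @return named list of subtotals (CTA ... CT).
#' @export
ledger_subtotals <- function(ledger) {
  attr(ledger, "subtotals")
}

#' Compute the full weekly batch: flow, ledger and economic report
#'
#' The main entry point: derives the batch flow, assembles the cost ledger
#' and computes the indicator suite for one farm configuration. Undefined
#' averages (unit costs or per-head revenue when no head is finished, ratio
#' indicators when total cost is zero) are stored as `NA` with a warning so
#' that the ledger of a degenerate configuration is still returned; the
#' underlying operations ([unit_costs()], [revenue()], [profitability()])
#' raise errors when called directly.
#'
#' @param cfg a [farm_config].
#' @param tb [time_basis()].
#' @return object of class `pigcost_batch`: list with `config`, `flow`
#'   (`batch_flow`), `ledger` (`cost_ledger`) and `report` (`batch_report`,
#'   a named list: `GS`, `Ntl`, `theta`, `CV`, `CFOP`, `COP`, `CO`, `CT`,
#'   `CTcab`, `CTarroba`, `CTkg`, `Rs`, `Rcab`, `Rkg`, `L`, `PN`, `RBC`,
#'   `ROI`, `RTs`, `RTkg`).
#' @examples
#' cfg <- generate_farm(scenario_spec(seed = 1, size_class = "small"))
#' batch <- compute_batch(cfg)
#' batch$report$CT        # total weekly cost
#' batch$report$CTarroba  # cost per arroba (18.75 kg)
#' @export
compute_batch <- function(cfg, tb = time_basis()) {
  flow <- compute_batch_flow(cfg, tb)
  ledger <- compute_ledger(cfg, flow, tb)
  s <- ledger_subtotals(ledger)

  uc <- tryCatch(unit_costs(s$CT, flow$Ntl, cfg$herd$kgcab, tb),
                 error = function(e) {
                   warning(conditionMessage(e), call. = FALSE)
                   list(CTcab = NA_real_, CTarroba = NA_real_, CTkg = NA_real_)
                 })
  rv <- tryCatch(revenue(flow$theta, flow$cull_kg, cfg$market, flow$Ntl),
                 error = function(e) {
                   warning(conditionMessage(e), call. = FALSE)
                   Rs <- flow$theta * cfg$market$Pvc +
                     sum(flow$cull_kg * cfg$market$Pvd)
                   list(Rs = Rs, Rcab = NA_real_, Rkg = NA_real_)
                 })
  pf <- if (s$CT > 0) {
    profitability(rv$Rs, s$CT, cfg$market$Pvc, cfg$herd$kgcab)
  } else {
    if (rv$Rs > 0)
      warning("ratio indicators undefined: total cost is zero",
              call. = FALSE)
    list(L = rv$Rs - s$CT, PN = NA_real_, RBC = NA_real_, ROI = NA_real_)
  }
  RTs <- producer_income(pf$L, s$CO, cfg$market$beta)

  report <- structure(list(
    GS = flow$GS, Ntl = flow$Ntl, theta = flow$theta,
    CV = s$CV, CFOP = s$CFOP, COP = s$COP, CO = s$CO, CT = s$CT,
    CTcab = uc$CTcab, CTarroba = uc$CTarroba, CTkg = uc$CTkg,
    Rs = rv$Rs, Rcab = rv$Rcab, Rkg = rv$Rkg,
    L = pf$L, PN = pf$PN, RBC = pf$RBC, ROI = pf$ROI,
    RTs = RTs,
    RTkg = if (flow$theta > 0) RTs / flow$theta else NA_real_
  ), class = "batch_report")

  structure(list(config = cfg, flow = flow, ledger = ledger,
                 report = report),
            class = "pigcost_batch")
}

# Flat table of the report in Table-1 order: line items, subtotals A..E,
# then unit costs and indicators. Used by the csv/text renderers.
.report_table <- function(report, ledger) {
  s <- ledger_subtotals(ledger)
  df <- as.data.frame(ledger)
  grp <- function(g) df[df$group == g, , drop = FALSE]
  sub <- function(group, item, value) .ledger_row(group, "subtotal", item, value)
  ind <- function(item, value) .ledger_row("R", "indicators", item, value)
  rbind(
    grp("A"),
    sub("A", "Subtotal animal costing (CTC)", s$CTC),
    sub("A", "A - Variable costs (CV)", s$CV),
    grp("B"),
    sub("B", "B - Fixed operating costs (CFOP)", s$CFOP),
    sub("C", "C - Operating cost (COP = A + B)", s$COP),
    grp("D"),
    sub("D", "D - Capital and land remuneration cost (CO)", s$CO),
    sub("E", "E - Total cost (CT = C + D)", s$CT),
    ind(c("Finished head (Ntl)", "Batch live weight kg (theta)",
          "Cost per head (CTcab)", "Cost per arroba (CTarroba)",
          "Cost per kg (CTkg)", "Revenue (Rs)", "Revenue per head (Rcab)",
          "Revenue per kg (Rkg)", "Profit (L)", "Leveling point head (PN)",
          "Benefit-cost ratio (RBC)", "Return on investment % (ROI)",
          "Producer total income (RTs)", "Producer income per kg (RTkg)"),
        c(report$Ntl, report$theta, report$CTcab, report$CTarroba,
          report$CTkg, report$Rs, report$Rcab, report$Rkg, report$L,
          report$PN, report$RBC, 100 * report$ROI, report$RTs, report$RTkg))
  )
}

#' Write a batch report to disk
#'
#' Emits every ledger line item with its group subtotal in the allocation
#' order A, B, C, D, E, followed by the unit costs and economic indicators.
#' `csv` and `json` carry full precision and round-trip exactly; `text` is a
#' human-readable statement rounded to 2 decimals (ROI shown as a
#' percentage).
#'
#' @param report `batch_report` from [compute_batch()].
#' @param ledger matching `cost_ledger`.
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"text"`.
#' @param currency currency label printed by the text format.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, ledger, path,
                         format = c("csv", "json", "text"),
                         currency = "BRL") {
  format <- match.arg(format)
  tab <- .report_table(report, ledger)
  if (format == "csv") {
    out <- tab
    out$value <- sprintf("%.17g", out$value)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else if (format == "json") {
    jsonlite::write_json(
      list(subtotals = ledger_subtotals(ledger),
           lines = as.data.frame(ledger),
           report = unclass(report)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("Weekly swine production cost report (%s)", currency)
    w("%s", strrep("=", 60))
    last_group <- ""
    labels <- c(A = "A - Variable costs", B = "B - Fixed operating costs",
                C = "C - Operating cost", D = "D - Opportunity costs",
                E = "E - Total cost", R = "Economic indicators")
    for (i in seq_len(nrow(tab))) {
      g <- tab$group[i]
      if (g != last_group && g %in% c("A", "B", "D", "R")) {
        w("%s", labels[[g]])
        last_group <- g
      }
      indent <- if (tab$section[i] == "subtotal") "  " else "    "
      w("%s%-46s %14.2f", indent, tab$item[i], tab$value[i])
    }
    w("%s", strrep("=", 60))
  }
  invisible(path)
}

#' @export
print.batch_report <- function(x, ...) {
  cat("Weekly batch report\n")
  cat(sprintf("  GS %.3f sows/wk | Ntl %.2f head | theta %.1f kg\n",
              x$GS, x$Ntl, x$theta))
  cat(sprintf("  CV %.2f + CFOP %.2f = COP %.2f; + CO %.2f = CT %.2f\n",
              x$CV, x$CFOP, x$COP, x$CO, x$CT))
  cat(sprintf("  unit cost: %.2f/head, %.2f/arroba, %.4f/kg\n",
              x$CTcab, x$CTarroba, x$CTkg))
  cat(sprintf("  revenue %.2f (%.2f/head, %.4f/kg); profit %.2f\n",
              x$Rs, x$Rcab, x$Rkg, x$L))
  cat(sprintf("  PN %.2f head | RBC %.4f | ROI %.2f%% | RTs %.2f (%.4f/kg)\n",
              x$PN, x$RBC, 100 * x$ROI, x$RTs, x$RTkg))
  invisible(x)
}

#' @export
print.pigcost_batch <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @export
print.cost_ledger <- function(x, ...) {
  s <- attr(x, "subtotals")
  cat(sprintf("Cost ledger: %d line items | CV %.2f | CFOP %.2f | CO %.2f | CT %.2f\n",
              nrow(x), s$CV, s$CFOP, s$CO, s$CT))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
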