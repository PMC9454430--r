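# Groups C and E of the ledger plus the economic indicator suite.

#' Operating and total cost
#'
#' `COP = CV + CFOP` (group C, operating cost) and `CT = COP + CO` (group E,
#' total cost).
#'
#' @param CV total variable cost (group A).
#' @param CFOP total fixed operating cost (group B).
#' @param CO total opportunity cost (group D).
#' @return list `COP`, `CT`.
#' @export
total_cost <- function(CV, CFOP, CO) {
  COP <- CV + CFOP
  list(COP = COP, CT = COP + CO)
}

#' Unit costs of the finished pig
#'
#' `CTcab = CT / Ntl` (per head), `CTkg = CT / (Ntl * kgcab)` (per kg live
#' weight) and `CTarroba = CT / ((Ntl * kgcab) / 18.75)` (per arroba), so
#' that `CTarroba = 18.75 * CTkg` always.
#'
#' When `CT` is zero all unit costs are zero; a positive `CT` with no
#' finished head is an error (the unit cost is undefined), never a silent
#' infinity.
#'
#' @param CT total weekly cost.
#' @param Ntl finished head count.
#' @param kgcab live weight per finished pig (kg).
#' @param tb [time_basis()] (supplies the arroba constant).
#' @return list `CTcab`, `CTarroba`, `CTkg`.
#' @export
unit_costs <- function(CT, Ntl, kgcab, tb = time_basis()) {
  if (CT == 0)
    return(list(CTcab = 0, CTarroba = 0, CTkg = 0))
  if (Ntl <= 0 || kgcab <= 0)
    stop("unit costs undefined: no finished live weight (Ntl = ", Ntl,
         ", kgcab = ", kgcab, ") against a positive total cost", call. = FALSE)
  CTkg <- CT / (Ntl * kgcab)
  list(CTcab = CT / Ntl, CTarroba = tb$arroba_kg * CTkg, CTkg = CTkg)
}

#' Weekly revenue
#'
#' `Rs = theta * Pvc + sum(cull_kg) * Pvd`: market pigs at the live-weight
#' market price plus cull animals at the cull price. Averages
#' `Rcab = Rs / Ntl` and `Rkg = Rs / theta` are returned alongside; a
#' nonzero revenue with a zero denominator is an error.
#'
#' @param theta batch live weight (kg).
#' @param cull_kg weekly cull weight per sex (kg), from
#'   [weekly_cull_weight()].
#' @param market list `Pvc`, `Pvd` (see [farm_config()]).
#' @param Ntl finished head count (for the per-head average).
#' @return list `Rs`, `Rcab`, `Rkg`.
#' @export
revenue <- function(theta, cull_kg, market, Ntl) {
  Rs <- theta * market$Pvc + sum(cull_kg * market$Pvd)
  if (Rs == 0)
    return(list(Rs = 0, Rcab = 0, Rkg = 0))
  if (Ntl <= 0 || theta <= 0)
    stop("average revenue undefined: nonzero revenue with Ntl = ", Ntl,
         ", theta = ", theta, call. = FALSE)
  list(Rs = Rs, Rcab = Rs / Ntl, Rkg = Rs / theta)
}

#' Profit, leveling point, benefit-cost ratio and return on investment
#'
#' `L = Rs - CT`; the leveling point `PN = CT / (Pvc * kgcab)` is the
#' break-even output in head — the minimum number of market pigs (at the
#' current price and weight, culls excluded) whose sale covers the total
#' cost; `RBC = Rs / CT` is revenue per unit of cost and `ROI = L / CT`
#' (a fraction; multiply by 100 for the percentage the report prints).
#' `ROI = RBC - 1` identically.
#'
#' @param Rs weekly revenue.
#' @param CT total weekly cost (> 0 for the ratio indicators).
#' @param Pvc market price (currency/kg live).
#' @param kgcab live weight per finished pig (kg).
#' @return list `L`, `PN`, `RBC`, `ROI`.
#' @export
profitability <- function(Rs, CT, Pvc, kgcab) {
  if (CT <= 0)
    stop("ratio indicators undefined: total cost is ", CT, call. = FALSE)
  per_head <- Pvc * kgcab
  list(L = Rs - CT,
       PN = if (per_head > 0) CT / per_head else NA_real_,
       RBC = Rs / CT,
       ROI = (Rs - CT) / CT)
}

#' Producer total income
#'
#' `RTs = L + CO + beta`: the batch profit plus the opportunity cost of
#' capital and land — a cost of the activity but income to the producer,
#' since it remunerates the producer's own factors — plus the weekly
#' remuneration `beta` for the producer's and family's work. Also reported
#' per kg of market pig produced (`RTs / theta`).
#'
#' @param L batch profit.
#' @param CO total opportunity cost.
#' @param beta producer/family labor remuneration (currency/week).
#' @return RTs, currency/week.
#' @export
producer_income <- function(L, CO, beta) {
  L + CO + beta
}
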