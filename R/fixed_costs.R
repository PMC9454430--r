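# Group B of the cost ledger: fixed operating costs.
#
# Monthly-basis items (labor, electricity, phone/internet, fuel) divide by
# omega; annual-basis items (depreciation, maintenance, fixed taxes) divide
# by phi. Items shared with other farm activities carry an apportionment
# share applied before the weekly conversion.

#' Weekly labor costs
#'
#' Labor is a fixed cost in this model — headcount does not move with one
#' more pig produced. Per activity, `CMO = (Sa / omega) * Nca` (monthly
#' salary with charges, converted to weekly, times employees); `CTMO` sums
#' the activities.
#'
#' @param labor labor register (see [farm_config()]).
#' @param tb [time_basis()].
#' @return list with `lines` (incl. `CMO`) and `total` (CTMO).
#' @export
labor_costs <- function(labor, tb = time_basis()) {
  CMO <- labor$Sa / tb$omega * labor$Nca
  list(lines = cbind(labor, CMO = CMO), total = sum(CMO))
}

#' Weekly electricity and phone/internet costs
#'
#' `CTE = share * Pe * Qe / omega` and
#' `CTTI = share * (Pt_phone + Pi_internet) / omega`. The apportionment
#' `share` imputes only the fraction of the bill attributable to the swine
#' activity (default 1).
#'
#' @param utilities list `Pe`, `Qe`, `Pt_phone`, `Pi_internet`, `share`.
#' @param tb [time_basis()].
#' @return list `CTE`, `CTTI`.
#' @export
utility_costs <- function(utilities, tb = time_basis()) {
  s <- utilities$share
  list(CTE = s * utilities$Pe * utilities$Qe / tb$omega,
       CTTI = s * (utilities$Pt_phone + utilities$Pi_internet) / tb$omega)
}

#' Weekly fuel costs
#'
#' Per fuel, the monthly cost is `CC = share * Pcx * Qcx`; the weekly
#' subtotal is `CTG = sum(CC) / omega`. Each fuel line carries its own
#' apportionment share (default 1).
#'
#' @param fuels fuel register.
#' @param tb [time_basis()].
#' @return list with `lines` (incl. monthly `CC`) and `total` (CTG).
#' @export
fuel_costs <- function(fuels, tb = time_basis()) {
  CC <- fuels$share * fuels$Pcx * fuels$Qcx
  list(lines = cbind(fuels, CC = CC), total = sum(CC) / tb$omega)
}

#' Straight-line depreciation of capital assets
#'
#' Per asset, `Vc = Pc * Qc`, the residual value is `Vres = Vc * txres`, and
#' the annual depreciation is `(Vc - Vres) / vu`. The weekly subtotal
#' prorates the annual sum: `CTDep = sum(CDep) / phi`. Biological assets
#' (dams, boars) use the same formula with the cull value as residual and a
#' useful life chosen by the manager — the model is managerial, not
#' statutory.
#'
#' @param assets asset register.
#' @param tb [time_basis()].
#' @return list with `lines` (incl. `Vc`, `Vres`, annual `CDep`),
#'   `annual` (sum of CDep) and `total` (weekly CTDep).
#' @export
depreciation_costs <- function(assets, tb = time_basis()) {
  if (any(assets$vu <= 0))
    stop("assets: useful life vu must be > 0", call. = FALSE)
  Vc <- assets$Pc * assets$Qc
  Vres <- Vc * assets$txres
  CDep <- (Vc - Vres) / assets$vu
  list(lines = cbind(assets, Vc = Vc, Vres = Vres, CDep = CDep),
       annual = sum(CDep), total = sum(CDep) / tb$phi)
}

#' Maintenance of capital assets
#'
#' Per asset, the annual maintenance is `Cman = Vc * txman` (a manager-set
#' rate on the asset value); weekly `CTMan = sum(Cman) / phi`.
#'
#' @param assets asset register.
#' @param tb [time_basis()].
#' @return list with `lines` (incl. `Vc`, annual `Cman`), `annual` and
#'   `total` (weekly CTMan).
#' @export
maintenance_costs <- function(assets, tb = time_basis()) {
  Vc <- assets$Pc * assets$Qc
  Cman <- Vc * assets$txman
  list(lines = cbind(assets, Vc = Vc, Cman = Cman),
       annual = sum(Cman), total = sum(Cman) / tb$phi)
}

#' Weekly fixed financial expenses
#'
#' Fixed taxes and fees (rural land tax, association and union memberships,
#' other) entered as annual amounts: `CTdff = (ITR + Txf + Otf) / phi`.
#'
#' @param taxes list `ITR`, `Txf`, `Otf` (currency/year).
#' @param tb [time_basis()].
#' @return CTdff.
#' @export
fixed_financial <- function(taxes, tb = time_basis()) {
  (taxes$ITR + taxes$Txf + taxes$Otf) / tb$phi
}

#' Total fixed operating cost
#'
#' `CFOP = CTMO + CTE + CTTI + CTG + CTDep + CTMan + CTdff` — group B of the
#' ledger.
#'
#' @param CTMO,CTE,CTTI,CTG,CTDep,CTMan,CTdff the seven weekly subtotals.
#' @return CFOP.
#' @export
total_fixed <- function(CTMO, CTE, CTTI, CTG, CTDep, CTMan, CTdff) {
  CTMO + CTE + CTTI + CTG + CTDep + CTMan + CTdff
}
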