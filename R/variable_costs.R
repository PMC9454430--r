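# Group A of the cost ledger: variable costs.
#
# Feed, health and reproduction lines are costed against the weekly
# populations of the batch flow; consumer goods are monthly amounts converted
# to weekly by omega; transport/insurance is per batch sold; variable taxes
# are annual amounts converted to weekly by phi.

.pop_lookup <- function(pop, category, phase, register) {
  key <- paste(pop$category, pop$phase, sep = "/")
  want <- paste(category, phase, sep = "/")
  idx <- match(want, key)
  if (anyNA(idx)) {
    bad <- want[is.na(idx)][1L]
    stop(sprintf("%s: line references unknown (category, phase): %s",
                 register, bad), call. = FALSE)
  }
  pop$count[idx]
}

#' Weekly feed costs
#'
#' Per diet line, the per-animal consumption in the phase is
#' `Crun = Ta * Qa` (supply period in days times kg/day); the weekly phase
#' intake is `Crs = Crun * Ncf` with `Ncf` the weekly count of that
#' `(category, phase)`; the line cost is `CCA = Pa * Crs` and the subtotal
#' `CTA` sums all lines.
#'
#' @param diets diet register (see [farm_config()]).
#' @param pop population data.frame from [phase_populations()].
#' @return list with `lines` (per-line data.frame incl. `Crun`, `Crs`,
#'   `CCA`) and `total` (CTA).
#' @export
feed_costs <- function(diets, pop) {
  if (nrow(diets) == 0L)
    return(list(lines = cbind(diets, Ncf = numeric(0), Crun = numeric(0),
                              Crs = numeric(0), CCA = numeric(0)),
                total = 0))
  Ncf <- .pop_lookup(pop, diets$category, diets$phase, "diets")
  Crun <- diets$Ta * diets$Qa
  Crs <- Crun * Ncf
  CCA <- diets$Pa * Crs
  list(lines = cbind(diets, Ncf = Ncf, Crun = Crun, Crs = Crs, CCA = CCA),
       total = sum(CCA))
}

#' Weekly health costs
#'
#' Per line, the weekly dose count is `Qds = q * Ncf` and the line cost
#' `CS = Pd * Qds`; `CTS` sums all lines.
#'
#' @param health health register.
#' @param pop population data.frame from [phase_populations()].
#' @return list with `lines` (incl. `Qds`, `CS`) and `total` (CTS).
#' @export
health_costs <- function(health, pop) {
  if (nrow(health) == 0L)
    return(list(lines = cbind(health, Ncf = numeric(0), Qds = numeric(0),
                              CS = numeric(0)),
                total = 0))
  Ncf <- .pop_lookup(pop, health$category, health$phase, "health")
  Qds <- health$q * Ncf
  CS <- health$Pd * Qds
  list(lines = cbind(health, Ncf = Ncf, Qds = Qds, CS = CS),
       total = sum(CS))
}

#' Weekly reproduction costs
#'
#' Reproduction inputs (semen doses, collection and insemination supplies)
#' are consumed by the weekly group of females: per line, `Qrs = q * GS` and
#' `CR = Pr * Qrs`; `CTR` sums every line present, whether the scenario is
#' on-farm semen production, purchased doses, or mixed.
#'
#' @param repro reproduction plan (scenario + lines, see [farm_config()]).
#' @param GS weekly sow group.
#' @return list with `lines` (incl. `Qrs`, `CR`) and `total` (CTR).
#' @export
repro_costs <- function(repro, GS) {
  lines <- repro$lines
  if (nrow(lines) == 0L)
    return(list(lines = cbind(lines, Qrs = numeric(0), CR = numeric(0)),
                total = 0))
  Qrs <- lines$q * GS
  CR <- lines$Pr * Qrs
  list(lines = cbind(lines, Qrs = Qrs, CR = CR), total = sum(CR))
}

#' Weekly consumer-goods costs
#'
#' Consumables (gloves, needles, syringes, marker sticks, rodent and fly
#' control, ...) are entered as average monthly quantities; per item
#' `CB = Pb * Qb / omega` and `CTB` sums the items.
#'
#' @param goods consumer-goods register.
#' @param tb [time_basis()].
#' @return list with `lines` (incl. `CB`) and `total` (CTB).
#' @export
consumer_goods_costs <- function(goods, tb = time_basis()) {
  CB <- goods$Pb * goods$Qb / tb$omega
  list(lines = cbind(goods, CB = CB), total = sum(CB))
}

#' Pig-raising subtotal
#'
#' `CTC = CTA + CTS + CTR + CTB` — the costs tied directly to the animals
#' (feed, health, reproduction, consumer goods). This subtotal also serves
#' as the working capital that the opportunity-cost module remunerates.
#'
#' @param CTA,CTS,CTR,CTB the four register subtotals.
#' @return CTC.
#' @export
raising_subtotal <- function(CTA, CTS, CTR, CTB) {
  CTA + CTS + CTR + CTB
}

#' Transport, loading and insurance of the batch sold
#'
#' Transport is priced per kilometer to the slaughterhouse, `Cta = Pt * Qt`.
#' Insurance applies the per-batch rate `Txseg` to the capital invested in
#' the batch, `Cminvest = Ntl * kgcab * Pvc` (the batch valued at the market
#' price). `CTtaseg = Cta + Cseg`.
#'
#' @param transport list `Pt`, `Qt`, `Txseg`.
#' @param Ntl finished head count.
#' @param kgcab live weight per finished pig (kg).
#' @param Pvc market price (currency/kg live).
#' @return list `Cta`, `Cminvest`, `Cseg`, `total` (CTtaseg).
#' @export
transport_insurance <- function(transport, Ntl, kgcab, Pvc) {
  Cta <- transport$Pt * transport$Qt
  Cminvest <- Ntl * kgcab * Pvc
  Cseg <- transport$Txseg * Cminvest
  list(Cta = Cta, Cminvest = Cminvest, Cseg = Cseg, total = Cta + Cseg)
}

#' Weekly variable financial expenses
#'
#' Variable taxes and fees (ICMS, animal transit guide, Funrural, other) are
#' entered as annual amounts and prorated to the week:
#' `CTdfv = (ICMS + GTA + FUN + Otv) / phi`.
#'
#' @param taxes list `ICMS`, `GTA`, `FUN`, `Otv` (currency/year).
#' @param tb [time_basis()].
#' @return CTdfv.
#' @export
variable_financial <- function(taxes, tb = time_basis()) {
  (taxes$ICMS + taxes$GTA + taxes$FUN + taxes$Otv) / tb$phi
}

#' Total variable cost
#'
#' `CV = CTC + CTtaseg + CTdfv` — group A of the ledger.
#'
#' @param CTC raising subtotal.
#' @param CTtaseg transport + insurance subtotal.
#' @param CTdfv variable financial expenses.
#' @return CV.
#' @export
total_variable <- function(CTC, CTtaseg, CTdfv) {
  CTC + CTtaseg + CTdfv
}
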