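# Group D of the cost ledger: opportunity cost of capital and land.
#
# Remuneration of the producer's own production factors — capital immobilized
# in assets, capital funding the raising of the animals, and land — at
# manager-chosen annual rates, prorated to the week by phi with no
# compounding. A cost of the activity, but income to the producer.

#' Remuneration of fixed capital
#'
#' `RCI = trci * sum(Vc) / phi`: the annual rate chosen by the manager (e.g.
#' Selic, or whatever best represents the alternative use of capital) applied
#' to the total value of the asset register, spread over the weeks of the
#' year.
#'
#' @param assets asset register (Vc = Pc * Qc per line).
#' @param trci annual remuneration rate (fraction/year).
#' @param tb [time_basis()].
#' @return RCI, currency/week.
#' @export
fixed_capital_remuneration <- function(assets, trci, tb = time_basis()) {
  trci * sum(assets$Pc * assets$Qc) / tb$phi
}

#' Remuneration of working capital
#'
#' `RCG = trcg * CTC / phi`: the annual rate applied to the weekly raising
#' subtotal (feed, health, reproduction, consumer goods), prorated to the
#' week. Note the asymmetry with [fixed_capital_remuneration()]: the base is
#' one week's expenditure, so RCG is typically small relative to RCI.
#'
#' @param CTC raising subtotal from [raising_subtotal()].
#' @param trcg annual remuneration rate (fraction/year).
#' @param tb [time_basis()].
#' @return RCG, currency/week.
#' @export
working_capital_remuneration <- function(CTC, trcg, tb = time_basis()) {
  trcg * CTC / tb$phi
}

#' Remuneration of land
#'
#' `RCT = arr * PATr / phi`: the hectares used by the swine activity at the
#' regional lease price per hectare-year, prorated to the week.
#'
#' @param arr area used (ha).
#' @param PATr regional lease price (currency/ha/year).
#' @param tb [time_basis()].
#' @return RCT, currency/week.
#' @export
land_remuneration <- function(arr, PATr, tb = time_basis()) {
  arr * PATr / tb$phi
}

#' Total opportunity cost
#'
#' `CO = RCI + RCG + RCT` — group D of the ledger.
#'
#' @param RCI,RCG,RCT the three remuneration items.
#' @return CO.
#' @export
total_opportunity <- function(RCI, RCG, RCT) {
  RCI + RCG + RCT
}
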