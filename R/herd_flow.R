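# Herd demography and weekly batch flow.
#
# The weekly group of sows (GS) is the model's basic production unit: the set
# of females inseminated each week to sustain the farrowing and weaning
# schedule. The piglet cohort it generates is propagated sequentially through
# the ordered grow-out phases, each discounting its mortality; the survivors
# of the last phase are the finished head of the weekly batch.

#' Weekly sow group
#'
#' Number of females in the weekly breeding group,
#' `GS = N * ppa * txparto / phi`: sows in production times farrowings per
#' sow-year times the farrowing rate, spread over the weeks of a 365-day
#' year. The result is fractional — it is an average weekly flow, not a
#' census — and is carried unrounded.
#'
#' @param herd herd parameter list (see [farm_config()]).
#' @param tb [time_basis()].
#' @return GS, females per week (numeric scalar).
#' @examples
#' h <- list(N = 1000, ppa = 2.4, txparto = 0.9)
#' weekly_sow_group(h)  # 2160 * 7 / 365 = 41.42466
#' @export
weekly_sow_group <- function(herd, tb = time_basis()) {
  herd$N * herd$ppa * herd$txparto / tb$phi
}

#' Phase-by-phase weekly populations and finished head count
#'
#' Seeds the farrowing-room cohort with `GS * Nnv` piglets born alive per
#' week and propagates it through the grow-out phases in their configured
#' order, each phase retaining a fraction `(1 - txmort)` of the cohort it
#' receives. The count recorded for a grow-out phase is the cohort *after*
#' that phase's mortality; the count surviving the final phase is the
#' finished head count `Ntl`. Breeding-herd rows (`role == "breeding"`) take
#' their weekly count from the user-entered `stock` column — the breeding
#' herd is a standing population, not a flow — and do not affect `Ntl`.
#'
#' @param herd herd parameter list with a `phases` data.frame.
#' @param GS weekly sow group from [weekly_sow_group()].
#' @return list with `pop` (data.frame `category`, `phase`, `role`, `count`)
#'   and `Ntl` (finished head per weekly batch).
#' @examples
#' h <- list(Nnv = 12, phases = data.frame(
#'   category = "piglet", phase = c("farrowing", "nursery", "finishing"),
#'   role = "growout", txmort = c(0.05, 0.02, 0.015), stock = 0))
#' phase_populations(h, GS = 10)$Ntl  # 120 * .95 * .98 * .985 = 110.0442
#' @export
phase_populations <- function(herd, GS) {
  ph <- herd$phases
  count <- numeric(nrow(ph))
  cohort <- GS * herd$Nnv
  for (i in seq_len(nrow(ph))) {
    if (ph$role[i] == "growout") {
      cohort <- cohort * (1 - ph$txmort[i])
      count[i] <- cohort
    } else {
      count[i] <- ph$stock[i]
    }
  }
  pop <- data.frame(category = ph$category, phase = ph$phase, role = ph$role,
                    count = count, stringsAsFactors = FALSE)
  list(pop = pop, Ntl = cohort)
}

#' Batch live weight
#'
#' Kilograms of market pig produced at the end of the weekly batch:
#' `theta = Ntl * kgcab`.
#'
#' @param Ntl finished head count.
#' @param kgcab average live weight per finished pig (kg).
#' @return theta, kg per weekly batch.
#' @export
batch_live_weight <- function(Ntl, kgcab) {
  Ntl * kgcab
}

#' Weekly cull weight by sex
#'
#' Kilograms of breeding animals (sows, boars) sold weekly through culling:
#' per sex, `Nherd * txdesc / phi * Pdesc` — the standing herd times the
#' annual culling rate, spread over the weeks of the year, times the cull
#' live weight.
#'
#' @param culls data.frame `sex`, `Nherd`, `txdesc`, `Pdesc`
#'   (see [farm_config()]).
#' @param tb [time_basis()].
#' @return named numeric vector of kg/week, one element per cull row (named
#'   by sex); `sum()` of it is the total weekly cull weight.
#' @examples
#' weekly_cull_weight(data.frame(sex = "female", Nherd = 1000,
#'                               txdesc = 0.4, Pdesc = 220))  # 1687.671
#' @export
weekly_cull_weight <- function(culls, tb = time_basis()) {
  kg <- culls$Nherd * culls$txdesc / tb$phi * culls$Pdesc
  stats::setNames(kg, culls$sex)
}

#' Compute the full weekly batch flow for a farm
#'
#' Convenience wrapper combining [weekly_sow_group()], [phase_populations()],
#' [batch_live_weight()] and [weekly_cull_weight()].
#'
#' @param cfg a [farm_config].
#' @param tb [time_basis()].
#' @return object of class `batch_flow`: list with `GS`, `pop`, `Ntl`,
#'   `theta` (kg of market pig per batch) and `cull_kg` (named kg/week per
#'   cull row).
#' @export
compute_batch_flow <- function(cfg, tb = time_basis()) {
  GS <- weekly_sow_group(cfg$herd, tb)
  pp <- phase_populations(cfg$herd, GS)
  structure(list(
    GS = GS,
    pop = pp$pop,
    Ntl = pp$Ntl,
    theta = batch_live_weight(pp$Ntl, cfg$herd$kgcab),
    cull_kg = weekly_cull_weight(cfg$herd$culls, tb)
  ), class = "batch_flow")
}

#' @export
print.batch_flow <- function(x, ...) {
  cat(sprintf("Weekly batch flow: GS = %.3f sows/week, Ntl = %.2f finished head, theta = %.1f kg\n",
              x$GS, x$Ntl, x$theta))
  if (length(x$cull_kg))
    cat("  cull weight:", paste(sprintf("%s %.1f kg", names(x$cull_kg),
                                        x$cull_kg), collapse = ", "),
        sprintf("(total %.1f kg/week)\n", sum(x$cull_kg)))
  print(x$pop, row.names = FALSE)
  invisible(x)
}
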