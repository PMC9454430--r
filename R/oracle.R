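# Independent brute-force ledger oracle.
#
# One flat pass that enumerates every cost line of a configuration from
# first principles and sums it, written deliberately WITHOUT reusing the
# engine's module functions (compute_ledger and friends). Its only purpose
# is equivalence testing of the engine: two independently coded routes to
# the same total.

#' Flat re-enumeration of the total weekly cost
#'
#' Recomputes the total weekly cost `CT` of a farm configuration in a single
#' flat enumeration of line items, independent of the ledger engine. Used in
#' the test suite to cross-check [compute_ledger()]; for any valid
#' configuration the two agree to floating precision.
#'
#' @param cfg a [farm_config].
#' @return total weekly cost (numeric scalar).
#' @export
oracle_ledger <- function(cfg) {
  omega <- 4.345
  phi <- 365 / 7
  h <- cfg$herd
  total <- 0

  # weekly sow group and sequential grow-out survival chain
  GS <- h$N * h$ppa * h$txparto / phi
  counts <- list()
  cohort <- GS * h$Nnv
  for (i in seq_len(nrow(h$phases))) {
    row <- h$phases[i, ]
    if (row$role == "growout") {
      cohort <- cohort * (1 - row$txmort)
      counts[[paste(row$category, row$phase)]] <- cohort
    } else {
      counts[[paste(row$category, row$phase)]] <- row$stock
    }
  }
  Ntl <- cohort

  # A: feed
  for (i in seq_len(nrow(cfg$diets))) {
    d <- cfg$diets[i, ]
    total <- total + d$Pa * d$Ta * d$Qa * counts[[paste(d$category, d$phase)]]
  }
  # A: health
  for (i in seq_len(nrow(cfg$health))) {
    v <- cfg$health[i, ]
    total <- total + v$Pd * v$q * counts[[paste(v$category, v$phase)]]
  }
  # A: reproduction (consumed by the weekly group of females)
  for (i in seq_len(nrow(cfg$repro$lines))) {
    r <- cfg$repro$lines[i, ]
    total <- total + r$Pr * r$q * GS
  }
  # A: consumer goods (monthly -> weekly)
  for (i in seq_len(nrow(cfg$consumer_goods))) {
    g <- cfg$consumer_goods[i, ]
    total <- total + g$Pb * g$Qb / omega
  }
  raising <- total  # CTC: feed + health + repro + goods

  # A: transport + batch insurance on invested capital
  total <- total + cfg$transport$Pt * cfg$transport$Qt
  total <- total + cfg$transport$Txseg * Ntl * h$kgcab * cfg$market$Pvc
  # A: variable taxes (annual -> weekly)
  vt <- cfg$variable_taxes
  total <- total + (vt$ICMS + vt$GTA + vt$FUN + vt$Otv) / phi

  # B: labor (monthly -> weekly)
  for (i in seq_len(nrow(cfg$labor)))
    total <- total + cfg$labor$Sa[i] / omega * cfg$labor$Nca[i]
  # B: utilities
  u <- cfg$utilities
  total <- total + u$share * u$Pe * u$Qe / omega
  total <- total + u$share * (u$Pt_phone + u$Pi_internet) / omega
  # B: fuel
  for (i in seq_len(nrow(cfg$fuels)))
    total <- total + cfg$fuels$share[i] * cfg$fuels$Pcx[i] *
      cfg$fuels$Qcx[i] / omega
  # B: straight-line depreciation + maintenance (annual -> weekly)
  asset_value <- 0
  for (i in seq_len(nrow(cfg$assets))) {
    a <- cfg$assets[i, ]
    value <- a$Pc * a$Qc
    asset_value <- asset_value + value
    total <- total + (value - value * a$txres) / a$vu / phi
    total <- total + value * a$txman / phi
  }
  # B: fixed taxes
  ft <- cfg$fixed_taxes
  total <- total + (ft$ITR + ft$Txf + ft$Otf) / phi

  # D: opportunity costs
  op <- cfg$opportunity
  total <- total + op$trci * asset_value / phi
  total <- total + op$trcg * raising / phi
  total <- total + op$arr * op$PATr / phi

  total
}
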