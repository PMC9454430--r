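# Fixtures built in code: a minimal working farm with zeroed cost registers
# (tests switch on one register at a time), a pool of seeded synthetic farms,
# and a single-field upward price/quantity perturbation for monotonicity
# checks.

base_herd <- function(N = 100, txmort = c(0.05, 0.02, 0.015)) {
  list(
    N = N, ppa = 2.4, txparto = 0.9, Nnv = 12, kgcab = 115,
    phases = data.frame(
      category = c("piglet", "piglet", "finisher", "dam"),
      phase = c("farrowing", "nursery", "finishing", "gestation"),
      role = c("growout", "growout", "growout", "breeding"),
      txmort = c(txmort, 0),
      stock = c(0, 0, 0, N),
      stringsAsFactors = FALSE
    ),
    culls = data.frame(sex = "female", Nherd = N, txdesc = 0, Pdesc = 220,
                       stringsAsFactors = FALSE)
  )
}

# A valid farm whose every cost register is empty/zero; `...` overrides
# individual farm_config() arguments.
base_farm <- function(...) {
  args <- list(...)
  if (is.null(args$herd)) args$herd <- base_herd()
  do.call(farm_config, args)
}

# n seeded synthetic farms cycling through the three size classes.
farm_pool <- function(n, offset = 0) {
  sizes <- c("small", "medium", "large")
  lapply(seq_len(n), function(i)
    generate_farm(scenario_spec(seed = i + offset,
                                size_class = sizes[1 + (i %% 3)])))
}

# Multiply one randomly chosen monetary or quantity field by (1 + u), u > 0.
# Every targeted field enters the ledger with a non-negative coefficient, so
# the total cost must not decrease.
perturb_price_up <- function(cfg, seed) {
  set.seed(seed)
  bump <- 1 + stats::runif(1, 0.01, 1)
  targets <- list(
    function(c) { i <- sample(nrow(c$diets), 1); c$diets$Pa[i] <- c$diets$Pa[i] * bump; c },
    function(c) { i <- sample(nrow(c$diets), 1); c$diets$Qa[i] <- c$diets$Qa[i] * bump; c },
    function(c) { i <- sample(nrow(c$health), 1); c$health$Pd[i] <- c$health$Pd[i] * bump; c },
    function(c) { i <- sample(nrow(c$repro$lines), 1); c$repro$lines$Pr[i] <- c$repro$lines$Pr[i] * bump; c },
    function(c) { i <- sample(nrow(c$consumer_goods), 1); c$consumer_goods$Pb[i] <- c$consumer_goods$Pb[i] * bump; c },
    function(c) { c$transport$Pt <- c$transport$Pt * bump; c },
    function(c) { c$variable_taxes$ICMS <- c$variable_taxes$ICMS * bump; c },
    function(c) { i <- sample(nrow(c$labor), 1); c$labor$Sa[i] <- c$labor$Sa[i] * bump; c },
    function(c) { c$utilities$Pe <- c$utilities$Pe * bump; c },
    function(c) { i <- sample(nrow(c$fuels), 1); c$fuels$Pcx[i] <- c$fuels$Pcx[i] * bump; c },
    function(c) { i <- sample(nrow(c$assets), 1); c$assets$Pc[i] <- c$assets$Pc[i] * bump; c },
    function(c) { i <- sample(nrow(c$assets), 1); c$assets$txman[i] <- c$assets$txman[i] * bump; c },
    function(c) { c$fixed_taxes$ITR <- c$fixed_taxes$ITR * bump; c },
    function(c) { c$opportunity$PATr <- c$opportunity$PATr * bump; c },
    function(c) { c$market$Pvc <- c$market$Pvc * bump; c }
  )
  targets[[sample(length(targets), 1)]](cfg)
}
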