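---
title: "The weekly batch cost model for full-cycle swine farms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The weekly batch cost model for full-cycle swine farms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigcost)
```

## The model

`pigcost` implements an enterprise-budget cost model for full-cycle swine
farms — operations that breed, farrow, wean and finish market hogs on one
site. The accounting unit is the *weekly batch*: the cohort of market pigs
sold in one week, driven by the weekly group of sows inseminated to sustain
the farrowing schedule. Every cost is expressed per weekly batch; inputs
entered per month divide by $\omega = 4.345$ weeks/month and inputs entered
per year divide by $\varphi = 365/7$ weeks/year.

Costs are allocated in the neoclassical order used in farm budgeting:

* **A — variable costs** $CV$: feed, health, reproduction, consumer goods
  (together the raising subtotal $CTC$), transport and insurance of the
  batch sold, and variable taxes;
* **B — fixed operating costs** $CFOP$: labor, electricity,
  telephone/internet, fuel, straight-line depreciation, maintenance, fixed
  taxes;
* **C — operating cost** $COP = CV + CFOP$;
* **D — opportunity cost** $CO$: remuneration of fixed capital
  ($RCI = t_{rci}\sum_j V_{cj}/\varphi$), of working capital
  ($RCG = t_{rcg}\, CTC/\varphi$) and of land
  ($RCT = a\, P_{AT}/\varphi$);
* **E — total cost** $CT = COP + CO$.

The herd flow seeds the farrowing room with $GS \times N_{nv}$ piglets born
alive per week, where $GS = N \cdot ppa \cdot tx_{parto} / \varphi$ is the
weekly sow group, and propagates the cohort *sequentially* through the
ordered grow-out phases, each retaining $(1 - tx_{mort})$ of what it
receives. The survivors of the last phase are the finished head $Nt_l$;
$\theta_l = Nt_l \times kg_{cab}$ is the batch live weight. A sequential
chain is the only reading of the per-phase mortality discount that does not
double-count losses: discounting each phase independently from the born-alive
cohort and summing would remove the same head repeatedly. Breeding
categories (dams, gilts, boars) are standing stock entered by the user, used
for feed and health costing only; the weekly group $GS$ drives
insemination-linked consumption and the piglet cohort.

From $CT$ the indicator suite follows: cost per head $CT/Nt_l$, per kg
$CT/\theta_l$ and per arroba ($18.75$ kg, the Brazilian market-hog price
basis, so cost per arroba is always $18.75\times$ cost per kg); revenue
$R_s = \theta_l P_{vc} + \sum_s \vartheta_s P_{vd}$ including weekly culls
$\vartheta_s = N_s\, tx_{desc}/\varphi \times P_{desc}$; profit
$L = R_s - CT$; leveling point $PN = CT/(P_{vc}\, kg_{cab})$ in head (culls
deliberately excluded from the break-even revenue side); benefit-cost ratio
$RBC = R_s/CT$; return on investment $ROI = L/CT = RBC - 1$; and producer
total income $RT_s = L + CO + \beta$, where the opportunity cost — a cost of
the activity — returns as income to the producer who owns the factors, and
$\beta$ is the weekly remuneration of producer/family labor ($\beta$ never
enters $CT$).

## Parameters that matter

| Parameter | Units | Meaning |
|---|---|---|
| `N`, `ppa`, `txparto` | head, farrowings/sow/yr, fraction | sow herd and its farrowing performance; set `GS` |
| `Nnv`, `txmort` per phase | head, fraction | born alive and the survival chain; set `Ntl` |
| `kgcab` | kg | finished live weight; scales weight-basis quantities |
| `Ta`, `Qa`, `Pa` per diet | days/cycle, kg/day, currency/kg | feed, typically 65–80 % of total cost |
| `txres`, `vu`, `txman` per asset | fraction, years, fraction/yr | straight-line depreciation and maintenance |
| `trci`, `trcg` | fraction/yr | opportunity rates; user-chosen (e.g. Selic), never hard-coded |
| `share` (utilities, fuel) | fraction in [0, 1], default 1 | imputes only the swine share of apportioned bills |
| `Txseg` | fraction/batch | insurance rate, applied once to the batch's invested capital |

Three conventions deserve note. First, $\omega$ is stored as the printed
constant 4.345, not recomputed from $\varphi/12$; the two differ in the
fourth decimal and the printed constant is the convention of the source
budgeting scheme. Second, the weekly group formula *multiplies* by the
farrowing rate; a demographic services model might divide by it (more
services than farrowings). The model follows the budgeting convention as
stated; users calibrating to service counts should enter `txparto`
accordingly. Third, $RCG$ applies an annual rate, divided by $\varphi$, to
*one week's* raising expenditure — it remunerates a week's working capital
for a week, and is therefore small relative to $RCI$; this asymmetry is
faithful to the scheme, and the documentation flags it.

Taxes (ICMS, Funrural, GTA, ITR, fees) are entered as *annual currency
amounts* and prorated by $\varphi$; the engine never computes Brazilian tax
law, and ICMS is prorated even though in reality it is
revenue-proportional — the model is implemented as specified. Labor is a
fixed cost by design (headcount does not move with one more pig); the schema
does not allow moving it to group A.

## Numerical choices

Arithmetic is full double precision throughout; rounding to 2 decimals
happens only in the `text` report rendering (`csv`/`json` round-trip at full
precision). Head counts are carried fractionally — the weekly group is an
average flow, not a census — so no integer rounding occurs anywhere in the
flow. Degenerate inputs are handled explicitly: a zero total cost yields
zero unit costs; a positive cost with no finished head is an undefined unit
cost and raises an error in the operation (stored as `NA` with a warning by
the `compute_batch()` pipeline so a degenerate ledger is still inspectable);
useful life must be positive; mortality 1 is excluded by validation.
Configuration serialization writes 15 significant digits and the synthetic
generator rounds its draws to at most 5 decimals, making load → write → load
exact.

## The synthetic generator and what tests show

`generate_farm()` draws complete, valid configurations from documented
uniform ranges at three size classes (50–200, 200–1000, 1000–5000 sows),
with prices and rates loosely calibrated to plausible Brazilian full-cycle
farms around 2022 (diet 1.2–2.5 BRL/kg, market hog 5.5–7.5 BRL/kg live,
capital rates 2–14 %/yr, four grow-out phases with mortalities 0.5–10 %).
Each register draws from its own named random stream, so adding a register
never shifts existing draws for a fixed seed. These bounds are test
scaffolding chosen once — not survey data and not fitted to any real farm.

The generator emulates the *structure* of real farms (register shapes,
plausible magnitudes, a coherent herd), not their joint distributions: real
input prices co-move (feed and fuel track commodity markets), zootechnical
indices correlate with technology level, and seasonal price cycles exist.
Passing tests therefore certify the accounting engine — additivity,
conservation, unit conversions, oracle equivalence, homogeneity and
monotonicity of the ledger — on a wide family of valid inputs; they do not
certify that any particular farm's cost level is realistic. The test suite
exercises 100 seeded farms per structural property and 200 single-price
perturbations (problem sizes chosen to keep the whole suite in the tens of
seconds on one CPU); the independent check is `oracle_ledger()`, a flat
single-pass re-enumeration of every cost line written without reusing the
engine's module code.

## Worked example

```{r}
cfg <- generate_farm(scenario_spec(seed = 42, size_class = "medium"))
batch <- compute_batch(cfg)
batch$report
```

```{r}
head(as.data.frame(batch$ledger))
```

## Known limitations

* Single-batch steady state: no multi-batch time series, discounting/NPV or
  sensitivity engine (sweeps can be scripted over configurations, e.g. with
  `scale_prices()`).
* No parity structure, replacement dynamics or gestation-calendar
  scheduling; the herd is a stationary weekly flow.
* No least-cost diet formulation or feed-price modelling; diets are entered
  as prices and quantities.
* Tax amounts are user inputs; no statutory computation.
* The insurance rate is per batch with no annualization, as specified by
  the scheme's formula; users with annual premiums should convert before
  entry.
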