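# pigcost

Weekly production cost ledgers and economic indicators for full-cycle swine
farms.

Most commercial pig producers do not know the cost of the market hog they
sell: internal controls are thin and no standard calculation method is in
everyday use. `pigcost` gives producers, technicians and researchers a
config-driven engine that computes, for the weekly batch of market pigs, the
complete cost ledger and the indicator suite used in farm enterprise
budgeting.

## The model

Costs are allocated in the neoclassical order:

* **A — variable costs** `CV`: feed, health, reproduction and consumer
  goods (the raising subtotal `CTC`), transport and insurance of the batch
  sold, variable taxes;
* **B — fixed operating costs** `CFOP`: labor, electricity,
  phone/internet, fuel, straight-line depreciation
  `(Vc − Vc·txres)/vu`, maintenance, fixed taxes;
* **C — operating cost** `COP = CV + CFOP`;
* **D — opportunity costs** `CO`: remuneration of fixed capital
  `trci·ΣVc/φ`, working capital `trcg·CTC/φ` and land `arr·PATr/φ`;
* **E — total cost** `CT = COP + CO`.

Everything is per weekly batch: monthly inputs divide by `ω = 4.345`
weeks/month, annual inputs by `φ = 365/7` weeks/year. The weekly sow group
`GS = N·ppa·txparto/φ` seeds `GS·Nnv` piglets born alive, which survive a
sequential chain of grow-out phases, each discounting its mortality, to give
the finished head `Ntl` and batch weight `θ = Ntl·kgcab`. Indicators follow:
cost per head / per kg / per arroba (18.75 kg), revenue including weekly
culls, profit `L = Rs − CT`, leveling point `PN = CT/(Pvc·kgcab)` in head,
benefit-cost ratio `RBC = Rs/CT`, `ROI = RBC − 1`, and producer total income
`RTs = L + CO + β` (the opportunity cost is a cost of the activity but
income to the producer who owns the factors).

## Worked example

```r
library(pigcost)
cfg   <- generate_farm(scenario_spec(seed = 42, size_class = "medium"))
batch <- compute_batch(cfg)
batch$report
#> Weekly batch report
#>   GS 38.036 sows/wk | Ntl 466.63 head | theta 56555.7 kg
#>   CV 230781.79 + CFOP 25544.16 = COP 256325.95; + CO 6434.89 = CT 262760.83
#>   unit cost: 563.10/head, 87.11/arroba, 4.6461/kg
#>   revenue 316971.60 (679.28/head, 5.6046/kg); profit 54210.77
#>   PN 393.47 head | RBC 1.2063 | ROI 20.63% | RTs 62079.04 (1.0977/kg)
```

This synthetic 958-sow farm inseminates 38 sows a week and finishes 467
market pigs (56.6 t live weight). Producing each pig costs 563.10 BRL
(4.65 BRL/kg, 87.11 BRL/arroba); selling the batch plus the weekly cull sows
grosses 316 971.60 BRL, leaving a 54 210.77 BRL weekly profit. At the
current price and weight the farm breaks even at 393 head — comfortably
below the 467 finished — earning 1.21 BRL of revenue per BRL spent (ROI
20.6 %). The producer's own weekly income, adding back the capital/land
remuneration and family labor, is 62 079.04 BRL.

Write the full ledger with `write_report(batch$report, batch$ledger,
"report.csv", format = "csv")` (also `json`, `text`), or drive everything
from a config file:

```sh
exec/pigcost synth    --seed 42 --size medium --out farm.yaml
exec/pigcost validate --config farm.yaml
exec/pigcost compute  --config farm.yaml --out report.csv --format csv
```

Configurations are single YAML/JSON files; tabular registers (diets, health,
labor, assets, ...) may be inline or external CSV files referenced by path.
`validate_config()` returns a findings table (severity + key path) instead
of aborting; `load_farm_config()` refuses configurations with errors.

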