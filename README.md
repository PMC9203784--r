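# crossimpact

Cross-impact matrix and network influence analysis for interacting goal
systems, such as the Sustainable Development Goals.

## The problem

Goal systems like the 2030 Agenda are explicitly interdependent: progress
on water and sanitation moves child health, child health moves education
and poverty, and poverty moves land use. Policy prioritisation needs those
interactions made explicit. In the SDG Synergies style of analysis, a
stakeholder group scores every ordered pair of goals on the Weimer-Jehle
seven-point scale — *"if progress is made on goal X, how does this
influence progress on goal Y?"*, answered with an integer from −3
(strongly restricting) to +3 (strongly promoting) — and the resulting
**cross-impact matrix** is analysed as a weighted directed network.

`crossimpact` is the analysis toolkit for that workflow, aimed at
researchers and facilitators running such assessments:

* **Matrix construction and validation** — seven-point scale with label
  mapping, goal registries, complete-matrix checks with precise, classed
  errors (duplicate pair, missing pair, self pair, out-of-range score).
* **Network influence** — for a matrix with weights $w_{ij}$:
  first-order influence (weighted out-degree) $D_g^{Out} = \sum_{j\ne g} w_{gj}$;
  second-order influence along length-2 paths
  $I^{2nd}_{A\to D} = \sum_i w_{Ai} w_{iD}$ (with $A = D$: the
  feedback-loop strength of a goal); total influence
  $I_g^{Total} = D_g^{Out} + \sum_{j \ne g} w_{gj} D_j^{Out}$;
  rankings with rank shifts; focal-goal perspectives.
* **Composition summaries** — counts and integer percentages of
  promoting / restricting / neutral interactions.
* **Workshop consensus** — discrepancy detection between scoring groups
  and consensus resolution (manual decisions, median, rounded mean).
* **Indicator trends** — direction-recoded, paired-observation Pearson
  correlation between sparse goal-indicator time series.
* **Synthetic data** — seeded generators for matrices, group scorings and
  indicator series, plus packaged fixtures from a published Cambodia
  assessment (goal registry, child-health row/column, indicator table).
* **IO and CLI** — CSV matrices, TSV edge lists, GraphML, JSON reports,
  and a `crossimpact` command line (`exec/crossimpact`).

## Worked example

The child-health row and column of the Cambodia assessment are published
verbatim and ship as a fixture; the rest of the 17-goal matrix is
generated (the focal goal's numbers depend only on its own row and
column, so they are identical under every seed):

```r
library(crossimpact)

m <- embed_fixture(generate_matrix(goals = cambodia_goals(), seed = 42))
summarize_matrix(m)
#> 17 goals, 272 ordered interactions
#>   positive: 211 (78%)
#>   negative: 9 (3%)
#>   zero    : 52 (19%)

weighted_degree(m, "3", "out")   # 16 — child health's first-order influence
weighted_degree(m, "3", "in")    # 29 — how strongly the network moves child health
second_order_influence(m, "3", "3")
#> 30  — positive feedback loop: progress on child health reinforces itself

head(rank_goals(m, "total"), 3)
#>   rank goal influence rank_other rank_shift
#> 1    1    2       745          3          2
#> 2    2    4       736          3          1
#> 3    3    7       727          1         -2
```

The composition line reads: of the 272 ordered interactions, 211 were
scored promoting, 9 restricting, 52 no-influence (percentages rounded
half away from zero). The ranking lists goals by total (first- plus
second-order) influence; `rank_shift` is positive for goals that gain
rank once indirect effects are counted.

Correlating observed indicator trends (series are first re-oriented so
larger = progress, then paired by exact year):

```r
tab <- cambodia_indicators()
u5 <- series_from_table(tab, "3", "under-five mortality rate (per 1000 live births)")
fa <- series_from_table(tab, "15")
progress_correlation(u5, fa)
#> Progress correlation 3/under-five mortality rate (per 1000 live births)
#>   vs 15/forest area as a proportion of total land area (%):
#>   r = -0.883 over 4 paired years (ok)
```

The negative r says child-health progress and forest-area progress have
moved in opposite directions over the shared years — a trade-off signal.

There is also a command line:

```sh
exec/crossimpact simulate --seed 7 --output matrix.csv
exec/crossimpact analyze --matrix matrix.csv --focal 3 --output report.json
exec/crossimpact rank --matrix matrix.csv --order total
```

## Package layout

* `R/` — implementation; `tests/testthat/` — unit, property and
  acceptance tests (oracle: brute-force path enumeration and textbook
  formulas)
* `inst/extdata/` — packaged fixtures (goal registry, indicator table)
* `vignettes/cross-impact-analysis.Rmd` — methods: model, assumptions,
  design choices, limitations
* `exec/crossimpact` — command-line entry point
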