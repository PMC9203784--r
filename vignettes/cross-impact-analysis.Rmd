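---
title: "Cross-impact analysis of interacting goal systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-impact analysis of interacting goal systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossimpact)
```

## The method

Cross-impact analysis asks a deceptively simple question about a system of
goals: *if progress is made on goal X, how does this influence progress on
goal Y?* A stakeholder group answers it for every ordered pair of goals on
the Weimer-Jehle seven-point scale — integer scores from $-3$ (strongly
restricting) through $0$ (no influence) to $+3$ (strongly promoting). The
answers form a **cross-impact matrix** $W$ whose cell $w_{ij}$ scores the
directed influence of goal $i$ on goal $j$. Self-influence is never scored:
the diagonal is structurally absent in this package (stored as `NA`, not
zero), and every aggregate explicitly skips $i = j$.

The matrix is equivalently a weighted directed network $G = (N, L)$ with
goals as nodes and scored interactions as links, which is where its
analytical value lies. The package computes three nested influence
measures for each goal $g$:

* **First-order influence** — the weighted out-degree, i.e. the row sum
  $D_g^{Out} = \sum_{j \ne g} w_{gj}$. The column sum $D_g^{In}$ measures
  how strongly the goal is influenced by the rest of the network.
* **Second-order influence of $A$ on $D$** — the sum over all directed
  length-2 paths,
  $I^{2nd}_{A \to D} = \sum_i w_{Ai}\, w_{iD}$,
  with the intermediate $i$ running over the goals connecting $A$ and $D$.
  With $A = D$ this is the **feedback-loop strength** of a goal: positive
  when progress on the goal indirectly reinforces itself.
* **Total influence** —
  $I_g^{Total} = I_g^{1st} + \sum I^{2nd}
             = D_g^{Out} + \sum_{j \ne g} w_{gj}\, D_j^{Out}$,
  the out-degree plus the out-degree-weighted second-order term.

Because the scores are integers, every one of these quantities is an exact
integer; no floating-point tolerance is involved anywhere in the influence
layer.

### Numerical and design choices

**The backlink term.** As written, the total-influence formula multiplies
$w_{gj}$ by the *full* out-degree of the neighbour, which includes the
backlink $w_{jg}$ — so a goal's total influence partially counts influence
it routes back to itself. We implement the formula verbatim as the
default, because that is what the published definition says, and expose
`exclude_backlink = TRUE` (equivalently `--exclude-backlink` on the
command line) which subtracts exactly the feedback-loop term
$\sum_j w_{gj} w_{jg}$ for users who prefer the stricter reading. The two
variants are related by `total - total_excl == diag(W %*% W)`, which the
test suite asserts.

**Ranking and ties.** Goals are ranked by descending influence with
competition ("1-2-2-4") ranking; within a tie group goals keep registry
order, so rankings are deterministic. The rank shift of a goal is
`rank_first - rank_total`: positive when the goal gains importance once
indirect effects are counted. No normalisation is applied to influence
scores — raw sums are reported, since differences between adjacent ranks
are often small and normalisation would only obscure that.

**Composition percentages** round half away from zero
(212/272 = 77.94% → 78, 12/272 = 4.41% → 4, 48/272 = 17.65% → 18). The
three rounded percentages can sum to 99, 100 or 101; they are reported as
computed, with no largest-remainder correction.

## Workshop consensus

In the scoring protocol, small groups score subsets of pairs, double-check
their own scoring, and verify a set of interactions originally scored by
another group; all discrepancies are settled in plenary consensus. The
package models this as data: `find_discrepancies()` lists every ordered
pair scored by two or more groups whose scores differ by at least a
threshold (default 1 — any difference is discussed), and
`resolve_consensus()` assigns each such pair a single in-scale score. The
plenary step is human; it is replayed through the `manual` rule from an
explicit decisions table and never auto-resolved silently. The `median`
and `rounded-mean` rules exist for simulation studies; non-integral
midpoints round half away from zero so results stay on the scale.

```{r consensus}
g1 <- group_scores("G1", data.frame(source = "A", target = "B", score = 3))
g2 <- group_scores("G2", data.frame(source = "A", target = "B", score = 1))
recs <- find_discrepancies(list(g1, g2))
recs
resolve_consensus(recs, rule = "median")
```

## Indicator trends

To situate perception-based scores in observed data, the package
correlates goal indicator time series. Two conventions matter:

* **Direction recoding.** Indicators are re-oriented so that larger always
  means progress (mortality and poverty series are negated; access and
  coverage series pass through). Without this step the sign of a
  correlation is meaningless.
* **Paired observations.** Pearson's $r$ is computed only over years
  observed in *both* series, paired by exact year match. Sparse indicator
  tables tempt interpolation; we refuse — interpolating would invent data.
  The default minimum overlap is 3 shared years; pairs below it are
  reported as `insufficient_overlap`, and constant series yield a
  `degenerate` status rather than a silent $r = 0$. Observations published
  against an off-grid year (a poverty estimate labelled "(2003)" in a 2000
  column) are stored at their true year.

Goals carrying several indicators are correlated per indicator pair; no
goal-level composite is formed, because averaging indicators with
different units and dynamics would manufacture a series nobody measured.

```{r indicators}
tab <- cambodia_indicators()
u5 <- series_from_table(tab, "3", "under-five mortality rate (per 1000 live births)")
fa <- series_from_table(tab, "15")
progress_correlation(u5, fa)
```

The negative correlation between recoded child-mortality progress and
forest-area progress is the classic development trade-off signal: the two
indicators have moved in opposite directions over the shared years.

## Synthetic data: what it emulates and what it does not

The full 272-score Cambodia matrix is distributed only as supplementary
data of the original assessment, so the package ships a generator that
stands in for it. `generate_matrix()` draws each off-diagonal cell
independently: sign from `(p_positive, p_negative, p_zero)` — defaults
`(0.78, 0.04, 0.18)`, calibrated to the published composition of that
assessment — and magnitude uniform on $\{1, 2, 3\}$, since only the sign
composition is published. All generators take a single seed and are
byte-reproducible under it.

Two fixtures *are* reconstructible from the published text and ship as
data: the 17-goal registry (goals 1–16 plus goal 18, with goal 3 meaning
child health), and the child-health row and column of the matrix. The row
sums to 16, the column to 29, and the implied feedback loop through the
eight reciprocal pairs is $3{\cdot}1 + 3{\cdot}2 + 3{\cdot}2 + 2{\cdot}2 +
2{\cdot}2 + 1{\cdot}2 + 1{\cdot}3 + 1{\cdot}2 = 30$. Because a goal's
out-degree, in-degree and feedback loop depend only on its own row and
column, these numbers hold in *any* completion of the rest of the matrix
— the tests embed the fixture into random completions and assert exactly
that.

```{r fixture}
m <- embed_fixture(generate_matrix(goals = cambodia_goals(), seed = 1))
weighted_degree(m, "3", "out")
weighted_degree(m, "3", "in")
second_order_influence(m, "3", "3")
```

What the generator does **not** emulate: real stakeholder matrices are not
i.i.d. across cells — reciprocal pairs correlate, some goals are
systematically generous scorers, and zero cells cluster. A `reciprocity`
parameter is exposed for sensitivity studies, but a passing test under the
i.i.d. generator shows the *computations* are right, not that any
statistical claim transfers to real matrices.

`generate_group_scores()` simulates the double-scoring protocol: each
group reproduces a truth matrix except that each cell is independently
perturbed with probability `disagreement_rate`. A perturbed score is
resampled from the in-scale values within `max_shift` of the truth,
*excluding the truth itself* — so a perturbation always changes the score,
and the fraction of pairs on which any of $k$ groups deviates from truth
follows the independence law $1 - (1 - p)^k$ exactly. (Had we shifted and
clamped at the scale boundary, perturbations of $\pm 3$ scores would
silently vanish half the time and no clean law would hold.) Note the
number of *discrepancy records* is slightly smaller than the number of
perturbed pairs: two groups can be perturbed onto the same wrong value and
agree with each other.

## Problem sizes in the test suite

The statistical properties of the generators are checked at desk scale:
sign composition over 1,000 replicates of a 17-goal matrix (about 272,000
binomial draws, a three-standard-error band of ±0.24 percentage points)
and the disagreement law over 200 seeded simulations of two groups on a
17-goal truth. Oracle-equivalence suites run brute-force path enumeration
on random matrices of up to 8 goals, where exhaustive enumeration is
instant. The whole suite runs in seconds on one CPU.

## Known limitations

* Influence accounting stops at second order; no third-or-higher-order
  propagation and no eigenvector/Katz-style centralities. This mirrors the
  method the package implements, not a numerical constraint.
* The scoring itself is expert perception, and nothing in the arithmetic
  can repair a biased panel; the package's job is to make the downstream
  accounting exact, reproducible and auditable.
* The indicator-correlation layer describes coincident trends over a
  handful of paired years; it supports no causal reading, and computes no
  significance tests — with 3–5 paired observations they would mislead.
* The packaged indicator table is a reconstruction of a sparse published
  overview; a few column alignments in the source are ambiguous and the
  chosen years are documented in the fixture help page. The two series
  used in the worked examples are unambiguous.
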