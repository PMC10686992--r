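---
title: "Group mixing, adjusted assortativity and asymmetric homophily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group mixing, adjusted assortativity and asymmetric homophily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupmix)
```

## The measure and its two blind spots

For a network whose nodes carry a categorical attribute with $B$ groups,
the mixing matrix $\mathbf{e}$ stores the fraction of edges between each
group pair. Nominal assortativity summarises it as

$$r = \frac{\sum_i e_{ii} - \sum_i a_i b_i}{1 - \sum_i a_i b_i},
\qquad a_i = \sum_j e_{ij},\; b_i = \sum_j e_{ji},$$

the excess of intra-group edges over the product-of-marginals
expectation, rescaled so that $r = 1$ when every edge is intra-group.
`groupmix` implements this together with two corrections motivated by how
the measure behaves under a transparent generative null.

**The random homophily model.** Nodes belong to groups with fractions
$f_i$; the tendency of a group-$i$ node to connect to group $j$ is
$h_{ij} \in [0,1]$, with rows of $\mathbf{h}$ summing to one (for two
groups, $h_{01} = 1 - h_{00}$). The probability weight of an ordered edge
between groups $i$ and $j$ is $p_{ij} = f_i f_j h_{ij}$, so the expected
mixing matrix is $e_{ij} = p_{ij}/T$ with $T = \sum_{ij} p_{ij}$
(`expected_mixing()`). The model is equivalent to a simple stochastic
block model with known memberships.

**Blind spot 1: group size.** Substituting the expected matrix into $r$
(`analytic_r()`) shows the coefficient depends on $f_0$ even at fixed
tendencies: at $f_0 = 0.5$ it reduces to $h_{00} + h_{11} - 1$, but it is
dragged toward zero as the minority shrinks, and the more so the smaller
the minority. The *adjusted* mixing matrix $e^\star_{ij} =
e_{ij}/(f_i f_j)$, renormalized to sum to one, removes exactly this
dependence: the adjusted coefficient (`assortativity_adjusted()`,
closed form `analytic_r_adj()`) equals $h_{00} + h_{11} - 1$ for *every*
$f_0$.

**Blind spot 2: asymmetry.** Both coefficients are single numbers and
vanish identically on the locus $h_{00} = 1 - h_{11}$
(`zero_locus()`), where a homophilic minority faces a heterophilic
majority. The package therefore inverts the model: from
$e_{00} = E_{00}/E$, $e_{11} = E_{11}/E$ and $f_0$ alone,

$$\hat T = \frac{2 f_0 f_1}
  {1 - e_{00}\,(1 - f_1/f_0) - e_{11}\,(1 - f_0/f_1)},
\qquad
\hat h_{00} = e_{00}\,\frac{\hat T}{f_0^2},\quad
\hat h_{11} = e_{11}\,\frac{\hat T}{f_1^2},$$

implemented in `estimate_homophily()` / `homophily_fit()`. On the
expected fractions of the model the inversion is exact (the test suite
checks $10^{-10}$ agreement over a parameter grid); on sampled networks
it is consistent, with sampling error shrinking as the intra-group edge
counts grow.

## Conventions that matter

* **Marginals.** $a_i$ is always the row sum and $b_i$ the column sum.
  For undirected (symmetric) matrices this coincides with the usual
  $\sum_i a_i^2$ form; for asymmetric matrices only the row×column form
  makes the zero locus exact, so it is used universally.
* **Undirected accounting.** From undirected counts the matrix is
  symmetrized with half-weight off-diagonals, $e_{ij} = e_{ji} =
  E_{ij}/(2E)$, $e_{ii} = E_{ii}/E$. This is the unique convention under
  which the nine bundled empirical count records reproduce their
  published coefficients.
* **Renormalization of the adjusted matrix.** The rescaled entries
  $e_{ij}/(f_i f_j)$ do not sum to one; `adjust_mixing()` renormalizes
  by the grand sum before the coefficient is computed (the raw matrix is
  available with `renormalize = FALSE`). Renormalization is what makes
  the adjusted coefficient of the empirical records match their
  published values; without it the adjusted matrix is not a mixing
  matrix at all. At equal fractions the rescaling is uniform and cancels.
* **Estimator inputs.** The inversion uses the *raw* intra-group edge
  fractions $E_{00}/E$ and $E_{11}/E$, not the half-weight matrix
  entries; the two conventions agree on the diagonal but the code keeps
  the quantities separate (`e_intra` on the fit object) to avoid
  aliasing.
* **Group ordering.** `group_partition()` orders groups minority-first
  (ties broken lexicographically), so "group 0" language in two-group
  work always refers to the smaller group.

## The generators

`er_homophily()` places a fixed number `m_edges` of distinct edges. Each
proposal draws an ordered candidate pair with group-pair probability
exactly $f_i f_j$ — source node uniform, target group by the realized
fractions, target node uniform within that group — and accepts it with
probability $h_{ij}$. This makes the expected group-pair weights exactly
$p_{ij} = f_i f_j h_{ij}$, the law the analytic results assume. The
variant that draws the target uniformly among all other *nodes* has an
$O(1/n_{\min})$ deficit of intra-minority pairs (there are
$n_i(n_i - 1)$ ordered intra pairs, not $n_i^2$); at $n = 500$,
$f_0 = 0.1$, $h = 0.8$ that deficit biases $r$ by about $-0.004$,
comparable to the standard error of a 60-run ensemble, which is why the
group-first sampling was chosen.

Two details are deliberate and documented rather than hidden:

* A rejected proposal (probability $1 - h_{ij}$) consumes a step but no
  edge; a candidate that repeats an existing edge or is a self-pair is
  redrawn *without* consuming acceptance probability. Under the
  simple-graph constraint the realized mixing can deviate from the model
  law only through the duplicate-redraw channel, which redistributes
  edges from denser to sparser blocks; at the densities used in
  validation (≤ 5%, mean degree 8) the effect on counts is below one
  edge in a hundred.
* Ensembles (`mixing_ensemble()`) measure generated networks with the
  drawn source→target orientation retained (a directed count matrix).
  The model defines its mixing matrix over ordered pairs, and only that
  accounting lands on $r = 0$ along the asymmetric zero locus;
  symmetrizing the same networks shifts $r$ on the locus to about
  $-0.066$ at $f_0 = 0.1$ — a property of the undirected projection,
  not of the generator. For symmetric tendencies the two accountings
  agree in expectation. User-facing measurement of empirical data
  (`assortativity_network()`) stays undirected unless asked otherwise.

`ba_homophily()` grows a preferential-attachment network in which an
arriving group-$i$ node attaches to existing nodes with probability
proportional to $h_{ij} \times k_j$, seeded by a fully connected clique
of `m_per_node + 1` nodes with shuffled group labels. Its exact degree
dynamics are not part of the analytic results; it is exercised
qualitatively (neutral mixing gives $r \approx 0$; unequal groups push
$r$ below $r_{adj}$), and the estimator's `model` argument accepts only
`"er"` — inversion under preferential attachment would require the
degree-weighted analogue of $\hat T$, which is out of scope.

## Numerical choices and degenerate inputs

* All coefficients are kept at full double precision; the CLI rounds to
  4 decimals by default (`--digits`).
* A single group (or any matrix with $\sum_i a_i b_i = 1$) has no
  defined assortativity and errors rather than returning `NaN`.
* Out-of-range tendency estimates are *flagged* (`out_of_range`), never
  clipped: $\hat h_{00} > 1$ is evidence against the generative
  assumption, and clipping would hide it. For valid inputs
  ($E_{00} + E_{11} \le E$) the denominator of $\hat T$ is provably
  positive — it equals $e_{01} + e_{00} f_1/f_0 + e_{11} f_0/f_1$ — so
  the "inconsistent counts" guard can only trigger on inputs that are
  already inconsistent; it is kept as a defensive check.
* Self-loops are rejected (the model has no self-loop term); duplicate
  undirected edges collapse unless `multigraph = TRUE`.
* Generator seeds restore the caller's RNG state on exit; ensemble run
  $k$ uses `seed + k`, so any sub-ensemble is reproducible in isolation.

## What the synthetic validation does and does not show

The bundled validation (test suite) checks, at desk scale:

* closed form vs. matrix route, $10^3$ random parameter draws, $10^{-10}$;
* the equal-size reduction and zero locus to $10^{-12}$, and
  $f_0$-independence of the adjusted coefficient to $10^{-10}$;
* exact inversion of expected counts to $10^{-10}$ on a grid;
* 60-run ensembles at $n = 500$, $m = 2000$ (mean degree 8) on
  $f_0 \in \{0.1, 0.3, 0.5\} \times h \in \{0.2, 0.5, 0.8\}$, comparing
  ensemble means of $r$, $r_{adj}$, $\hat h_{00}$, $\hat h_{11}$ with
  their closed-form targets in 2-standard-error bands. Each of the 36
  bands individually carries the ~5% excursion risk any 2 SE check has,
  so the joint assertion is coverage-based: more than four excursions,
  or any excursion beyond 4 SE, fails. Two caveats are known and
  expected at this scale: the adjusted coefficient is a nonlinear
  function of small counts ($E_{00} \approx 23$ at $f_0 = 0.1$,
  $h = 0.8$), giving a finite-sample (Jensen) bias of roughly $-0.005$
  on $r_{adj}$, and the duplicate-redraw channel adds a comparable
  shift; both vanish as $m$ grows.

The generator emulates group-dependent tie formation with independent
edges and no degree heterogeneity beyond chance, which is exactly the
regime the closed forms describe. Passing these tests therefore shows
the implementation is faithful to the model — not that real networks
follow it. On empirical data the estimator should be read as
model-based: if the degree distribution is strongly heterogeneous the
`"er"` inversion mis-specifies $\hat T$, and an out-of-range flag or a
poor fit between $r_{adj}$ and $\hat h_{00} + \hat h_{11} - 1$ is the
first symptom.

## The empirical records

Nine published per-network summaries (node count, minority fraction,
total/intra/inter edge counts, reported $r$ and $r_{adj}$) are shipped
as a plain-text fixture (`empirical_networks()`). The reported
coefficients are printed to two decimals and the minority fractions are
rounded the same way, so `empirical_regression()` asserts agreement
within ±0.01 — at that tolerance all eighteen values recompute exactly
(two-decimal rounding of the recomputation matches the print for every
record). In the source the intra/inter count columns appear in an order
inconsistent with their header; the shipped records use the unique
assignment under which every reported coefficient recomputes, and the
regression check keeps that choice executable.

Worth knowing when comparing with the networks' original descriptions:
the nominal coefficient is lower than the adjusted one for all records
except the most balanced network (SocioPatterns 5, $f_0 = 0.44$), where
they agree — the group-size bias disappears as $f_0 \to 0.5$, exactly as
the closed form predicts.

## Limitations

* The estimator is two-group only and assumes the random-mixing null;
  there is no uncertainty quantification for $\hat h$ (bootstrap over
  networks is the pragmatic route and is easy to script over
  `mixing_ensemble()`).
* Weighted, bipartite and temporal networks are out of scope; edges are
  counted, not weighed.
* The preferential-attachment generator is a validation device, not a
  calibrated model of any dataset.
* Beyond two groups the scalar-tendency shorthand splits off-diagonal
  mass evenly; strongly structured multi-group mixing should pass a full
  row-stochastic $\mathbf{h}$ instead.
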