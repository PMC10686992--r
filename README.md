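# groupmix

Measuring group mixing and homophily in node-attributed networks.

## The problem

Nominal (discrete) assortativity is the standard single-number summary of
how strongly a network's edges stay within groups defined by a categorical
node attribute (gender, race, protein class, ...). It is built on the B×B
mixing matrix **e**, whose entry e_ij is the fraction of edges connecting
group *i* to group *j*:

    r = (Σᵢ e_ii − Σᵢ aᵢ bᵢ) / (1 − Σᵢ aᵢ bᵢ),

with marginals aᵢ = Σⱼ e_ij and bᵢ = Σⱼ e_ji. The coefficient runs from −1
(fully disassortative) through 0 (no preference) to +1 (fully assortative).

On realistic data this measure has two failure modes that `groupmix`
addresses:

1. **Group-size bias.** Smaller groups have quadratically fewer
   opportunities to connect among themselves. Under a random tie-formation
   model with group fractions f and intra-group tendencies h (edge weight
   p_ij = fᵢ fⱼ h_ij), r depends on the minority fraction f₀ even when the
   mixing tendencies are fixed: at h = 0.8, r slides from 0.6 at equal
   sizes to 0 as the minority vanishes. The **adjusted nominal
   assortativity** r_adj removes the bias by rescaling the mixing matrix,
   e*_ij = e_ij / (fᵢ fⱼ) (renormalized to sum to 1); under the model it
   equals h₀₀ + h₁₁ − 1 for every f₀.

2. **Asymmetric mixing.** Any single-valued coefficient collapses the
   whole mixing matrix; on the locus h₀₀ = 1 − h₁₁ both r and r_adj are
   exactly zero even though the minority can be strongly homophilic while
   the majority is strongly heterophilic. `groupmix` inverts the model
   analytically to recover both tendencies from four aggregate numbers
   (E, E₀₀, E₁₁, f₀):

       ĥ₀₀ = (E₀₀/E) · T̂ / f₀²,   ĥ₁₁ = (E₁₁/E) · T̂ / f₁²,
       T̂ = 2 f₀ f₁ / (1 − e₀₀(1 − f₁/f₀) − e₁₁(1 − f₀/f₁)).

The package also ships seeded generative models (an Erdős–Rényi-style
model with tunable group mixing and a preferential-attachment variant)
used to validate the closed forms, and the published aggregate
gender-mixing counts of nine empirical networks (APS, GitHub, DBLP
1980–2010, INFORMS, two SocioPatterns classes) with a regression check
that recomputes all eighteen reported coefficients.

## Worked example

A 500-node network generated on the zero locus (h₀₀ = 0.8, h₁₁ = 0.2,
f₀ = 0.1) looks unmixed to both coefficients, but the analytical inversion
exposes the hidden asymmetry:

```r
library(groupmix)
net <- er_homophily(n = 500, f0 = 0.1, h = c(0.8, 0.2), m_edges = 2000, seed = 42)
assortativity_network(net$edges, net$labels)
#> Nominal assortativity r = -0.0735
#>   intra-group edge fraction 0.6520, expected 0.6758
summary(homophily_fit(net$edges, net$labels))
#> Asymmetric homophily estimate (random homophily model)
#>   h00 (minority) = 0.7778
#>   h11 (majority) = 0.2026
#>   T (sum of p_ij)  = 0.2637
#>   nominal r        = -0.0735
#>   adjusted r       = -0.1115
#>   h00 + h11 - 1    = -0.0195
#>   inputs: E = 2000, E00 = 59, E11 = 1245, f0 = 0.1000
```

r ≈ −0.07 would suggest a near-neutral network; the recovered tendencies
(ĥ₀₀ ≈ 0.78, ĥ₁₁ ≈ 0.20) show a strongly homophilic minority facing a
strongly heterophilic majority — the generating values were 0.8 and 0.2.

Aggregate counts work the same way. The GitHub collaboration network
(women are 6% of the nodes) goes from an apparently negligible r to a clearly
assortative r_adj:

```r
assortativity_counts(E00 = 7432, E01 = 149069, E11 = 1381069, f0 = 0.06)
#>          r      r_adj
#> 0.03946597 0.15155975
```

A thin command-line interface wraps the same functions:

```sh
exec/groupmix assort-counts --e00 7432 --e01 149069 --e11 1381069 --f0 0.06
exec/groupmix estimate --e 1000 --e00 400 --e11 400 --f0 0.5
exec/groupmix simulate --model er --n 500 --f0 0.3 --h00 0.8 --m-edges 2000 \
    --seed 7 --out-edges edges.tsv --out-attrs groups.tsv
exec/groupmix empirical --check
```

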