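# thresholdPGG

Evolution of cooperation in the multi-player **threshold public goods
game** with a payoff **redistribution mechanism**, under
**aspiration-driven stochastic dynamics** with mutation, in a finite
well-mixed population.

Who it is for: researchers in evolutionary game theory who want the exact
mutation–selection stationary analysis of this model, its closed-form
weak- and strong-selection approximations, and reproducible parameter
sweeps — from R or from a shell.

## The model in brief

Groups of size *d* are sampled from a population of *N* individuals.
Cooperators pay *c* into a pot; if at least *m* members cooperate the pot
is multiplied by *r* and shared equally, otherwise nobody is paid. Every
member then surrenders a fraction *τ* of its payoff to a group pot that is
redistributed equally ("second-order payment"), giving the payoff vectors

  a_k = ((k+1)/d)(r−τ)c + τc  (k ≥ m−1),  b_k = (k/d)(r−τ)c + c  (k ≥ m),

with zeros below the threshold. Individuals update by satisficing: they
switch strategy with Fermi probability 1/(1+e^{−ω(α−π)}) comparing their
expected payoff π (hypergeometric over group compositions) with an
aspiration level α, and mutate at rate δ. The cooperator count performs a
reversible birth–death chain; its stationary law follows from detailed
balance as a normalized product of stepwise ratios h(i,ω), computed here
entirely in log space. The headline quantity is the **average abundance**

  X_A(ω) = Σ_j (j/N) ϑ_j(ω),

the long-run cooperator fraction; cooperation is favoured when
X_A > 1/2. The package provides the exact X_A, a first-order
weak-selection expansion (and from it the **critical multiplication
factor** r\* and the **abundance-maximising threshold** m\*), a
strong-selection approximation with validity diagnostics, a Monte-Carlo
simulator as an independent cross-check, and a config-driven sweep runner.

## Worked example

```r
library(thresholdPGG)

gp <- game_params(N = 100, d = 15, m = 8, r = 8, c = 1, tau = 0.25)
ap <- aspiration_params(omega = 4, alpha = 1, delta = 0.03)

average_abundance_exact(gp, ap)
#> Average abundance X_A = 0.533651  [method: exact]

strong_selection_abundance(gp, ap)
#> Average abundance X_A = 0.534013  [method: strong]
#>   validity regime: neither

critical_r(d = 15, m = 8, tau = 0.25)
#> [1] 2.0178

optimal_threshold(d = 15, r = 8, tau = 0.25)
#> [1] 9
```

At these parameters cooperation is favoured (X_A > 1/2, consistent with
r = 8 exceeding the critical factor 2.02), the strong-selection
approximation is within 4·10⁻⁴ of the exact value at ω = 4, and the
weak-selection abundance over m = 1..14 peaks at the closed-form optimal
threshold m = 9. The Monte-Carlo simulator agrees with the exact value
within its batch-means standard error:

```r
estimate_abundance(gp, ap, sim_config(n_steps = 2e6, burn_in = 2e5, seed = 7))
#> Monte-Carlo abundance estimate: X_A = 0.53399 (batch-means SE 0.00071)
#>   2000000 steps, 200000 burn-in, seed 7
```

## Command line

The installed `exec/thresholdpgg` script exposes the same machinery:

```sh
thresholdpgg abundance --m 8 --omega 4 --method exact
thresholdpgg critical-r --d 15 --m 8 --tau 0.25
thresholdpgg optimal-m --d 15 --r 8 --tau 0.25
thresholdpgg sweep --config sweep.yaml --out sweep.csv --seed 1
```

where `sweep.yaml` is a flat key-value document, e.g.

```yaml
vary: m
grid: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14]
methods: [weak, exact]
omega: 0.5
```

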