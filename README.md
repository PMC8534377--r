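# funcstate

Multiscale emergent functional states, spectral entropy and
randomized-weight nulls for weighted undirected networks.

## The problem

The adjacency matrix of a biological network — a fungal mycelium, a slime
mould, a vascular or neural system — only records *direct* interactions.
The communication that actually matters happens at every scale: signals
released at one node diffuse through the whole topology and, within a
propagation time τ, exchange flow with nodes far beyond the first
neighbourhood. `funcstate` implements an information-dynamics framework
that makes this multiscale communication structure explicit and
quantifies its diversity:

- **Diffusion propagator.** A field φ on the nodes evolves by the network
  diffusion equation ∂τ φ = −L φ, with L = K − W the combinatorial
  Laplacian (strength diagonal minus weight matrix). Its solution is the
  heat kernel U(τ) = e^{−τL}, which is symmetric and doubly stochastic on
  undirected networks.
- **Emergent functional state.** W̃(τ) = φ₀ U(τ) with the diagonal removed:
  a network whose link i–j carries the flow exchanged between i and j
  within time τ. At small τ it linearises to φ₀τW (the structure); at
  large τ every entry tends to φ₀/N (full entanglement).
- **Functional modules.** Louvain modularity maximisation applied to the
  dense W̃(τ) finds groups of nodes that exchange more flow internally
  than externally — many neighbourhood-like modules at small τ, few large
  ones past the diffusion time τ_d = 1/λ₂.
- **Von Neumann entropy.** The network Gibbs state ρ(τ) = U(τ)/Tr U(τ)
  has eigenvalues p_ℓ = e^{−τλ_ℓ}/Z; S(τ) = −Σ p_ℓ log p_ℓ measures the
  diversity of flow pathways, falling from log N to 0 (log C on a network
  with C components). The number of functional modules scales
  log-linearly with S across scales.
- **RWCM null.** The randomized-weight configuration model keeps the edge
  positions (hence connectivity — rewiring nulls shatter sparse networks)
  and redraws the weights uniformly, rescaled to conserve total weight.
  Comparing S(τ) against it isolates the contribution of structured
  weights to flow diversity.

Scales are compared across networks via the rescaled parameter τ/τ_d,
swept log-spaced over [10⁻¹⁰, 10].

## Worked example

```r
library(funcstate)

net <- generate_network("watts_strogatz", 100, mean_degree = 4,
                        p_rewire = 0.05, seed = 1)
dec <- spectral_decomposition(net)
dec
#> <spectral_decomposition> N = 100, components = 1, lambda_2 = 0.0930165, tau_d = 10.7508

sw <- sweep_network(net, sweep_config(n_points = 6, n_restarts = 5, seed = 1))
dplyr::inner_join(sw$entropy[c("ratio", "entropy")],
                  sw$modules[c("ratio", "n_modules")], by = "ratio")
#>           ratio  entropy n_modules
#> 1  0.0000000001 4.61             9
#> 2  0.0000000158 4.61             9
#> 3  0.00000251   4.61             9
#> 4  0.000398     4.61             9
#> 5  0.0631       3.79             7
#> 6 10            0.000524         1
```

Entropy starts at log 100 = 4.61 nats where all 100 diffusion modes are
alive, and collapses to ≈0 past the diffusion time; the functional
modules coarsen from 9 to 1 over the same sweep. The two observables move
together — the pooled log-linear fit:

```r
glance(modules_entropy_relation(
  dplyr::inner_join(sw$entropy, sw$modules, by = "ratio")))
#>   slope intercept r_squared     n
#> 1 0.478    0.0197     0.996     6
```

Functional modules at one intermediate scale, and the null comparison on
a transport-weighted tree (weights ∝ edge betweenness, mimicking
conductance-structured biological cords):

```r
functional_partition(dec, 0.1 * dec$diffusion_time, seed = 1)
#> <partition> 100 nodes in 6 modules, Q = 0.5667 (tau = 1.075)

tree <- transport_weights(generate_network("barabasi_albert", 100, m = 1, seed = 2))
eg <- entropy_gap(tree, rescaled_tau_grid(tree, n_points = 6), n_null = 20, seed = 1)
eg[c("ratio", "s_real", "s_null_mean", "gap")]
#>           ratio   s_real s_null_mean      gap
#> 1  0.0000000001 4.61        4.61     8.26e-14
#> 2  0.0000000158 4.61        4.61     2.06e-09
#> 3  0.00000251   4.61        4.61     4.93e-05
#> 4  0.000398     4.60        4.51     9.25e-02
#> 5  0.0631       4.40        2.68     1.71e+00
#> 6 10            0.000551    0.000513 3.76e-05
```

The empirical and null curves agree at both extremes and separate at
middle scales — the structured weights keep flow diversity 1.7 nats above
the randomized-weight null near τ_d.

Each result type has a plot: `plot_entropy_curve()`,
`plot_strength_curve()`, `plot_module_curve()`, `plot_entropy_gap()`, and
`autoplot()` on a sweep. A command-line interface (`exec/funcstate`)
wraps `generate`, `sweep`, `rwcm`, `compare`, `corpus` and `plot` for
shell pipelines over edge-list files.

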