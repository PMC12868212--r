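# fraccomm

Stability-aware community detection on **dynamic graphs** with
fractional-order node dynamics, Laplacian spectral filtering, and Lyapunov
stability monitoring.

Graph neural embeddings on evolving networks are prone to *hallucinated*
communities: spurious partitions spawned by high-frequency Laplacian
eigenmodes that amplify noise faster than the dynamics can damp it.
`fraccomm` is for network scientists — in systems biology (protein
interaction and co-expression networks), social-network analysis, and
infrastructure monitoring — who need community assignments over a sequence
of graph snapshots *together with a certificate of how stable those
assignments are*.

## The model

Node states `X_t ∈ R^{n×d}` evolve under a Caputo fractional-order equation

    D^α X = −C X + W f(X) + U,      α ∈ (0, 1],

discretised by the truncated Grünwald–Letnikov operator with memory horizon
`H` (weights `w_j = (−1)^j C(α, j)`; `α = 1` recovers forward Euler).  Each
snapshot's Laplacian `L_t = D_t − A_t = U Λ Uᵀ` supplies a graph Fourier
basis; embeddings are low-pass filtered with a decay kernel `φ(λ) =
exp(−τλ)`, and every retained eigenmode is scored by the **hallucination
index**

    η_k = λ_k F − c_k,

positive exactly when the mode's forcing gain outweighs its leakage.  The
**stability margin**

    ρ = λ_min(PC) − F‖PW‖,    AᵀP + PA = −2I,  A = −(C − F W_sym),

summarises distance from instability; with ρ > 0 the deviation from a
hallucination-free trajectory obeys the Mittag-Leffler bound
`‖e(t)‖ ≤ ‖e(0)‖ E_α(−ρ t^α) + λ_max(P) ū / ρ`.  A closed-form ridge
refinement shrinks unstable-mode energy before Newman–Girvan modularity
clustering; training optimises coupling, leakage and kernel rate under the
stability-regularised objective `L = L_recon + λ_ρ(−ρ) + λ_η Σ_k max(0, η_k)`.

A key property of the truncated fractional operator: its discarded weight
tail `S_H(α) = Σ_{j≤H} w_j ≈ H^{−α}/Γ(1−α)` acts as extra leakage, so lower
fractional orders *mechanically* enlarge ρ and push η negative — the
long-memory damping that suppresses hallucinations.

## Worked example

```r
library(fraccomm)

g <- generate_dynamic_sbm(sbm_config(n = 200, k = 4, p_in = 0.3, p_out = 0.02,
                                     n_snapshots = 5, rewire = 0.02, seed = 1))
fit <- fraccomm_fit(g, fraccomm_config(epochs = 30), seed = 1)
fit
#> <fraccomm_fit> 30 epoch(s); s=0.1710 c=0.3076 tau=0.4885
#>   final loss 38.5538, rho 0.1564, eta_max 2.0239, mean Q 0.5448

fit$stability
#> # A tibble: 5 × 6
#>   snapshot   rho rho_method eta_max n_unstable modularity
#>      <int> <dbl> <chr>        <dbl>      <int>      <dbl>
#> 1        0 0.156 commuting     2.01         49      0.581
#> 2        1 0.156 commuting     2.01         49      0.563
#> 3        2 0.156 commuting     2.02         49      0.558
#> 4        3 0.156 commuting     2.02         49      0.547
#> 5        4 0.156 commuting     2.00         49      0.476

evaluate_timeline(fit$timeline, graph_labels(g))$summary
#> # A tibble: 1 × 2
#>     ari   nmi
#>   <dbl> <dbl>
#> 1 0.974 0.973
```

Reading the output: the fitted coupling scale `s`, leakage `c` and kernel
rate `tau` give a per-snapshot stability margin `ρ ≈ 0.16 > 0` (the dynamics
are certified stable, with `rho_method = "commuting"` because the pipeline's
`C = cI`, `W = sÂ` parameterisation diagonalises the Lyapunov condition
exactly).  `eta_max ≈ 2` with 49 of the 50 retained modes above threshold
says the high-frequency end of the spectrum would amplify noise if left
unfiltered — those modes are attenuated and shrunk, not clustered on.  The
timeline recovers the four planted communities almost perfectly
(ARI = 0.974) with per-snapshot modularity around 0.55; labels are matched
across snapshots by optimal assignment.

`tidy()`, `glance()` and `autoplot()` work on fits, detections and
`alpha_sweep()` results; `community_detect()` is the training-free inference
path.  A command-line front end is installed at
`system.file("cli", "fraccomm", package = "fraccomm")` with subcommands
`simulate`, `fit`, `detect`, `stability`, `evaluate`, `sweep`.

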