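# gmcnet

Graph-neural-network module clustering for weighted gene co-expression
network analysis (WGCNA).

## What it does, and for whom

WGCNA groups genes into modules from a topological overlap matrix (TOM)
built on pairwise expression correlations. The classical route —
average-linkage hierarchical clustering of the TOM dendrogram — sees only
topology: two genes with similar expression profiles but modest
topological overlap can be split into different modules, and early merges
are never revisited. `gmcnet` implements gmcNet, an unsupervised
graph-neural-network clusterer that uses the expression matrix and the
TOM simultaneously, for analysts who already have a normalized gene ×
sample expression table (e.g. RPKM) and, optionally, sample traits.

The pipeline:

1. **Network construction.** Unsigned adjacency
   `a_ij = |cor_ij|^β`, plus positive-only and negative-only channels,
   each with its own soft-threshold power (defaults β = 6 / 9 / 10).
   Topological overlap

   ```
   t_ij = (l_ij + a_ij) / (min{k_i, k_j} + 1 − a_ij),
   l_ij = Σ_{u≠i,j} a_iu a_uj,   k_i = Σ_{u≠i} a_iu
   ```

   and the message-passing operator `T̃ = D^{-1/2} (T − I) D^{-1/2}`.
2. **CEPR embedding.**
   `X̄ = ReLU(T̃ X W_c + T̃_p X W_p + T̃_n X W_n + X W_s)`, embedding each
   gene into `m′ = 8` dimensions from its full/positive/negative
   co-expression neighbourhoods plus a single-expression skip term.
3. **Module classifier.** `M = softmax(X̄ W_m)`, an n × k assignment
   probability matrix; hard labels are row argmaxes.
4. **Training.** Full-batch Adam on the MinCut-style loss
   `L = λ·L_c + L_o` with
   `L_c = −Tr(MᵀT̃M)/Tr(MᵀD̃M)` and
   `L_o = ‖ MᵀM/‖MᵀM‖_F − I_k/√k ‖_F`;
   100 warm-up epochs (λ = 0, lr 0.01) then λ = 2.6, lr 0.001, up to
   5,000 epochs, early-stopped when L_o exceeds τ = 0.8. Gradients are
   analytic (single-layer model) and finite-difference verified.
5. **Evaluation.** Graph modularity `Q = (1/s) Σ (t_ij − c_i c_j/s) δ[i,j]`,
   module eigengenes (first PC per module), the DEM signal
   `Σ −log10(p_lt)·ρ[l,t]` over significant module–trait regressions,
   hub genes (top 25 by eigengene correlation), and a k sweep.
   Baselines: average-linkage HC and PAM K-medoids on `1 − T`, K-means
   on expression.
6. **Synthetic data.** A planted-module generator (latent factors,
   anti-correlated gene fractions, background genes, trait effects) so
   the whole pipeline is testable without external data.

## Worked example

```r
library(gmcnet)

# simulate the reference study conditions: 4 planted modules of 100 genes,
# 100 background genes, 20 samples, one trait per module factor
fx <- simulate_expression(fixture_spec(seed = derive_seed(1, "fixture")))

run <- run_gmcnet_pipeline(fx$expr, fx$traits,
                           config = default_run_config(k = 4, filter_alpha = 1))
run
#> gmcnet_run: 500 genes x 20 samples
#> gmcnet_fit: 500 genes -> 4 modules; 5000 epochs
#> module sizes: 126 126 123 125
#> final losses: cut -0.9209 ortho 0.0137 total -2.3807
#> modularity Q = 0.6868; DEM signal = 40.3390
```

The four planted modules are recovered (the ~25 background genes folded
into each module are noise that every method must place somewhere); the
cut loss near −1 says nearly all topological overlap lies within modules,
and the low orthogonality loss says module sizes stayed balanced. Each
module's eigengene is significant exactly for its planted trait:

```r
round(run$dem$pvalues, 5)
#>     trait1  trait2  trait3  trait4
#> K1 0.00000 0.08076 0.02929 0.88470
#> K2 0.02075 0.04430 0.00000 0.47339
#> K3 0.54928 0.00000 0.33501 0.24285
#> K4 0.58791 0.17887 0.71515 0.00000

head(hub_genes(run$expr, run$fit$labels, module_id = 1, top_n = 5))
#>    gene_id       cor
#> 1 gene0011 0.9750126
#> 2 gene0003 0.9748039
#> 3 gene0061 0.9725506
#> 4 gene0052 0.9696842
#> 5 gene0067 0.9680161
```

Passing `out_dir =` writes `modules.tsv`, `probs.tsv`,
`loss_history.tsv`, `metrics.json` (keys `modularity`, `dem_signal`,
`k`, `n_genes`, `epochs_run`, `stopped_early`), `dem_table.tsv`,
per-module hub lists, a `config.yaml` snapshot and a checksummed
manifest. A thin command-line wrapper with subcommands `simulate`,
`network`, `cluster`, `baselines`, `evaluate` and `sweep` is installed at
`system.file("cli", "gmcnet.R", package = "gmcnet")`.

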