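---
title: "Module clustering for weighted gene co-expression networks with gmcnet"
author: "gmcnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module clustering for weighted gene co-expression networks with gmcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Weighted gene co-expression network analysis (WGCNA) groups thousands of
genes into modules so that system-level function can be read off a handful
of module summaries instead of individual transcripts. The classical
pipeline builds a topological overlap matrix (TOM) from pairwise
correlations and cuts an average-linkage dendrogram. Because the dendrogram
sees only topology, two genes with similar expression but modest
topological overlap can end up in different modules, and an early
agglomeration is never revisited.

gmcNet addresses this by clustering genes with a small graph neural
network that sees *both* signals at once: the single-level expression
matrix and three topological overlap channels (all correlations,
positive-only, negative-only). A message-passing layer — the co-expression
pattern recognizer (CEPR) — embeds each gene, and a softmax classifier
assigns it to one of $k$ modules. Training is unsupervised, driven by a
MinCut-style cut loss plus an orthogonality (balance) loss.

## Network construction

For genes $i,j$ with Pearson correlation $cor_{ij}$, the unsigned
adjacency is $a_{ij} = |cor_{ij}|^\beta$. The positive channel keeps only
positive correlations ($cor_{ij}^\beta$, else 0), the negative channel only
negative ones ($|cor_{ij}|^\beta$, else 0). Topological overlap is

$$t_{ij} = \frac{l_{ij} + a_{ij}}{\min\{k_i,k_j\} + 1 - a_{ij}},
\qquad l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj},\quad
k_i = \sum_{u \ne i} a_{iu}.$$

The neighbour sums exclude the two endpoint genes and the connectivity
excludes self-adjacency. This is the original WGCNA convention; with
unrestricted sums and unit self-adjacency $t_{ij}$ can exceed 1, which
breaks its contract as a similarity measure, so the restricted form is the
only self-consistent reading. Under it the triple-loop definition and the
package's vectorized implementation agree to machine precision, which the
test suite asserts on random adjacencies.

For message passing the TOM is zero-diagonal degree-normalized:

$$T_z = T - I, \qquad \tilde T = D^{-1/2} T_z D^{-1/2},
\qquad D = \mathrm{diag}(T_z \mathbf{1}).$$

A gene that is fully disconnected in the *full* channel makes $D$ singular
and is reported as an error (the caller should drop it or lower $\beta$).
In the sign-restricted channels isolation is expected — a gene may simply
have no negative partners — so those rows are left at zero and the gene
receives no message through that channel.

**Soft-threshold powers.** Defaults are $\beta = 6, 9, 10$ for the full,
positive and negative channels. A scale-free fit helper is provided: for
each candidate $\beta$ the connectivities are binned into 10 equal-width
bins and the fit index is $-\mathrm{sign}(\text{slope}) \cdot R^2$ of the
log–log regression of bin frequency on bin mean, so an exactly decaying
power law scores $+1$. Equal-width bins are essential: equal-count
(quantile) bins would make every bin frequency identical by construction
and the regression degenerate. The fit is advisory — planted-block
networks, like many small designed experiments, are not scale-free at any
power, and the channel defaults are configuration, not the argmax of the
fit.

**Trait filter.** Before network construction, genes can be filtered by
trait relevance: the exact $t$-test on the Pearson correlation with each
trait ($m-2$ degrees of freedom), keeping genes significant at
$\alpha = 0.1$ for *at least one* trait (mode `"any"`). The stricter
`"all"` mode (significant for every trait) is exposed behind a flag; with
four traits it retains on the order of $\alpha^4$ of null genes and is
rarely what an analyst wants.

## The model

With expression $X \in \mathbb{R}^{n \times m}$ and the three normalized
TOMs, the CEPR embedding is

$$\bar X = \mathrm{ReLU}\!\left(\tilde T X W_c + \tilde T_p X W_p
  + \tilde T_n X W_n + X W_s\right) \in \mathbb{R}^{n \times m'},$$

with $m' = 8$ by default, and the module assignment is the row softmax
$M = \mathrm{softmax}(\bar X W_m) \in \mathbb{R}^{n \times k}$. The
classifier is exactly the printed single linear map plus softmax — no
hidden layer. Hard labels are row argmaxes, ties broken deterministically
toward the lowest module index.

### Loss

$$\mathcal{L} = \lambda\,\mathcal{L}_c + \mathcal{L}_o, \qquad
\mathcal{L}_c = -\frac{\mathrm{Tr}(M^\top \tilde T M)}
                      {\mathrm{Tr}(M^\top \tilde D M)}, \qquad
\mathcal{L}_o = \left\| \frac{M^\top M}{\|M^\top M\|_F}
  - \frac{I_k}{\sqrt k} \right\|_F,$$

with $\tilde D = \mathrm{diag}(\tilde T \mathbf 1)$ and $\lambda = 2.6$.
$\mathcal{L}_c \in [-1, 0]$ rewards keeping edge weight inside modules;
$\mathcal{L}_o \in [0, 2]$ is zero exactly for balanced, orthogonal
assignments. The orthogonality term uses a *minus* sign between the
normalized Gram matrix and $I_k/\sqrt k$, the MinCutPool form: only with
the minus sign is 0 the optimum, and only then does an early-stopping
threshold of $\tau = 0.8$ make sense (a uniform random assignment starts
at $\mathcal{L}_o = 1$ and warm-up drives it toward 0; with a plus sign
the loss is bounded away from zero and training would stop immediately).

### Training

All $n$ genes are one batch (the graph is global; dense $n \approx 5000$
is desk-scale). Weights are Glorot-uniform initialized from the run seed.
Optimization is Adam with the two-phase schedule: 100 warm-up epochs with
$\lambda = 0$ and learning rate $0.01$ — balancing module sizes before any
cut optimization, which prevents empty modules — then $\lambda = 2.6$ at
learning rate $0.001$ for up to 5,000 epochs total. After warm-up,
training stops at the first epoch whose $\mathcal{L}_o$ exceeds
$\tau = 0.8$, and the assignment of that epoch is returned ("the
assignment at the end of training"); evaluating the stop only after
warm-up matters because the initial random assignment already exceeds
$\tau$. Empty modules, if any remain, are reported in the fit summary but
not re-split.

Because the model is a single CEPR layer plus a linear softmax classifier,
the gradient of the loss has a short closed form and the package
implements it analytically (softmax and ReLU backpropagation around the
two loss terms) rather than through an autodiff framework; the test suite
verifies every weight gradient against central finite differences. The
per-channel products $\tilde T X$ are constants and are computed once per
fit. A 500-gene, 5,000-epoch fit takes a few seconds on one CPU core.

## Evaluation

**Modularity.** For a partition $\delta$,
$Q = \frac1s \sum_{ij} (t_{ij} - c_i c_j / s)\,\delta[i,j]$ with
$c_i = \sum_u t_{iu}$, $s = \sum_{ij} t_{ij}$, computed on the
zero-diagonal $T_z$: unit self-overlap would add a constant,
partition-independent term, and the degree-matched null concerns edges
between distinct genes. $Q = 0$ exactly for the single-module partition,
and the implementation matches an independent graph-library oracle on
random cases.

**Module eigengenes.** The first principal component over samples of the
module's gene-standardized submatrix (the WGCNA convention), unit norm,
sign-aligned with the module's mean standardized profile so hub
correlations are reproducible across platforms; when that profile is
degenerate (a module that is half anti-correlated) the largest-magnitude
gene loading is made positive instead.

**DEM signal.** Each trait is regressed on each module eigengene
(trait as response; for a simple regression the slope p-value is
direction-symmetric, so the direction affects only the sign convention of
the reported coefficients). A module–trait cell is significant at raw
$p \le 0.05$ — no multiple-testing correction, matching the usual
module–trait star heatmaps; a correction flag would be a one-line change
but would alter the metric. The DEM signal is
$\sum_{l,t} -\log_{10}(p_{lt})\,\rho[l,t]$ over significant cells.

**Hub genes.** Within a module, genes ranked by correlation with the
eigengene; the top 25 are reported by default.

**Baselines.** Average-linkage hierarchical clustering and PAM K-medoids
on the topological distance $1 - T$, and Hartigan–Wong K-means with 10
restarts on the raw expression rows. All three take $k$ as an input: the
dynamic-tree-cut procedure that would choose $k$ for HC is out of scope
here, and $k$ is an explicit parameter everywhere downstream. Linkage is
exposed as an argument since the convention (average) is a choice, not a
theorem. No baseline gets a noise/grey module — every gene is assigned —
mirroring the classifier, which also assigns every gene.

## The synthetic generator

`simulate_expression()` plants co-expression modules: one latent Gaussian
factor per module per sample; a module gene is
$\pm \lambda_w f_j + \varepsilon$, with the loading $\lambda_w$ chosen so
that two same-sign genes correlate at `within_module_cor`
($\lambda_w^2 / (\lambda_w^2 + \sigma^2) = w$, an identity the tests check
empirically). A fraction of each module loads negatively to exercise the
negative TOM channel. Background genes are i.i.d. with the same marginal
variance as module genes (so expression-space methods cannot separate them
by variance alone). Traits are linear in chosen module factors plus noise.
Background genes carry true label $-1$ and are excluded from recovery
scoring, since every clusterer here assigns them somewhere.

Defaults — the package's reference study conditions — are 500 genes by 20
samples: four modules of 100 genes at within-module correlation 0.8 with a
quarter of each module anti-correlated, 100 background genes, and four
traits, each driven by one module factor with effect 2 against unit trait
noise (a strong but not deterministic module–trait link, regression
$p \sim 10^{-7}$ at $m = 20$ when the module is recovered).

What the generator does *not* emulate: count-level noise (negative
binomial reads, library sizes — the inputs here are already normalized
expression), correlated or hierarchically nested factors, overlapping
module membership, heavy-tailed expression, batch effects. Passing tests
on these fixtures demonstrate correctness of the algorithms and recovery
under clean planted structure; they do not demonstrate that gmcNet beats
any baseline on real tissue data.

One consequence is worth stating plainly: at within-module correlation
0.8 the planted structure is easy, and every topology-aware method —
gmcNet and PAM K-medoids in particular — recovers the planted modules
exactly. Their modularity then differs only in where the background genes
land (differences of order $10^{-4}$ to $10^{-3}$), so strict "method A
beats method B" orderings among tied methods are coin flips on this
fixture, unlike on real data where module boundaries are genuinely
ambiguous. Average-linkage HC is the exception: background genes merge
last, so a forced cut at small $k$ can yield one giant cluster plus
singletons and a modularity near 0 — a real and known fragility of
average linkage under outliers, not an implementation artifact.

## Numerical choices and degenerate inputs

- Softmax rows are max-shifted before exponentiation (shift-invariant,
  overflow-safe); row sums are exactly renormalized.
- Argmax ties break toward the lowest module index, everywhere.
- Correlations are symmetrized and clamped to $[-1, 1]$ after `cor()` to
  absorb floating-point overshoot before powering.
- Zero-variance genes are rejected by name at load (or dropped with a
  count when reading files); constant traits are rejected at alignment.
- `cut_loss` errors on an all-zero degree graph; `ortho_loss` on an
  all-zero assignment; `normalize_tom` names the disconnected gene.
- A non-finite training loss aborts with the epoch index rather than
  continuing silently.
- One top-level seed derives fixed per-component seeds (fixture, weight
  initialization, K-means, K-medoids), so runs are reproducible from a
  single knob and components stay independent.

## Problem sizes used by the test suite

Unit tests run on 150-gene, 3-module fixtures with shortened schedules
(a few hundred epochs); the end-to-end property checks use the full
reference conditions above with the complete 5,000-epoch schedule, which
fits comfortably in a few seconds per fit on one CPU core. DEM-signal
calibration uses 400-gene, 50-sample fixtures: 50 samples give the
planted module–trait regression enough resolution ($p \sim 10^{-60}$)
that the planted cell's share of the DEM mass cleanly separates from
chance significances among null cells, and 63 null fixtures supply just
over 1,000 cells for the false-positive-rate check.

## Known limitations

- $k$ must be supplied; there is no automatic model selection beyond the
  `k_sweep()` table.
- The classifier assigns every gene, including uniform background genes;
  probability thresholding to leave noise unassigned is future work.
- Single CEPR layer only — by design, matching the published
  architecture; no attention, no deeper stacks.
- Dense matrices throughout; fine to ~10k genes on a laptop, not for
  100k-node graphs.
- Biweight midcorrelation, Spearman and missing-value-aware correlation
  are not offered; inputs must be complete.
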