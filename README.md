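# ceRNAflow

Kinetic modelling and network analysis of perturbation propagation
between **distant competing endogenous RNAs (ceRNAs)**.

A miRNA and its targets are coupled in both directions: binding a miRNA
into a complex with one target relieves its pressure on the others. RNAs
sharing a miRNA regulator therefore act as ceRNAs, miRNAs sharing a
target compete likewise, and chaining the two couplings lets a
perturbation travel along alternating miRNA/target paths to genes that
share no regulator with the perturbed node — distant ceRNAs. This
package is for systems biologists who want to model that propagation
quantitatively, measure how far it reaches, and test for it in
interactome-scale data.

## What it computes

**Mass-action kinetics.** For free miRNA *R*, free target *T* and
complex *C*:

    dR/dt = g_R − bRT + u_C·C + (1−α)d_C·C − d_R·R
    dT/dt = g_T − bRT + u_C·C − d_T·T
    dC/dt = bRT − (u_C + d_C)·C

with the stoichiometric factor α ∈ [0,1] interpolating between
catalytic (α = 0, miRNA recycled) and stoichiometric (α = 1) repression.
Systems are built on single pairs, chains of 2N alternating species, or
arbitrary bipartite interactomes; steady states come from closed forms
(pair, circular chain) or a Newton/ODE hybrid solver.

**Correlation length.** The steady-state response of a node at distance
ℓ to a small source perturbation, C(ℓ) = (ΔT_ℓ/T_ℓ)/(ΔT₀/T₀), obeys
C(ℓ) = qp·[C(ℓ+2) + 2C(ℓ) + C(ℓ−2)] on homogeneous chains, with
exponential solution C(ℓ) = exp(−ℓ/ℓ₀) and

    ℓ₀ = 1 / arcosh( 1 / (2·√(qp)) ),   valid for qp < 1/4,

where p and q are the linear-response coefficients at the chain steady
state. Closed form, a truncated-recurrence oracle, and exponential fits
to simulated chains are implemented as three independent routes and
agree within 5% across the validity domain.

**Interactome statistics.** CLASH-style table reading (transcript→gene
aggregation, strict −13.4 kcal/mol confidence filter), bipartite
projections with shared-neighbour weights, shortest-path statistics,
average clustering, small-world σ against a seeded Erdős–Rényi
ensemble, and degree power-law fits.

**k-sep perturbation analysis.** BFS distance classification from a
perturbed miRNA (1-sep) through its targets (2-sep), target-sharing
miRNAs (3-sep), and so on, with a uniqueness retention rule for target
groups; median normalization of log2 fold changes; two-sided
Kolmogorov–Smirnov comparisons of distance groups against non-target
controls; regulator-count subgroup analysis and a TF-confound filter.

**Synthetic data.** Heavy-tailed bipartite interactome generation and
fully simulated depletion experiments with known ground truth, so every
stage is testable without external downloads.

## Worked example

```r
library(ceRNAflow)

## correlation length of the reference chain, three ways
p <- kinetic_params()            # g_R = g_T = 1, b = 1, u_C = 0.1,
                                 # d_C = 1, d_R = d_T = 0.17, alpha = 1
derived_params(p)$qp
#> [1] 0.1943143
correlation_length_closed_form(p)$l0
#> [1] 1.950898

sys  <- build_chain(100, p, boundary = "circular")
prof <- correlation_function_numerical(sys, "T0", delta_fraction = 0.01)
head(prof$by_distance, 4)
#>   distance          C
#> 1        0 1.00000000
#> 2        2 0.35970332
#> 3        4 0.12916335
#> 4        6 0.04635162
fit_correlation_length(prof$by_distance)$l0
#> [1] 1.951113
```

A 1% knockdown of one target in a 200-species chain is still felt two
targets away at 13% relative strength; the fitted decay length (1.951)
matches the analytic value (1.9509) to 0.01%.

```r
## end-to-end synthetic depletion experiment
raw <- generate_interactome(seed = 11)          # 40 miRNAs x 300 genes
tab <- aggregate_interactions(raw[c("mirna", "gene", "reads", "energy")])
sim <- simulate_perturbation_experiment(tab, seed = 12)   # deplete hub to 50%
expr <- normalize_log2fc(sim$expression)
compare_groups(expr, sim$classification,
               pairs = list(c("2-sep", "control"), c("4-sep", "control")))
#>   group1  group2  n1  n2 D p_value direction skipped reason
#> 1  2-sep control  27 300 1       0         1   FALSE   <NA>
#> 2  4-sep control 205 300 1       0         1   FALSE   <NA>
```

Direct (2-sep) targets of the depleted miRNA are strongly upregulated,
and — the distant-ceRNA signature — so are 4-sep targets, which the
source miRNA does not bind at all. D = 1 means complete ECDF separation
from the control genes, and the asymptotic two-sided K-S p-value
underflows to 0 at these group sizes. (Exact group sizes vary with the
seed.)

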