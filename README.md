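# culsel

Drift-versus-selection inference for the cultural evolution of
communication systems in laboratory micro-societies.

## The problem

When a small population invents a communication system from scratch —
for example, 8 people repeatedly drawing a fixed set of concepts for
each other in rotating pairs — the variants they produce compete, spread
and go extinct. Does a variant's rise require any *selection*, or is the
population just copying at random from what it remembers (neutral
evolution, "drift")? Two selectionist forces are candidates:

* **coordination bias** — a preference between one's own previously
  produced variants (*egocentric*) and those witnessed from partners
  (*allocentric*);
* **content bias** — an intrinsic preference for one particular variant,
  effective only once that variant has been encountered.

`culsel` implements a parametrized probabilistic model of variant choice
that nests all of these accounts, fits it to coded micro-society data by
exhaustive maximum likelihood, and quantifies the evidence for each bias
with best-account Bayes factors. Because the interesting question is
whether such inference *works*, the package also ships a forward
simulator of complete micro-society corpora with known parameters, so
the whole pipeline can be validated by parameter recovery, calibration
and power studies without any human data.

## The model

The unit of analysis is a **data structure**: the 8 × 7 grid of coded
variant productions (8 participants, 7 generations of round-robin
pairings, one production each per generation — 56 in all) for one
concept in one micro-society, together with the pairing schedule and
within-pair draw order.

At each decision, the producer's history splits into **ego** entries
(their own past productions) and **allo** entries (partner productions
they witnessed, including the current partner's production if they drew
second). With memory size *m*, only the last *m*/2 entries of each kind
count. Writing f<sub>E</sub> and f<sub>A</sub> for the
relative-frequency distributions of the two windows,
γ = (*c* + 1)/2 for the coordination bias *c* ∈ \[−1, 1\], β for the
effective content bias (β = *b* if the target τ is in memory, else 0),
and φ for the flat distribution over the variant universe, the
probability of producing variant *x* is

P(x) = (1 − μ) · \[ (1 − β) · ( (1 − γ) f_E(x) + γ f_A(x) ) + β · δ_τ(x) \] + μ · φ(x)

with mutation rate μ = 0.02. Drift is the special case *b* = 0, *c* = 0.

A data structure's likelihood is the product of these probabilities over
all choices from generation 2 on (first productions have no history).
The likelihood is maximized by exhaustive search over the standard grid
— *m* ∈ {2, 4, 6, 8}, *c* from −1 to 1 in steps of 0.2, *b* from 0 to 1
in steps of 0.1, i.e. **484 grid points**, with τ profiled over the
structure's most frequent variants. Evidence for a bias is the
best-account Bayes factor: the maximum likelihood over all models
divided by the maximum over models with that bias switched off, with
significance threshold 19. Each structure is then classified as
`content_only`, `coordination_only`, `both`, `indeterminate_bias` or
`drift_consistent`.

## Worked example

Simulate eight micro-society data structures under a known egocentric +
content-biased regime, fit, and classify:

```r
library(culsel)

cfg <- simulation_config(
  true_params = list(m = 2, c = -0.8, b = 0.6, mu = 0.02),
  tau_rule = "random_g1", n_societies = 1, n_concepts = 8
)
corp <- simulate_corpus(cfg, seed = 2024)

d <- corp$data_structures[[1]]
diversity_trajectory(d)
#> [1] 4 4 4 4 2 1 1

fit <- grid_search(d)
fit
#> <fit_result S1/C1: 484 grid points; ML m=2 c=-0.8 b=0.8 tau=V1 (loglik -14.802)>

bayes_factors(fit)
#> <bayes_factors S1/C1: content=1.79e+03 coordination=103 any=9.18e+03 (threshold 19) -> both>
```

The first structure starts with 4 variant types and collapses onto one
by generation 6; the fitted setting recovers the generating memory size
and coordination bias exactly and the content bias to within two grid
steps, and both biases are individually supported (Bayes factors far
above 19). Corpus-level aggregation:

```r
fits <- lapply(corp$data_structures, grid_search)
summarize_corpus(corp, fits)
#> Corpus summary (8 data structures, evidence threshold 19)
#> ...
#> Bias categories:
#>                    count proportion
#> content_only           2      0.250
#> coordination_only      1      0.125
#> both                   3      0.375
#> indeterminate_bias     1      0.125
#> drift_consistent       1      0.125
#>
#> Median Bayes factors:
#>      content coordination          any
#>       250.78        57.05      4756.08
```

Corpora can be written and re-read with `write_corpus()` /
`read_corpus()` (JSON or flat CSV), and the whole pipeline is available
as `cmd_simulate()`, `cmd_fit()` and `cmd_classify()` (or from a shell
via `inst/cli/culsel.R`).

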