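# trajbinDE

Branch-aware differential expression along binned pseudotime.

`trajbinDE` finds genes whose expression changes along the pseudotime of
a single-cell trajectory and *between* its branching paths. It is built
for the common situation where a trajectory-inference tool (Monocle3,
Slingshot, ...) has already assigned each cell a pseudotime and a
lineage, and the question is which genes drive the fate decision.

Instead of modelling every cell, the package aggregates: pseudotime is
discretized into ordinal bins separately per path (Sturges rule by
default, with a drop-factor `k` controlling compression), counts are
summed into pseudo-bulk profiles per bin, and each gene is modelled as

    log mu = b0 + b1*t + b2*t^2 + b3*t^3
           + z*(b4 + b5*t + b6*t^2 + b7*t^3) + offset

with `t` the ordinal bin index, `z` a dummy per non-reference path,
counts negative binomial with per-gene dispersion, and the log size
factor of each bin as offset. Selection is two-stage, in the spirit of
serial-expression polynomial-regression methods: (1) a likelihood-ratio
screen of the full model against intercept-only (BH-corrected, alpha
0.05); (2) backward stepwise elimination of non-significant terms,
followed by a gate on the deviance-explained R² (`>= 0.6` by default).
Selected genes are classified *branch-dependent* (a path term survived)
or *time-only*, and their fitted trends can be clustered.

A Splatter-style bifurcation simulator with per-gene ground truth
(`delta = gamma - alpha` per path) and an evaluation harness (confusion
metrics, ROC over R² thresholds, filtered-gene `p = 1` ranking export)
round out the package for benchmarking.

## Worked example

```r
library(trajbinDE)

sim <- simulate_bifurcation(sim_config(n_genes = 500, n_cells = 1500,
                                       seed = 42))
ce  <- sim$experiment                      # SingleCellExperiment

bm  <- bin_pseudotime(ce)                  # Sturges k=1, split_bin on
be  <- aggregate_bins(ce, bm)              # pseudo-bulk + size factors
res <- run_trajectory_de(be, workflow_config())
sel <- get_siggenes(res, rsq_threshold = 0.6)

length(sel$selected); length(sel$branch_dependent); length(sel$time_only)
#> [1] 105
#> [1] 102
#> [1] 3

truth <- sim$truth$de[match(res$gene, sim$truth$gene)]
confusion_metrics(classify_genes(res), truth)
#>   TP FP  TN FN       TPR        FPR accuracy       F1
#> 1 94 11 356 39 0.7067669 0.02997275      0.9 0.789916
```

105 genes pass both the significance screen and the R² gate; 102 of them
keep a path term (their dynamics differ between the two branches), 3
change with pseudotime only. Against the simulated truth this run calls
94 of 133 DE genes at a 3.0% false positive rate — the method is tuned
to keep false positives rare, at some cost in sensitivity for weak,
sparsely observed genes.

The same analysis runs from the shell via the installed wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/trajbinde", package="trajbinDE"))') \
    simulate --out run1 --seed 42 --genes 500 --cells 1500
```

with `bin`, `fit`, `evaluate` and `run --config run.yaml` subcommands
mirroring the R functions.

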