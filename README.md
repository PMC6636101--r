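# foldreg

Sparse detection of cell-type specific parameters in dynamic models.

## The problem

Mechanistic ODE models of cell signalling or gene regulation are often
fitted to data from *two* cell types at once — say a healthy and a
malignant line — under the assumption that the two types share most of
their kinetics and differ in only a few rates. `foldreg` encodes the
second cell type by log10 fold-changes on the reference parameters,

    log10 p_i[1] = log10 p_i[0] + r_i ,

and shrinks the fold-change vector `r` towards zero with a sparsity
penalty added to the weighted least-squares likelihood:

    chi2(p, r, lambda) = chi2_ML(p, r) + lambda * nu(r) .

Four penalty families are available — l1 (Lasso), the non-convex lq
pseudo-norm `sum |r_i|^q`, the Elastic Net, and the Adaptive Lasso —
each controlled by one *deformation* parameter that reduces it to l1 at
zero. For every penalty strength on a log-spaced scan the package runs
the two-step routine (penalized fit to find the zero set `Z(lambda)`,
then an unpenalized refit with `Z(lambda)` fixed to zero), computes the
likelihood-ratio statistic `D(lambda) = chi2(lambda) - chi2(0)`, and
selects the *parsimonious* model: the largest penalty strength whose
shrinkage still satisfies `D(lambda) < q_alpha` with `#Z(lambda)`
degrees of freedom. Fold-changes left nonzero at that strength are the
predicted cell-type specific parameters; profile-likelihood confidence
intervals are available for post-hoc inspection.

The package ships a compiled Hill-kinetics gene-network simulator
(6 genes, mRNA + protein states, 29 kinetic parameters) and a
synthetic two-cell-type benchmark that measures, over randomized
replicates, how reliably each penalty family classifies parameters as
cell-type specific (sensitivity / specificity / accuracy, ROC along
the path, paired method comparisons with Bonferroni-corrected t-tests).

It is aimed at systems-biology modellers comparing two conditions or
cell lines with a shared mechanistic model, and at methods people who
want a self-contained testbed for sparse model selection in nonlinear
dynamic models.

## Worked example

A benchmark run on the 3-gene network reduction: a model, a randomly
drawn ground truth and design, simulated noisy data, and a full lq
regularization scan.

```r
library(foldreg)

model <- build_network_model(3)             # 3-gene network, 13 parameters
truth <- sample_ground_truth(model, seed = 4)
design <- sample_design(model, seed = 4)
meas <- simulate_dataset(model, truth$r, design, seed = 4)
problem <- fc_problem(model, meas, design$conditions,
                      penalized = model$param_names)

fit <- fit_ml(problem, n_starts = 5, seed = 1)
scan <- scan_lambda(problem, penalty_spec("lq", deformation = 0.2),
                    default_lambda_grid(17), seed = 1, init_fit = fit)
glance(scan)
scan$positives
classify(scan$positives, truth$table$parameter, problem$penalized)
truth$table$parameter
```

which prints:

```
#> # A tibble: 1 x 8
#>   family deformation lambda_star n_zero n_positive chi2_0 D_star alpha
#>   <chr>        <dbl>       <dbl>  <int>      <int>  <dbl>  <dbl> <dbl>
#> 1 lq             0.2        42.2      5          8   577.  0.758  0.95
#> [1] "pro_g1"  "pro_g2"  "pro_g3"  "rbs_g1"  "deg"     "km_e1"   "hill_e1"
#> [8] "hill_e2"
#> # A tibble: 1 x 7
#>      tp    fp    tn    fn sensitivity specificity accuracy
#> 1     4     4     5     0           1       0.556    0.692
#> [1] "km_e1"   "hill_e1" "pro_g3"  "hill_e2"
```

`lambda_star` is the selected penalty strength, `n_positive` the number
of fold-changes predicted cell-type specific. The scan recovers all
four true differences (sensitivity 1) together with four spurious ones
(specificity 0.56): with only two proteins or the mRNAs observed, some
fold-changes lie on compensation rays of the likelihood and the
sparsest admissible pattern is not unique. `tidy(scan)` gives the
per-lambda records and `autoplot(scan)` the `D(lambda)` / threshold
diagnostics; a profile such as
`profile_likelihood(problem, scan$final_fit, "r_pro_g1")` shows which
of the reported fold-changes are compatible with zero within their 95%
confidence interval and could be pruned manually.

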