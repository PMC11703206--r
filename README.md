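# pepbound

Binding free-energy regression for multi-round peptide-display affinity
selection.

Display selection experiments (e.g. bacterial display of phosphopeptide
libraries selected against an SH2 domain) produce paired input/bound
sequencing counts per peptide and selection round. The common summary — a
position-specific log-enrichment matrix — is confounded by library design,
non-specific capture, and secondary binding offsets. `pepbound` instead fits
an explicit enrichment model to the counts and reports additive binding
free-energy differences (ΔΔG/RT) that are properties of the protein–peptide
interface.

The predicted enrichment of peptide *s* in count table *c* sums a
sequence-specific and a non-specific binding mode,

    kappa_c(s) = alpha_c,NS * sum_x exp( X(s_[x:x+w_NS]) . beta_NS + gamma_x )
               + alpha_c,S  * sum_x exp( X(s_[x:x+w_S])  . beta_S ),

where the specific mode scans all offsets of the peptide padded with up to
f_S = 5 residues of the constant displayed flanks, and `beta_S` holds
−ΔΔG/RT. Each table is modelled as a single-round selection with a scaled
binomial likelihood over input/bound outcomes,

    l_data = sum_c (1/k_c) sum_i [ k_c,i,I * ln( eta_I / (eta_I + eta_B kappa_c(s_i)) )
                                 + k_c,i,B * ln( eta_B kappa_c(s_i) / (eta_I + eta_B kappa_c(s_i)) ) ],

maximised jointly over all rounds (L-BFGS with analytic gradients, L2 +
barrier + Dirichlet regularization, optional frozen central tyrosine
column). Fitted models score phosphosites, predict missense-variant effects
on binding, and validate against measured K_D values.

## Worked example

Simulate a three-round selection of an X5-Y-X5 library with a known energy
matrix, fit it back, and compare:

```r
library(pepbound)

sim <- simulate_experiment(design = x5yx5_design(), n_unique = 20000,
                           rounds = 2, reads_per_column = 100000, seed = 1)
sim$tables[[1]]
#> <count table> round R1: 19956 sequences, 100000 input / 100000 bound reads

fit <- fit_binding_model(sim$tables, seed = 1)
glance(fit)
#> # A tibble: 1 × 8
#>    loss log_lik penalty convergence n_eval n_par n_tables n_starts
#>   <dbl>   <dbl>   <dbl>       <int>  <int> <int>    <int>    <int>
#> 1  14.7  -0.803    13.9           0    619   275        2        1

compare_models(ddg_matrix(fit), ddg_matrix(sim$truth$model))$r2
#> [1] 0.9968404
```

`glance()` reports the optimiser's final loss (`-l_data + l_reg`), and the
comparison is the squared Pearson correlation between fitted and true
ΔΔG/RT over all non-central residue–position coefficients: the fit recovers
the ground truth almost perfectly at this depth. Downstream:

```r
scan_sites(fit, tibble::tibble(site_id = c("siteA", "siteB"),
                               peptide = c("EEEIPYEEIEE", "GGGGGYGGGGG")))
#> # A tibble: 2 × 3
#>   site_id peptide     log_affinity
#>   <chr>   <chr>              <dbl>
#> 1 siteB   GGGGGYGGGGG         1.58
#> 2 siteA   EEEIPYEEIEE        -2.01

variant_effect(fit, "site", "EEEIPYEEIEE", "EEEIPYREIEE")$direction
#> [1] "gain"
```

(Scores are relative log affinities under this run's randomly drawn
simulated truth, so the ranking reflects that matrix; with a model fitted to
real selection data the same calls rank candidate interaction partners and
variant effects.)

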