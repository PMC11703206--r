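---
title: "Free-energy regression for peptide-display selection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy regression for peptide-display selection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepbound)
```

## The problem

Peptide-recognition domains such as SH2 domains bind short linear motifs with
an affinity that depends strongly on the residues flanking a central anchor
(for SH2 domains, a phosphorylated tyrosine). Display selection experiments
probe this specificity at scale: a large randomized peptide library is
displayed, phosphorylated, selected for binding on immobilized domain, and
deep-sequenced before ("input") and after ("bound") each selection round. The
data are paired per-sequence read counts.

The classic summary of such data is a position-specific log-enrichment
matrix: per-position residue frequencies in the bound library divided by
those in the input library. That summary is easy to compute but confounded —
it depends on the library design, ignores non-specific capture, fixes the
binding register, and credits enrichment driven by secondary (off-centre)
binding sites to the wrong positions. `pepbound` instead regresses an
explicit biophysical model against the counts and reports additive binding
free-energy differences (ddG/RT), which are properties of the protein-peptide
interface rather than of the assay.

## The model

For a peptide $s$ of variable-region length $L$, the predicted enrichment in
count table $c$ is the sum of two binding modes,

$$
\kappa_c(s) \;=\; \alpha_{c,NS}\sum_{x=1}^{L-w_{NS}+1}
  e^{\vec X(s_{x:x+w_{NS}})\cdot\vec\beta_{NS}+\gamma_x}
\;+\;\alpha_{c,S}\sum_{x=1-f_S}^{L+f_S-w_S+1}
  e^{\vec X(s_{x:x+w_S})\cdot\vec\beta_S},
$$

where $\vec X(\cdot)$ is the one-hot encoding of a subsequence, so each
exponent is the sum of one coefficient per window position. The specific
mode ($w_S = 11$ by default) scans every offset of the peptide padded with
up to $f_S = 5$ residues of the constant displayed flanks (`GQSGQ` /
`GGQSG`), because a binding site may straddle the variable region; summing
over offsets is what controls for non-central tyrosines. The non-specific
mode uses short windows ($w_{NS} = 3$; width 1 is appropriate for domains
whose motif a 3-mer could capture) plus a per-offset bias $\gamma_x$
absorbing positional sequence artefacts, and scans the variable region only.
The entries of $\vec\beta_S$ are $-\Delta\Delta G/RT$: the free-energy matrix
we want.

Each count table is modelled as a single-round selection under linear
(non-saturating) capture. A read of sequence $s_i$ lands in the bound column
with probability $\eta_{c,B}\kappa_c(s_i)/(\eta_{c,I}+\eta_{c,B}\kappa_c(s_i))$,
giving the scaled binomial log-likelihood

$$
l_{data}=\sum_{c=1}^{N_C}\frac{1}{k_c}\sum_{i\in S_c}
\left(k_{c,i,I}\ln\frac{\eta_{c,I}}{\eta_{c,I}+\eta_{c,B}\kappa_c(s_i)}
+k_{c,i,B}\ln\frac{\eta_{c,B}\kappa_c(s_i)}{\eta_{c,I}+\eta_{c,B}\kappa_c(s_i)}\right),
$$

with $k_c$ the table's total reads (input plus bound). A multi-round
experiment contributes one table per round and a single shared energy matrix
is fitted jointly to all of them.

To focus the specific mode on anchored binding, its central column can be
frozen to $0$ for tyrosine and $-10$ for all other residues; the
unconstrained fit is available (`constrain_center = FALSE`) for
target-agnostic profiling.

### Identifiability and gauges

Two exact invariances shape the parameterisation:

* $\eta_{c,B}$ multiplies both activities, so it is fixed to 1 and
  $\eta_{c,I}$ is free per table.
* Adding a constant $\delta$ to a full column of $\vec\beta_S$ while
  multiplying every $\alpha_{c,S}$ by $e^{-\delta}$ leaves every
  $\kappa_c$ unchanged (each offset window covers every column because the
  window is as wide as the matrix). After fitting, each non-frozen column is
  therefore mean-centred and the aggregate shift absorbed into the specific
  activities; reported ddG/RT values are in this centred gauge, matching how
  energy logos are drawn ("relative to the position mean").

A joint rescaling of all activities and $\eta_{c,I}$ is also invariant; it is
left as a flat direction of the objective (harmless to a quasi-Newton
optimiser) rather than pinned arbitrarily.

### Regularization

The loss is $-l_{data} + l_{reg}$ with three standard ingredients: an L2 term
(weight $10^{-6}$ by default — a gentle ridge, since the likelihood itself is
informative about every coefficient that occurs in the data), an exponential
barrier $e^{\theta-B}+e^{-\theta-B}$ with $B = 20$ keeping coefficients of
unobserved residue-position combinations from drifting to infinity, and a
Dirichlet penalty with count 5 on each table's activity fractions
$-5\sum_c\sum_{m}\ln(\alpha_{c,m}/\sum_{m'}\alpha_{c,m'})$, which resolves
the remaining scale split between the two modes. Frozen constrained columns
are excluded from all penalties. The barrier and Dirichlet forms are this
package's concrete choices; their hyperparameters are exposed in
[reg_config()].

### Optimisation

All free parameters (non-frozen $\vec\beta_S$, $\vec\beta_{NS}$, $\gamma$,
and per-table $\log\alpha_{c,NS}$, $\log\alpha_{c,S}$, $\log\eta_{c,I}$ —
logs enforce positivity) are optimised jointly with L-BFGS-B using analytic
gradients; gradient correctness is unit-tested against central finite
differences at $10^{-6}$ relative tolerance. Energies are accumulated as
log-sum-exp and outcome probabilities through softplus, so the computation
stays finite for coefficient magnitudes far beyond anything data can
support (tested at $|\beta| = 50$). Initialisation draws coefficients from
$N(0, 0.1^2)$, starts activities equal, and sets $\eta_{c,I}$ from each
table's observed input/bound read ratio; `n_starts` seeded restarts are
supported, with the best loss winning. Convergence is by projected-gradient
tolerance (`tol`, default $10^{-7}$) or `max_iter`.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_experiment(design = x5yx5_design(), n_unique = 20000,
                           rounds = 2, reads_per_column = 100000, seed = 1)
fit <- fit_binding_model(sim$tables, seed = 1)
compare_models(ddg_matrix(fit), ddg_matrix(sim$truth$model))$r2
autoplot(fit)
```

Downstream, [score_peptide()] ranks peptides by total log affinity,
[scan_sites()] applies that to phosphosite tables (with an optional
co-expression filter), [variant_effect()] reports the allelic log affinity
ratio and a direction call, [fit_kd_regression()] validates predictions
against measured dissociation constants by ordinary least squares on
$\ln K_D$, and [cluster_models()] groups fitted matrices by
$1 - r$ average linkage.

## What the simulator emulates — and what it does not

[simulate_experiment()] generates the data-generating process the likelihood
assumes: a library drawn uniformly (or NNS-weighted) from the design space,
linear selection with bound frequencies proportional to pool frequency times
$\kappa$, independent multinomial sequencing of input and bound pools, and
noiseless re-amplification between rounds. Two realism knobs are provided:
`nonspecific_fraction` (the share of initially selected mass carried by the
non-specific mode; default 0.2, calibrated on the initial pool) and
`phospho_efficiency` (the fraction of tyrosine-containing members competent
for specific binding; default 1 — incompetent members keep only their
non-specific term, emulating incomplete enzymatic phosphorylation).

The simulator deliberately omits saturation of the binding reagent, PCR and
re-amplification noise, sequencing errors (read-level artefacts are exercised
separately through the read-processing fixtures), residue-position
interdependencies, and real phosphorylation sequence biases. Parameter
recovery on these simulations therefore demonstrates correctness of the
estimator under its own assumptions — it does not certify accuracy on real
selections, which is why validation against measured $K_D$ values remains
part of the workflow.

Problem sizes used in the package's checks were chosen as desk-scale versions
of a realistic experiment: libraries of $5\times10^4$ distinct members
sequenced at $2\times10^5$ reads per column over three rounds, with true
non-central coefficients drawn from $N(0,1)$. For the fully degenerate
(X11-style) comparison of single-round versus multi-round inference, the
library is made genuinely weak-binder-dominated: $5\times10^4$ members
sequenced at only $2\times10^4$ reads per column (under one read per member,
so single-round per-sequence enrichment is mostly noise) and a 90%
non-specific share of the initially bound mass, as expected when most members
carry no tyrosine at all.

## Read processing choices

Anchor scanning tolerates up to five mismatches *combined* across both
flanking anchors (a per-anchor budget would be more permissive; combined is
the conservative reading), choosing the placement with the fewest mismatches
and breaking ties leftward. The PHRED filter (default minimum 20 at every
base) applies to the cropped variable region only — errors inside the
anchors were already tolerated by the mismatch budget, so discarding a read
for them would be inconsistent. Reads whose region contains an `N`, violates
the NNS codon scheme, translates to a stop (NNS admits TAG; a displayed
peptide cannot contain a stop), or misses a fixed library residue are
discarded. The order of the quality and design filters does not affect which
reads survive, only how the losses are attributed in the stage log.

## Numerical and interface conventions

Natural logarithms everywhere; ddG/RT is dimensionless. The default scan
mode is `"total"` (all offsets), matching how the model itself explains the
data; `"central"` is the fast, register-fixed approximation. The
log-enrichment baseline uses a pseudocount of 0.5 per residue-position cell
because degenerate libraries can leave cells empty. The variant direction
call uses a neutral band of 0.1 on the log ratio — an interpretability
choice, not an estimate of measurement error. Ranked outputs break ties by
identifier so they are total orders. Count tables are 3-column TSV with a
`# round=` header; models serialize to JSON with an explicit residue-order
string.

## Known limitations

The model is additive: residue-pair interdependencies and multiple specific
binding modes are out of scope. Selection is assumed linear, so strongly
saturating experiments will compress recovered energies. Phosphorylation
efficiency enters the simulator but not the fitted model — a global
suppression is partially absorbed by the non-specific mode and activities.
Uncertainty quantification of fitted coefficients (e.g. bootstrap over
sequences) is not implemented.
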