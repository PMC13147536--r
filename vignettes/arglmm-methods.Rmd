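---
title: "Methods: the ARG linear mixed model in arglmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ARG linear mixed model in arglmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`arglmm` fits a linear mixed model in which relatedness between
individuals is read off an ancestral recombination graph (ARG) stored as
a succinct tree sequence.  The phenotype model is

$$y = Xb + Zu + \varepsilon,$$

where rows of the dosage matrix $Z$ index individuals and columns index
*sub-edges*: maximal fragments of ARG edges over which the set of sample
nodes below the edge is constant ($Z_{ie} \in \{0,1,2\}$ for diploids).
Each sub-edge carries an area $A_e = (b_e - a_e)(t_{p_e} - t_{c_e})$ —
genomic span times branch length, in bp-generations — which is its total
opportunity for mutation.  Sub-edge effects are independent with mean
zero and variance $\tau^2 A_e$; environmental deviations are i.i.d. with
variance $\sigma^2_\varepsilon$.  Consequently

$$\mathrm{Cov}(y) = V = \tau^2 B + \sigma^2_\varepsilon I,
  \qquad B = Z \Sigma_A Z^\top,$$

with $B$ the *branch GRM* and $\Sigma_A = \mathrm{diag}(A_e)$.  $\tau^2$
is a generative parameter — mutational-effect variance per generation per
base pair — and is distinct from the realized additive genetic variance
of the sample, $V_G = \frac1N \sum_i (g_i - \bar g)^2$, whose first two
moments under the model are $E[V_G] = \tau^2\,\mathrm{tr}(\tilde B)/N$
and $\mathrm{Var}(V_G) = 2\,\tau^4\,\mathrm{tr}(\tilde B^2)/N^2$, where
$\tilde B = P_N B P_N$ is the doubly centered GRM (`estimate_vg()`).
The factor 2 is the variance of a Gaussian quadratic form,
$\mathrm{Var}(g^\top A g) = 2\,\mathrm{tr}\!\big((A\Sigma)^2\big)$; it is
sometimes dropped in print, and the package's moment tests verify it
empirically against replicate generative draws.

The model itself uses the uncentered $B$ with an intercept in $X$: mean
effects are absorbed into the intercept, and centering is available as an
orthogonal flag on every GRM product.

## Exact implicit GRM products

`grm_matvec()` computes $Bw$ (and centered and submatrix variants)
without forming $B$ or the sub-edges.  Conceptually there is an up-pass
(per sub-edge, the weighted count of samples below times its area) and a
down-pass (per sample, the sum over ancestral sub-edges), but both are
realized in a single incremental sweep over edge insertions and removals
along the genome.  Every node keeps a lazily accrued contribution over
the genomic interval since its subtree or parent last changed — those
intervals are exactly the sub-edges — and a path-sum baseline trick makes
subtree detachment and attachment O(depth) per edge event, giving
$O(N + E\log N)$ per product overall.  Batched right-hand sides share a
single sweep, which matters because every randomized-algebra step below
applies the operator to 50-plus vectors at once.

Sub-edges are materialized only by `subedge_decompose()`, an
oracle used in the tests to check the partition property, the
constant-descendant-set invariant, and the dense reconstruction
$B = \sum_e A_e z_e z_e^\top$.  The implicit product is additionally
cross-checked in the test suite against the independent implementation
in the `tskit` Python library.

The same sweep yields three more primitives: generative simulation of
genetic values (`simulate_genetic_values()`; one Gaussian draw of
variance $\tau^2 A$ per flushed interval — splitting a sub-edge across
intervals leaves the law of $Zu$ unchanged), dosage sums of mutation
effects placed at (position, node) pairs, and the total root area
$\sum_T s_T t_{\mathrm{root},T}$ with multi-root trees summed over every
root that subtends a sample.

## Variance component estimation

The restricted likelihood is optimized in its doubled negated-log form
$\ell = \log\det V + \log\det(X^\top V^{-1}X) + y^\top P y$ with
$P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}$.  The gradient is

$$\nabla_i \ell = \mathrm{tr}(P\dot V_i) - y^\top P \dot V_i P y,
  \qquad \dot V_\sigma = I,\; \dot V_\tau = B,$$

and the update is $\theta \leftarrow \theta - AI^{-1}\nabla\ell$ with the
average-information matrix $AI_{ij} = y^\top P\dot V_i P \dot V_j P y$.
This matrix is the average of the observed Hessian and the Fisher
information of $\ell$; their trace terms cancel, so the curvature needs
no stochastic estimation and is positive semidefinite by construction.
A sign ambiguity in some published statements of the AI entries is
resolved here by requiring exactly this PSD/descent convention; the test
suite verifies the matrix against (numerical Hessian + Fisher)/2 of the
dense objective, and the fixed point — the score equations — is
unaffected.

Computationally:

* $V^{-1}$ products use preconditioned conjugate gradients
  (`conjugate_gradient()`, relative-residual tolerance $10^{-5}$,
  zero start, batched with per-column step sizes).
* The preconditioner is a randomized Nystrom approximation
  (`nystrom_preconditioner()`).  The sketch is taken of $B$ once per fit
  (rank 500 by default) and the preconditioner for
  $V = \tau^2 B + \sigma^2_\varepsilon I$ at each iterate is composed as
  $U(\tau^2\Lambda + \sigma^2_\varepsilon)^{-1}U^\top +
  \sigma^{-2}_\varepsilon (I - UU^\top)$; the shift is the current
  $\sigma^2_\varepsilon$, which bounds $V$'s spectrum from below.
  Composing from a fixed sketch of $B$ rather than re-sketching $V$ each
  iteration changes no fixed point and saves a large constant factor.
* $\mathrm{tr}(V^{-1})$ and $\mathrm{tr}(V^{-1}B)$ are estimated by the
  exchangeable deflated estimator in `xtrace()` (50 test vectors per
  trace by default; variance decays like $1/m^2$, much faster than plain
  Hutchinson — the suite compares both).  The $K\times K$ covariate
  corrections to $\mathrm{tr}(P)$ and $\mathrm{tr}(PB)$ are computed
  exactly.  Trace test vectors are redrawn at every iteration from
  per-iteration seeds derived from the fit seed, keeping gradient noise
  independent across iterations while remaining reproducible.
* Quadratic forms are exact given the CG solves: $Py$ comes from one
  batched solve of $V^{-1}[X\;y]$ per iteration.

Iterations start from the randomized Haseman-Elston estimate
(`he_initialize()`): residualize $y$ against $X$ by OLS — the printed
moment system carries no covariates, and residualization matches
standard HE practice — then solve the 2-by-2 system in
$(\mathrm{tr}(B^2), \mathrm{tr}(B), N; \; y^\top By, y^\top y)$ with
XTrace estimates of the traces.  After each AI update both components are
clamped below at $10^{-8}\mathrm{Var}(y)$, keeping $V$ positive definite
at the boundary.  Convergence: when both components change by less than
5% relative (measured against $\max(|\theta|, 10^{-8}\mathrm{Var}(y))$ to
handle near-zero components), 15 further iterations run and their mean is
returned.  Reported standard errors come from the inverse AI at the final
estimate (delta-method scale $2\,AI^{-1}$ for the doubled objective).

`dense_spectral_reml()` is the deterministic oracle: eigendecompose a
dense $B$, rotate $y$ and $X$, and minimize the now-factorized restricted
likelihood by bounded multi-start L-BFGS-B.  The suite requires the
stochastic fit to agree with it within the seed-to-seed spread at
$N \in \{200, 500\}$.

## Prediction

`predict_blup()` computes empirical BLUPs
$\hat g_n = \hat\tau^2 B_{n,o}(\hat\tau^2 B_{o,o} +
\hat\sigma^2_\varepsilon I)^{-1}(y_o - X_o\hat b)$, with the single
shared solve done by preconditioned CG and the cross-covariance product
by one implicit submatrix matvec (scatter, product, gather).  Observed
and target sets may overlap.  Conditional variances follow the Gaussian
conditioning identity column by column — one solve per target — and are
therefore guarded to at most 2,000 targets by default.
`predict_linear_combination()` exposes the general form: any linear
functional of sub-edge effects with a computable cross-covariance against
the observed phenotypes (e.g. restricted to a genomic window) reuses the
same shared solve.

## The simulation harness

`simulate_arg()` delegates coalescent simulation to msprime through a
bundled Python helper, exchanging tables as TSV; no binary formats cross
the language boundary.  The default demography is the evaluation
condition used throughout: 100,000 diploids at present, declining at a
continuous rate of 1% per generation backward in time (the printed
"1% per generation" admits discrete or continuous compounding; the
continuous reading is used, and results are insensitive to the choice),
recombination rate $10^{-8}$ per bp per generation, 1 Mbp genomes.
Constant-size and linear stepping-stone demographies are available;
`structured_fixture()` provides the reduced stand-in for spatially
structured designs.

Phenotypes (`simulate_phenotypes()`) divide the simulated genetic values
by $\sqrt{4\sum_T s_T t_{\mathrm{root},T}}$ — four times the total root
area bounds the generative variance of a diploid genome — so that
genetic and environmental variances are comparable at
$\tau^2 = \sigma^2_\varepsilon = 1$; the test suite checks the realized
variance ratio stays within [0.25, 4] under the evaluation demography.
Under this scaling the model GRM is $B / (4\sum_T s_T t_{\mathrm{root},T})$,
which is what `grm_scale` passes to `fit_reml()`; component estimates are
then on the same unit scale as the generating values.  The
mutation-effect mode places Poisson mutations on the ARG, marks 1% causal
by default, draws standard-normal effects and sums dosages — phenotypes
that violate the Gaussian sub-edge assumption, used to check that point
estimation does not depend on it.

What the generator does *not* emulate: selection, dominance and
epistasis, heterogeneous mutation rates along the genome, genotyping
error, and ARG inference error (all tests run on true simulated ARGs).
Passing tests therefore demonstrate correctness of the computations under
the generative model, not robustness to misspecified real data.

## Problem sizes used by the test suite

Chosen so the default run stays comfortable on one CPU; all are stated
here as the package's own evaluation design:

* Matvec oracle: 20 random ARGs, up to ~90 individuals and ~60 kb.
* Generative moments and $V_G$: a 30-haplotype ARG, 2,000 replicate
  draws.
* REML vs dense oracle: $N \in \{200, 500\}$, 1 Mbp, 10 stochastic seeds.
* Recovery and REML-vs-HE ordering: $N = 600$, 1 Mbp,
  $\tau^2 \in \{0, 0.5, 1\}$, $\sigma^2_\varepsilon = 1$, 10 phenotype
  replicates per setting across 2 ARGs.  The REML-vs-HE comparison in
  the $\tau^2 = 0$ boundary cell runs at $N = 2{,}000$ (2 replicates)
  instead: exact REML has positive boundary excursions at small $N$
  (confirmed against the dense oracle), so the ordering there is a
  large-sample property.
* Relative-error bound on $\hat\tau^2$: $N = 2{,}000$, 1 Mbp, 3
  replicates (the full-scale design uses $N = 50{,}000$; accuracy
  improves with $N$, so the bound is the harder to meet at this size).
* Held-out BLUP accuracy: $N = 500$, 1 Mbp, 50/50 split,
  $\tau^2 \in \{0.2, 0.6, 1.0\}$.

## Numerical and design notes

* Positions are 0-based half-open intervals in bp; times are generations
  into the past; node ids are 0-based throughout, as in the tree-sequence
  ecosystem.  Individual weights are replicated to their sample nodes
  before the up-pass and summed after the down-pass, so $Z$'s 0/1/2
  dosages are never formed.
* Uncoalesced ARGs are supported: only existing edges contribute area,
  isolated roots contribute nothing, and root areas sum over all
  sample-subtending roots per tree.
* CG refuses to report a non-converged solve (error carrying the final
  residual) rather than returning silently inaccurate products.
* `xtrace()` falls back to an exact trace when asked for at least as
  many test vectors as dimensions, and to plain quadratic-form averages
  if the sketch is numerically rank deficient.
* The Nystrom fallback at `rank >= dim` materializes and inverts the
  operator exactly (test scale only).
* At desk scale, stepping-stone structure *concentrates* the centered
  GRM spectrum into a few deme-contrast eigenvalues rather than
  flattening it (measured across 4-16 demes, migration
  $10^{-4}$-$10^{-3}$); the structured fixture is therefore documented
  and tested with that direction.  Slowly decaying spectra comparable to
  large spatial simulations require genome lengths and sample sizes
  beyond the suite's scale.
* BLUP from a non-converged fit proceeds with a warning; the result
  carries the flag.

## Known limitations

* Two variance components only (one GRM plus noise); the operator layer
  is written so further components could be added, but none are exposed.
* No frequency-dependent weighting of branches ($\alpha \ne 0$).
* No ARG inference: inputs are tree sequences produced elsewhere
  (msprime here; tsinfer/tsdate pipelines in practice).
* Conditional variances are dense in the target set and priced
  accordingly.
* The Python bridge requires msprime/tskit on `PATH` for simulation and
  `.trees` input; in-memory `arg_data()` tables work without Python.
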