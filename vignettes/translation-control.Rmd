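---
title: "Modeling genome-scale translation from polysome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genome-scale translation from polysome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotraffic)
```

## The problem

Polysome profiling separates a cell's mRNA-ribosome complexes on a sucrose
gradient into elution fractions by mass. For each gene, microarray
quantification of the fractions yields the proportions of that gene's mRNA
copies carrying 0, 1, ~2, ~4, ~7 or ~14 ribosomes. `ribotraffic` turns such
fraction tables into per-gene estimates of polysome size, ribosome
occupancy and ribosomal density, then uses a mechanistic model of ribosome
traffic to infer protein synthesis rates and to quantify how control over
translation is distributed between initiation, elongation and termination.
The package was built with fast-growing bacteria in mind (gene lengths of
60-1500 codons, seven-fraction gradients, triplicate profiles), but nothing
in it is organism-specific.

## The traffic model

Translation is modeled as a totally asymmetric exclusion process with
extended particles: an mRNA is a chain of `n` codons; each ribosome covers
`L` codons (default 10) and is indexed by the codon it decodes, its front.
Initiation places a ribosome on codon 1 at effective rate `kappa_I`
(the initiation rate constant lumped with the free-ribosome pool, since
only the product is identifiable from polysome data) provided codons
`1..L` are empty. A ribosome at codon `i` steps to `i + 1` at rate `k_E`
provided codon `i + L` is free (no condition once its footprint overhangs
the chain end), and terminates at codon `n` at rate `k_T`, releasing a
protein.

Writing `p[i]` for the probability that a ribosome front occupies codon
`i`, the stationary state must carry a uniform flux
`J = kappa_I * (1 - sum(p[1:L])) = k_E * p[i] * q_i = k_T * p[n]`,
where `q_i` is the conditional probability that codon `i + L` is vacant
given a front at `i`. The package closes this hierarchy with the refined
(pair-level) mean-field expression

```
q_i = (1 - sum(p[(i+1):(i+L)])) / (1 - sum(p[(i+1):(i+L-1)]))
```

The summary quantities are the polysome size `P = sum(p)`, the ribosomal
density `rho = L * P / n` (0 = empty, 1 = fully covered), and the specific
synthesis rate `V_s = J` in proteins per second per engaged mRNA copy.

For a long homogeneous lattice the closure gives the classic
current-density relation
`J(rho) = k_E * (rho/L) * (1 - rho) / (1 - (L-1) * rho / L)`, maximal at
`rho* = sqrt(L)/(1 + sqrt(L))` with `J* = k_E / (1 + sqrt(L))^2`. With the
package defaults (`k_E = 23` codons/s, a cell-averaged bacterial value
taken as a configuration input, and `L = 10`) this peak is 1.33 proteins/s
at a density of 0.76 — the model's central quantitative prediction, which
`rate_density_curve()` reproduces for finite genes.

```{r optimum}
mean_field_optimum(k_E = 23, L = 10)
```

## Solving for the steady state

`steady_state()` solves the closed stationary equations in two stages.

First, the equations are triangular in disguise: given a trial flux `J`,
the sites under the terminal footprint are pinned
(`p[n] = J/k_T`, `p[i] = J/k_E` for `n-L < i < n`), and every earlier
`p[i]` follows by a backward recursion. The initiation balance
`kappa_I * (1 - sum(p[1:L])) = J` then becomes a scalar root-finding
problem, solved by bisection. This construction is exact (to rounding) in
the initiation-limited and maximal-current regimes, but in the
termination-limited (jammed) phase the recursion is numerically unstable —
perturbations grow like `(rho/(1-rho))^n` site over site — so its result
cannot be trusted there.

Second, the profile is relaxed by damped pseudo-time integration of the
full mass-balance system until every transition flux agrees to a relative
tolerance (`tol`, default `1e-8`). The update is a positivity-preserving
Patankar step `p <- (p + a*dt) / (1 + b*dt)` applied in alternating-
direction Gauss-Seidel sweeps, so information crosses the whole lattice in
one sweep rather than one site per step. Three properties make this stage
robust:

* the Patankar update's fixed point is the steady state for *any* `dt`, so
  the time step only sets the relaxation pace (default `2/k_E`, halved
  automatically when the residual stagnates);
* footprint windows are capped during the update — transiently overfull
  windows are unphysical and would drain only at the (possibly tiny)
  termination rate;
* in deeply jammed lattices all fluxes are of order `k_T` and the relative
  flux spread bottoms out at rounding noise, so convergence is also
  declared below an absolute spread floor of order `n * k_E * eps`.

The relaxation stage is the authority; the recursion is an accelerator.
Seeding follows the same logic: while termination is non-limiting the
recursion initializer is near-exact and a cold start converges in tens of
sweeps, whereas relaxing a neighbouring profile would transport its
differences diffusively across the lattice; in the jammed branch the
recursion is unusable and repeated solves are instead warm-started from
the previous candidate.
The test suite checks the solver against an independent plain-R explicit
integrator and, for a 20-codon gene, against the exactly enumerated
Markov chain.

## Calibration under rate maximization

Polysome data constrain one number per gene — its polysome size — but the
model has two free rates, `kappa_I` and `k_T`. `calibrate_gene()` resolves
the indeterminacy with a rate-maximization assumption: among all rate
pairs reproducing the observed polysome size, the cell operates at the one
with the largest synthesis rate. Operationally, termination is first
pinned at a non-limiting value (`k_T = 1e3`/s, far above `k_E`) and
`kappa_I` is raised by a bracketed log-space root search (Illinois
false position, falling back to bisection until both bracket ends have
been evaluated) until the target polysome size is met. If the polysome size plateaus below the target (relative growth
per doubling of `kappa_I` below `plateau_eps = 1e-3`, consistent with the
matching tolerance `P_tol = 1e-3`), the gene is in the jammed regime:
`kappa_I` stays at its upper bound and `k_T` is lowered instead. The
returned branch label records which regime applied. Unreachable targets
(beyond the packing limit of about `n/L` ribosomes) raise an error
carrying the achievable maximum.

Full packing (`rho = 1` exactly) is reached only asymptotically as
`k_T -> 0`, so the pipeline calibrates genes sitting at the density cap at
0.995 of full packing.

## Control coefficients

`control_coefficients()` quantifies rate limitation by metabolic control
analysis: `C_X = d ln J / d ln k_X` for X = initiation, elongation (all
codons perturbed jointly) and termination, evaluated by central finite
differences in log space (default 1% perturbation) with fully re-converged
steady states. Because the kinetics are homogeneous of degree one in the
three rate constants, the coefficients sum to one; the suite verifies
`|C_I + C_E + C_T - 1| <= 0.01` across the density range, and halving the
step changes each coefficient by less than `1e-3`. Genes are binned into
six control regimes — initiation-dominated (I) through
elongation-dominated (V), with VI collecting genes with termination
control at least 0.2; boundary values go to the lower-numbered group and
finite-difference noise below zero is clipped.

## Density estimation from fraction profiles

The seven elution fractions carry mean polysome sizes
`{B: 0, C: 0, D: 1, E: 2.1, F: 4.1, G: 7.4, H: 14}`. Fractions B and C are
non-engaged (ribosome-free, or co-sedimenting with a single ribosomal
subunit; the initiation-inhibition simulator below rationalizes the C
peak), so the ribosome occupancy `p_rib` is the replicate-averaged mass in
D-H. The polysome size estimator is the engaged-mass-weighted mean of the
fraction sizes — the only estimator consistent with fractions being
defined by their average ribosome load; a modal-fraction variant is
available behind a flag. Density follows as `rho = L * P / n`.

Two corrections wrap the raw estimate:

* **Co-elution recalibration.** mRNAs co-sedimenting with heavy
  non-ribosomal complexes inflate the last fraction and can imply
  `rho > 1`, which is physically impossible. `recalibrate_coelution()`
  removes the minimal H-fraction mass (closed form, iterated when
  replicate scatter shifts the average) to bring the gene to the cap, or
  excludes it when even an empty H fraction cannot. Mass is removed from
  fraction H only, matching the diagnosis that the excess sits in the
  heaviest fraction.
* **Operon handling.** Genes on one polycistronic transcript co-sediment
  at the transcript's total ribosome load. The conservative mode keeps
  that (deliberate) overestimate for every member; the shared mode splits
  the detected count among members in proportion to length.

## Stochastic simulators

`simulate_translation()` is an exact event-driven (Gillespie)
implementation of the same footprint rules on independent mRNA copies,
reproducible under `set.seed()`. It reports each copy's time-averaged
polysome size after a burn-in and its size at the final time — the
snapshot is what a gradient samples. The suite validates exactness against
the enumerated Markov chain of a 20-codon gene and exponential waiting
times in the initiation-limited limit (Kolmogorov-Smirnov, n > 10^4).

`simulate_with_inhibitor()` adds a per-copy bound/free state for a complex
blocking initiation (binding `k_on`, release `k_off`). With slow exchange
the copy distribution becomes bimodal — one near-empty mode, one at the
engaged mean — reproducing the double-peaked fraction profiles that
motivate treating fraction C as non-engaged.

`simulate_fragments()` asks whether incompletely transcribed or decaying
mRNAs could masquerade as partially loaded full-length copies: molecules
are born by a Poisson process, grow at the transcription rate (69 nt/s,
matching translation at 23 codons/s), wait an exponential time set by the
mRNA half-life, then erode processively (default 200 nt/s, a configurable
stand-in for the degradosome's speed). At stationarity the full-length
fraction has the renewal closed form
`tau_full / (tau_tx + tau_full + tau_deg)`; with a 5-minute half-life it
exceeds 95% for gene lengths from 97 to 311 codons, so fragments cannot
explain broad polysome distributions.

## The synthetic-data generator

`generate_catalog()` and `generate_profiles()` produce a study with known
ground truth so that every stage is testable without any external data.
Defaults emulate a 1108-gene bacterial catalog in triplicate:

* functional categories at the published composition (REG 73, UNK 383,
  TRD 96, TSP 103, NRJ 96, ... of 1108); the five categories without
  published counts (ENV, FAT, INT, REP, TRS) split the remaining 125
  genes evenly;
* control regimes at fractions 788/202/53/19/41/5 of 1108, each gene's
  true density drawn within its regime's interval (the top interval ends
  at 0.94 so that only contamination can imply an impossible density);
* gene lengths log-normal (median 280 codons, sdlog 0.6) *truncated* to
  `n <= 14 L / rho`: the heaviest fraction holds 14 ribosomes, so a gene
  observable at density `rho` cannot be longer — dense genes are short.
  Truncation uses inverse-CDF sampling to avoid a pile-up at the cap;
* occupancy Beta-distributed with mean 0.61 (the global engaged fraction,
  kept as reporting metadata), decreasing with mRNA half-life (2.8-18
  min, log-uniform) to mirror the observed negative coupling between
  stability and engagement;
* engaged mass split between the two fractions bracketing the true
  polysome size by linear interpolation — which makes the weighted-mean
  estimator exactly unbiased — plus a 10% spill to adjacent fractions for
  realistically broad peaks; multiplicative log-normal replicate noise
  (sdlog 0.1);
* co-elution contamination on 12% of genes *where it is observable*:
  non-operonic genes of density at least 0.6 for which an H-fraction
  contamination below 75% of the mass pushes the implied density past 1.
  When fewer genes qualify, all of them are contaminated. Contaminating
  long or sparse genes would be undetectable by the density-cap rule and
  would silently corrupt any recovery benchmark;
* operon members share one transcript density (the minimum of the
  members' draws, additionally bounded so the conservative overestimate
  stays below the cap), giving them identical pre-noise engaged
  distributions.

What passing the recovery tests shows, therefore, is that the estimators
are consistent under the generator's assumptions — interpolated dispersion,
independent multiplicative noise, detectable contamination. Real gradients
add effects the generator does not model: fraction cross-talk, baseline
subtraction errors, undetectable co-elution in long genes, and
condition-dependent fraction sizes.

## Category statistics

`absolute_rate()` converts the per-copy rate to the gene level,
`V_abs = m_rel * p_rib * V_s`, in arbitrary units because mRNA levels are
relative. `category_summary()` reports medians with notched intervals
`median ± 1.57 * IQR / sqrt(n)` (the standard notched-boxplot rule;
type-7 interpolated quartiles), and `compare_conditions()` calls a
category changed between two conditions when the notches do not overlap.
`operon_anova()` is a one-way fixed-effects ANOVA on replicate-averaged
proportions with genes as units. `enrichment()` is the one-sided
hypergeometric upper-tail test with raw p-values (an optional BH column is
off by default); on the published regulatory-category counts (64 of 73
inside a 788-gene group of 1108) it gives p = 4.8e-4, matching the
published value and confirming the test choice.

## Pipeline

`run_pipeline()` composes the stages — estimation, recalibration, operon
adjustment, calibration, control analysis, absolute rates, summaries,
enrichment — and returns per-gene results plus a run report (regime
histogram, shared-control fraction, excluded genes with reasons). Runs are
deterministic given seeds. TSV readers/writers and a thin command-line
wrapper (`inst/cli/ribotraffic-cli.R`, subcommands `generate`, `run`,
`simulate`) cover scripted use; the R functions are the primary interface.

```{r pipeline, eval = FALSE}
cfg <- generator_config(n_genes = 300, n_operons = 2, seed = 1)
gen <- generate_catalog(cfg)
profiles <- generate_profiles(gen$catalog, gen$truths, cfg)
run <- run_pipeline(gen$catalog, profiles)
run
```

## Numerical choices and problem sizes

* Solver tolerance `1e-8` (relative flux spread), iteration cap `2e6`
  sweeps; calibration matches polysome sizes to 0.1%.
* The saturation solve (initiation at its upper bound) is cached per
  `(n, L, k_E, k_T_max, tol)`, so density scans pay for it once; the
  cached object is itself deterministic, preserving bit-for-bit
  reproducibility.
* The test suite exercises genes of 100-2000 codons, density scans at
  0.01 resolution, stochastic runs of 200-300 copies over 600-1500 s, and
  a 300-gene synthetic study preserving the default composition; these
  sizes were chosen to probe every regime at desk scale.

## Known limitations

* The refined mean-field closure is accurate but not exact. Against the
  exactly enumerated 20-codon chain it overestimates the jammed polysome
  size by ~0.4%, and against exact stochastic simulation of a 200-codon
  gene near the maximal-current density it overestimates polysome size by
  about 2%. Per-copy snapshot comparisons resolve this bias at the
  transition density (about 3-4 standard errors with 200 copies) while
  agreeing well below and above it; per-copy *time averages*, with their
  much smaller standard errors, resolve it sharply. Any mean-field
  treatment of this process shares the limitation.
* Elongation uses one cell-averaged rate constant; codon-specific
  constants are accepted by the solver (`k_E` may be a per-codon vector)
  but the calibration and pipeline default to the uniform value.
* The co-elution rule can only flag genes whose implied density exceeds
  the cap; contamination of long or sparse genes passes through
  undetected, and for a flagged gene the minimal-removal correction
  returns the cap value, not the unknown true density.
* All ribosomes are assumed actively translating (no 5'-UTR pool), and
  the free-ribosome concentration is not estimated separately from
  `kappa_I`.
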