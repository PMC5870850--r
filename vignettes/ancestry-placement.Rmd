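---
title: "Placing individuals in a fixed PCA ancestry space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing individuals in a fixed PCA ancestry space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refplace)
```

## The problem

Genetic association studies need comparable ancestry estimates for samples
that were characterised with different genotyping arrays, different exome
capture kits, or sequencing at very different depths. Running PCA separately
per study does not give comparable coordinates: the axes depend on the
variant set and on the sampling of populations, and naively projecting new
samples onto fixed reference loadings shrinks them toward the origin
whenever the new sample contributes no information to the loadings
(the classic projection-bias problem).

`refplace` addresses this by anchoring everything to a *reference panel*:
N individuals with known population labels, densely genotyped at L
biallelic SNPs. PCA of the panel defines a K-dimensional ancestry space S
with reference coordinates Y. Each study individual is then placed into S
one at a time:

1. intersect the individual's usable sites with the panel sites;
2. run a *joint PCA* of the N + 1 individuals (panel plus the one study
   sample) on the shared sites, giving a K′-dimensional space S′ (K′ ≥ K);
3. fit a *projection Procrustes* transform mapping the N reference
   individuals from S′ onto their known coordinates in S;
4. apply that transform to the study individual's S′ coordinates.

Because the study sample participates in its own PCA, its position is
estimated without shrinkage; the Procrustes step only re-expresses the
joint axes in the common frame. The procedure repeats per sample, so two
cohorts typed on disjoint variant sets still land in the same coordinate
system.

## Projection Procrustes

Given source coordinates X (N × K′) and targets Y (N × K), the transform
minimises

$$\lVert \rho\, X_c A + \mathbf{1} b^\top - Y \rVert_F^2$$

over matrices A (K′ × K) with orthonormal columns, an isotropic scale
ρ > 0, and a translation b, with both configurations centred. For K′ = K
this is the classical orthogonal Procrustes problem and has the one-step
SVD solution. For K′ > K no single SVD solves it: the textbook device of
padding Y with K′ − K zero columns changes the objective (it additionally
penalises source variance outside the target subspace, which is exactly
the shrinkage the method is meant to avoid). `fit_projection_procrustes()`
therefore uses the standard padding *iteration*: the padded columns are
initialised at zero and replaced, after each classical Procrustes step, by
the transform's own trailing columns. Each step minimises the padded
objective exactly, the K-dimensional residual decreases monotonically, and
at convergence ρ equals the conditionally optimal
tr(AᵀX_cᵀY_c)/tr(AᵀX_cᵀX_cA), so a configuration that can be mapped
exactly is mapped exactly (verified against a random-search plus local
optimisation oracle in the test suite). Convergence is declared when D
changes by less than `tol` (default 1e-15) relative to tr(Y_cᵀY_c), with a
hard iteration cap; typical fits converge in under a hundred iterations.
On small configurations the fitter additionally runs a deterministic
multistart of the iteration and a quasi-Newton polish (plus a closed-form
generalized-Rayleigh candidate when K = 1), guarding against the local
optima and slow crawl that unstructured or ill-conditioned inputs can
induce; the internal draws use a private RNG stream, so the caller's
random-number state is never disturbed.

The *Procrustes similarity*

$$t = \sqrt{1 - D / \mathrm{tr}(Y_c^\top Y_c)}$$

summarises placement quality per study individual. The original
publications do not print the formula; this definition follows the
method's lineage, with the *target* variance in the denominator so that t
is comparable across study individuals sharing one reference space. Low t
flags samples with too little data for reliable placement and is the
recommended filtering statistic.

## Genotype and sequence modes

Genotype mode consumes VCF genotypes (alt-allele dosages 0/1/2). Sites are
matched to the panel by (chromosome, position); alleles must match the
panel pair exactly or be swapped (dosage then becomes 2 − d). Strand flips
are *not* attempted — a mismatching record is dropped — because silent
strand errors are worse than losing sites. Multi-allelic records are
skipped; the method is defined on biallelic SNPs.

Sequence mode consumes a pileup matrix: per-sample, per-site read depth,
reference-allele read count, and a per-site base-error rate. The study
dosage is taken directly from read fractions (2 − 2·ref/depth) with no
genotype calling. To make the joint PCA comparable, the reference panel is
*degraded to the same coverage*: at each site, reads are simulated over
every reference genotype g with alt-read probability
(g/2)(1 − ε) + (1 − g/2)ε at the study sample's own depth. This puts
reference and study data on the same noisy scale, which is the mechanism
that lets a 1× sample be placed in a space built from clean genotypes. The
resampling can be repeated (`reps`) and coordinates and t averaged;
the default is a single repetition, which is fast and adequate at the
panel sizes we target, with `reps` exposed for low-depth work. Joint
standardization uses statistics from all N + 1 rows in both modes — the
Procrustes step absorbs the resulting frame differences.

## Diagnostics

Two post-placement statistics are attached by `place_all()`:

* **kNN ancestry composition** — the population labels of the k nearest
  reference neighbours (Euclidean distance in S, ties broken by index),
  as fractions summing to one. The modal label is a simple ancestry call.
* **Z score** — placement can *succeed* geometrically while the panel is
  still wrong for the sample (e.g. a European panel used for non-European
  samples, where the sample clusters with whatever population is least
  distant). The Z score compares the study individual's genetic-variance
  statistic v with the same statistic computed for its k nearest
  reference neighbours on the same sites:
  Z = (v − mean(v_neighbours)) / sd(v_neighbours). We reconstruct v as the
  frequency-standardised mean squared dosage deviation,
  v = mean((g − 2p)² / (2p(1 − p))), with p the panel's alt-allele
  frequencies clipped to [0.01, 0.99] (protecting against
  monomorphic-in-panel sites). Under Hardy–Weinberg sampling from the
  panel's frequencies E[v] = 1, and an individual whose ancestry the panel
  does not represent shows inflated v at its (mismatched) neighbours'
  frequencies. The exact variance definition used by the original server
  is not public; ours is isolated behind `genetic_variance_statistic()` so
  an alternative is a one-function swap, and only the qualitative
  behaviour — calibrated in panel, inflated out of panel — is asserted.
  |Z| > 3 flags a sample (default threshold, `knn_k` = 20 neighbours so
  the standard deviation is stable).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 4 | ancestry space dimension; 4 suits continental-scale panels |
| `K_prime` | 20 | joint PCA dimension; capped at min(N, L′) with a warning |
| `scaling_mode` | `center_only` | per-site standardization; `center_scale` divides by √(p(1−p)) |
| `min_loci` | 100 | hard floor on shared sites; a warning is raised below 1000 |
| `reps` | 1 | read-resampling repetitions in sequence mode |
| `knn_k` | 20 | neighbours for composition and Z |
| `z_threshold` | 3 | \|Z\| flag level |

`center_only` is the default because variance scaling inflates
low-frequency sites and the placement geometry is driven by the common
variants; both modes are available and the choice is recorded in the
persisted ancestry space. K = 4 / K′ = 20 is the worldwide-analysis
operating point; finer regional panels may warrant larger K.

A note on K′ and self-consistency: replaying a reference individual as a
study sample reproduces its own coordinates *exactly* (to machine
precision) when K′ equals the full joint rank min(N, L′), because the
joint PC subspace then contains the reference PCs exactly. At the K′ = 20
operating point the containment is approximate and self-placement is
accurate to roughly 1e-3–1e-2 of the coordinate scale, with t ≥ 0.999
either way. The self-placement tests use the full rank; routine analyses
can stay at K′ = 20, where t, not exact reproduction, is the relevant
quality measure.

## The synthetic-data generator

No reference dataset ships with the package; `simulate_panel()` generates
structured panels under the Balding–Nichols model: ancestral alt-allele
frequencies uniform on (0.05, 0.95) (avoiding near-monomorphic sites that
destabilise scaling), population frequencies Beta-distributed around them
with divergence F, genotypes Binomial(2, q). `simulate_study()` draws
in-panel, admixed (mixed-frequency), or out-of-panel individuals (a fresh
population diverged at `outgroup_Fst`); `simulate_reads()` adds
Poisson-depth, binomial-error sequencing reads, optionally with per-sample
mean depth and an exome-style restricted target set.

The generator reproduces what the method consumes — population cluster
structure in PC space and coverage-dependent noise — and deliberately
omits linkage disequilibrium, selection, and realistic demography. Sites
are exchangeable for this method, so unlinked sites are adequate for
testing its geometry; but absolute performance numbers from these
simulations (e.g. how many sites are needed for a given t) do not
transfer to real data, where LD reduces the effective number of
independent sites. Passing tests demonstrate correctness of the
machinery, not field accuracy of any particular panel.

The test and acceptance runs use desk-scale study conditions throughout:
three populations at Fst 0.1, N = 150 reference individuals, L = 2000
sites, 5× shallow coverage with 1% base error, 80× on a 10% target subset
for the exome-style comparison, and an absent outgroup at Fst 0.2 for the
Z diagnostic. These sizes resolve the relevant structure cleanly while
keeping every check fast.

## Numerical choices and edge cases

* Missing genotypes are column-mean imputed before PCA (the standard
  dosage-PCA convention); a column that is entirely missing is an error
  unless statistics are supplied.
* PCA signs are fixed by making each loading's largest-magnitude entry
  positive (ties to the lowest site index), so results are reproducible
  across BLAS builds.
* Degenerate Procrustes inputs error (rank-deficient source, zero-variance
  target); near-tied singular values in X_cᵀY_c warn that A is non-unique
  (D and the placement are unaffected).
* Zero-variance sites get scale 1 under `center_scale`; panel frequencies
  are clipped to [0.01, 0.99] in the Z statistic.
* Sequence-mode randomness derives per-sample seeds from the master seed
  and a stable polynomial hash of the sample id, so batch results are
  identical for any worker count and any batch composition.
* t is clamped at 0 for numerically tiny negative values of
  1 − D/tr(Y_cᵀY_c).

## Limitations

* One sample at a time: related study samples or batch artefacts are not
  modelled (and relatives in the panel distort the space as in any PCA).
* Admixture is visible as intermediate placement but not quantified; no
  admixture proportions are estimated.
* The Z statistic is a reconstruction (see above); its absolute values are
  not comparable to the original server's, only its behaviour is.
* No BAM parsing: sequence mode starts from the pileup matrix format.
* No strand-flip reconciliation; ambiguous A/T, C/G sites at mismatched
  alleles are dropped rather than guessed.

## A worked example

```{r example, eval = FALSE}
library(refplace)

cfg <- sim_config(n_pops = 3, n_per_pop = 50, L = 2000, Fst = 0.1, seed = 1)
sim <- simulate_panel(cfg)
space <- pca_reference(sim$panel, K = 4)

study <- simulate_study(sim$freqs, rep(c("POP1", "POP2", "POP3"), 10), cfg)
placements <- place_all(sim$panel, space, study$study,
                        placement_config(K = 4, K_prime = 20))
placements |> write_placements("cohort.placements.tsv")
plot_placements(placements, space)
```
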