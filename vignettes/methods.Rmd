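---
title: "Structure-conditioned potentials: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-conditioned potentials: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
statistical models, the tunable parameters and their defaults, the numerical
conventions, the synthetic-data design, and the limits of what the bundled
experiments can show.

## 1. The models

### Contact potential

For a set of $n_c$ contacts, the contact potential is the log-odds of
observed against expected pair counts,

$$E(a,b) = -\log\frac{N_{\mathrm{obs}}(a,b)+\varepsilon}
                     {N_{\mathrm{exp}}(a,b)+\varepsilon},
\qquad
N_{\mathrm{exp}}(a,b) = n_c\, f(a)\, f(b)\, H(a,b),$$

where $N_{\mathrm{obs}}(a,b)$ sums both orders of a heterotypic pair,
$f(a)$ is the fraction of amino acid $a$ among the $2 n_c$ contact residues,
and $H(a,b) = 2 - \mathbb{1}[a=b]$ doubles the heterotypic expectation
because the potential is directionless. We use the quasichemical
normalisation in which the expectations sum to the number of contacts, so
that a database with no pair preferences yields energies that are zero up to
counting noise; this exactness is asserted in the tests. A formulation that
divides the marginal-count product by the total residue count instead
differs from ours only by a uniform $+\log 2$ offset, which no downstream
comparison (correlation, arg-min identification, ROC) can see; we chose the
variant in which the no-preference database gives exactly zero because that
is the property a reference state is for.

`cd_binned_potentials()` applies the same estimator to the contacts of each
of the 11 contact-degree bins separately, giving a family of potentials
indexed by a one-dimensional projection of contact geometry.

### Structure-conditioned energies

An interaction motif (1×1, 3×3 or 5×5) is used as a structural query; all
database fragments within an RMSD cutoff form its match ensemble $M$, and

$$\mathrm{SCE}(a_i,a_j) = -\log\frac{N_{\mathrm{obs}}(a_i,a_j)+\varepsilon}
                                    {N_{\mathrm{exp}}(a_i,a_j)+\varepsilon}$$

over the ensemble's central-pair counts. The reference state is a per-match
double softmax under the first-order background $E_1$:

$$N_{\mathrm{exp}}(a_i,a_j)=\sum_{m\in M}
  \frac{e^{-E_1(a_i|m_i)-\Delta_i(a_i)}}
       {\sum_{a}e^{-E_1(a|m_i)-\Delta_i(a)}}\cdot
  \frac{e^{-E_1(a_j|m_j)-\Delta_j(a_j)}}
       {\sum_{a}e^{-E_1(a|m_j)-\Delta_j(a)}},$$

with the residual $\Delta_p(a) = -\ln\!\big(N_o(a)/N_e(a)\big)$ chosen so the
expected marginals at each position reproduce the observed ones
($N_e(a)$ is the plain-$E_1$ softmax expectation). The matrix is *ordered*
(rows index position $i$); `symmetrize()` averages the two orders for
comparisons against symmetric contact potentials. Matches whose segments
aligned to the query in swapped order are order-corrected at search time, so
their counts contribute transposed, as they must for heterotypic statistics.

Assumptions worth keeping in mind: the ensemble members are treated as
independent observations (homologous database entries violate this — users
should supply non-redundant structure lists), and marginal deviations are
attributed entirely to first-order effects, which is the standard one-shot
approximation; an iterated variant is not implemented because the one-shot
form already reproduces marginals exactly in the flat-background limit.

### The hierarchical background $E_1$

Three tiers, each trained as a (conditional) statistical potential:

1. **φ/ψ** — 36×36 bins of 10°×10°, half-open $(\mathrm{lo},\mathrm{hi}]$
   over $(-180,180]$ so that $-180^\circ$ folds into the first bin;
   energies $-\log[(N_{\mathrm{obs}}(a,\mathrm{bin})+\tilde\varepsilon)/
   (f(a)\,N(\mathrm{bin})+\tilde\varepsilon)]$.
2. **ω** — cis ($|\omega|\le 30^\circ$) versus trans bins, with the
   expectation per bin taken from the smoothed φ/ψ-conditional amino-acid
   probabilities of the residues observed in that bin. A cis bin with fewer
   than 50 observations is merged into trans: cis/trans is the dominant
   signal and sparser splits are not statistically supportable at desk
   scale.
3. **burial** — the count of Cα atoms within 12 Å (excluding ±1 sequence
   neighbours), binned into five training-set quintiles, conditioned on the
   two previous tiers. The coordination-number proxy was chosen because the
   hierarchy, not the particular burial metric, is what carries the model's
   content; radius and level count are arguments.

The training pseudocount is one count per cell. `flat_background()` gives
the exactly-uniform model used for closed-form limits and null experiments.

### Contact degree

$$\mathrm{CD}(p_i,p_j)=\sum_{a,b}\sum_{r_i\in R_i(a)}\sum_{r_j\in R_j(b)}
  C(r_i,r_j)\,\mathbb{P}(a)\,\mathbb{P}(b)\,\mathbb{P}(r_i)\,\mathbb{P}(r_j),$$

where $C = 1$ when any heavy-atom pair between the two placed rotamers is
within 3 Å. "Allowed" rotamers are those whose side-chain heavy atoms stay
at least 2.5 Å from the main chain of every residue other than the host and
its two sequence neighbours — a tighter bond-adjacent tolerance mirroring
the 3 Å interference rule. After exclusion, rotamer probabilities are used
*unrenormalised* (occluded positions carry less total mass; a renormalised
mode exists behind the `renormalize` flag). $\mathbb{P}(a)$ defaults to
uniform for single-pair calls and to database amino-acid frequencies in
`enumerate_contacts()`; a user table is accepted everywhere.

Side-chain templates are grown from the backbone by ideal internal
coordinates as a coarse linear heavy-atom chain (CB from a fixed improper,
then one atom per chi torsion at 1.52 Å/113°). This deliberately simple
model is sufficient for clash counting, which is all CD needs; it is not a
rotamer-accurate side-chain builder and is documented as such.

## 2. Parameters and defaults

| Parameter | Default | Notes |
|---|---|---|
| RMSD cutoff | 1.0 / 0.79 / 0.77 Å | by motif size (1×1 / 3×3 / 5×5) |
| max matches | 50,000 | search truncation |
| minimum ensemble | 1,000 | warning threshold for sparse SCEs |
| pseudocount ε | max(N_obs, N_exp, 1)/20 | see §3 |
| Δ smoothing δ | 0 | see §3 |
| CD interference | 3 Å | heavy-atom pair distance |
| main-chain clash | 2.5 Å | rotamer exclusion |
| CD bins | 11, $[0,2^{-10}),\dots,[2^{-1},1]$ | half-open, last closed |
| scoring CD threshold | 0.1 | `score_model()` |
| same-chain separation | ≥ 5 residues between | contact enumeration |
| chain length filter | 40–10,000 | `filter_chains()` |
| cluster radius | 0.5 Å (RMSD), 0.3 (r_E) | greedy clustering |
| cluster sampling n | 1,000 | **no published value exists**; with $n \ge |S|$ the medoid choice is exhaustive |
| clustering rounds | 100 | one cluster per round |

## 3. Numerical choices

* **ε.** The pseudocount is reconstructed as
  $\varepsilon = \max(N_{\mathrm{obs}}, N_{\mathrm{exp}}, 1)/20$, which
  bounds the energy of zero-count pairs and vanishes in relative terms for
  well-populated cells; fixed (0.05), Laplace (1) and none modes are
  available. With no pseudocount, unobserved pairs are infinite and 0/0
  pairs are reported as 0.
* **δ.** The residual Δ is applied multiplicatively as the marginal ratio
  $N_o(a)/N_e(a)$, so an amino acid never observed at a position simply gets
  zero weight — no $-\infty$ is ever formed — and the flat-background limit
  $N_{\mathrm{exp}}(a,b) = N_o(a)N_o(b)/|M|$ and the $|M| = 1$ marginal
  identity hold to machine precision. A smoothing count $\delta > 0$
  (ratio $(N_o+\delta)/(N_e+\delta)$) is available but breaks those
  exactness properties, which is why the default is 0.
* **Tie-breaks.** Arg-min identification breaks ties lexicographically in
  the canonical alphabet `ARNDCQEGHILKMFPSTWYV`; ROC ties use the
  average-rank (midpoint) convention, making the AUC equal to the
  Mann–Whitney $U/(n_+n_-)$ statistic exactly. Greedy-cluster medoid ties go
  to the lowest index; search result ties order by structure id and
  addresses.
* **Bins.** φ/ψ and CD bins are half-open with the stated boundary
  conventions; both are asserted in tests at the exact boundary values.
* **Degenerate inputs.** Constant energy matrices flag the modified z-score
  (MAD = 0) and energetic distance (zero variance) as undefined with a
  warning; models with no qualifying contacts return a flagged empty score;
  empty CD bins yield zero matrices flagged `n = 0`.
* **Search prefilter.** The central-CA distance screen uses the bound
  $\mathrm{RMSD} \ge |d_q - d_t| / (2\sqrt{n})$ from the triangle
  inequality; it is provably conservative and the tests assert equality with
  an unfiltered double-loop oracle. Fragment windows within one chain must
  be disjoint and separated by at least one residue; the ≥5-residue rule
  applies to contact-database construction, not to match windows.
* **Alternate locations** resolve to the highest-occupancy conformer, ties
  to the first encountered, fixed for determinism.

## 4. The synthetic generators, and what they do not emulate

The generators make every experiment self-contained:

* `generate_synthetic_database()` builds two-segment structures (chains A/B)
  from ideal internal coordinates (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å,
  standard angles, ω = 180°) with per-residue dihedral noise and a rigid
  placement of segment B facing segment A at 5.5 Å — a typical
  side-chain-mediated contact distance. Noise defaults (σ = 3° dihedral,
  0.2 Å / 5° placement) give families whose pairwise motif RMSDs sit mostly
  inside the 3×3 ensemble cutoff, i.e. a "family" is one structural context.
* `generate_planted_ensemble()` plants central-pair sequences from a
  Potts-like model $P(a,b)\propto e^{-h_i(a)-h_j(b)-J(a,b)}$ by exact
  enumeration of the 400 outcomes. Couplings recovered from SCEs are
  compared in the double-centered gauge, since log-odds against
  marginal-matched expectations identify $J$ only up to row/column offsets.
* `generate_model_set()` adds isotropic Cartesian noise;
  `generate_torsion_decoys()` perturbs the backbone in torsion space with a
  rigid per-chain wobble. The scoring experiment uses the torsion-space
  decoys: Cartesian noise corrupts covalent geometry, to which rotamer
  placement (and hence the contact-degree metric) is directly sensitive, so
  contacts vanish before quality degrades; real low-quality models are
  locally plausible but globally wrong, which is what torsion-space decoys
  emulate.

What passing these experiments does **not** show about real data: the
generators have no side chains, no homology structure, no composition bias,
and sequence statistics enter only at the planted central pair. They
validate the estimators and the directionality of every comparison (SCE
versus CP), not database-scale effect sizes; the headline numbers of a
PDB-scale analysis (correlations of averaged energies, absolute enrichment
levels, absolute AUCs) depend on a large non-redundant structural database
that the package consumes but does not ship.

## 5. The bundled experiments

`scripts/acceptance.R` (and the acceptance tests) run, at sizes chosen to
keep each experiment in the minutes range on one core while the measured
statistics stay stable:

* **Nulls** — a 50,000-contact product-distributed CP, a coupling-free
  10,000-match SCE (the per-cell counting noise at 25 counts/cell is ~0.2,
  which is what the measured values show; the same statistic is also
  reported at 400,000 pooled draws where it shrinks toward zero), a
  geometry-independent 60-structure training run for $E_1$, and 1,000
  random-matrix $r_E$ draws against the uncorrelated reference of 1.
* **Recovery** — 5,000 planted matches, double-centered correlation with
  the known $J$.
* **Convergence** — 40 contexts × 3,000 matches whose couplings share a
  common component plus context deviations; the averaged symmetrized SCEs
  are correlated with the pooled-contact CP. The shared component is
  essential: with purely context-specific couplings the pooled potential
  has no signal to converge to.
* **Identification** — six families, each strongly favoring one
  family-specific pair; enrichment of SCE-based versus pooled-CP-based
  native-pair identification over the 1/400 chance rate.
* **Clustering** — eight geometric families × 15 motifs with
  family-specific couplings; greedy clustering by RMSD (d = 0.5) and by
  $r_E$ (d = 0.3) against size-matched random controls, comparing
  within-cluster cohesion in the *other* metric (the bidirectional
  structure–energy link).
* **Profile** — 48 motifs along a geometric continuum whose couplings
  interpolate with the placement angle; all pairs binned by RMSD with mean
  $r_E$ per bin (low bins well below 1, high bins at the uncorrelated
  reference).
* **Decoy scoring** — the full pipeline: a 50-structure planted database,
  an 8-contact native assembly, 20 torsion-space decoys over five noise
  levels, mean-SCE and mean-CE scores, Spearman ordering against
  RMSD-to-native and the SCE-versus-CP AUC comparison at the median-RMSD
  threshold.

## 6. Known limitations

* The fragment search is an exhaustive O(windows²) scan per structure —
  correct and adequate for desk-scale databases, but not an indexed search;
  no performance parity with dedicated fragment-search engines is intended.
* The coarse side-chain chain model underestimates the reach/branching of
  aromatic and branched residues; CD values are internally consistent but
  not calibrated against rotamer-accurate implementations.
* The burial metric and ω binning are reasonable defaults for an
  underdetermined part of the hierarchy; both are configurable and
  serialized with trained models.
* Sequence-identity filtering of structure lists is the user's
  responsibility (supply a non-redundant list); the package filters only by
  chain length and residue validity.
* Experimental coupling-energy sweeps require the user's structural
  database and coupling tables; the package ships the machinery
  (`coupling_sweep()`) and tests it on synthetic tables.
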