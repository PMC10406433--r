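---
title: "A fractal scaling model of biomolecular condensate architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fractal scaling model of biomolecular condensate architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condenscale)
```

## The model

Biomolecular condensates assembled from multivalent, often intrinsically
disordered proteins show structure on every length scale from single chains
(nm) to droplets visible under a light microscope (um). `condenscale`
implements an analytical formalism that bridges those scales using just two
single-molecule descriptors measurable in crowded-phase simulations:

* **compactness** $\varphi$ — the ratio of a chain's van der Waals volume to
  its hydrodynamic (apparent) volume, a volume fraction in $(0, 1]$;
* **valency** $n$ — the average number of chains simultaneously bound to a
  given chain. It is an ensemble average, so it is generally non-integer.

The assembly picture is iterative. A monomer of apparent radius $R_0$ and
mass $M_0$ binds $n$ partners, giving a cluster of $n+1$ molecules that fills
the fraction $\varphi$ of its own apparent volume. Clusters then associate
with the same valency and packing at every subsequent generation. With
$V_0 = \tfrac{4}{3}\pi R_0^3$ and $C_0 = 1/(N_A V_0)$, iteration $i$ has

$$N_i = (n+1)^i,\quad V_i = V_0\Big(\frac{n+1}{\varphi}\Big)^{i},\quad
R_i = R_0\Big(\frac{n+1}{\varphi}\Big)^{i/3},\quad M_i = M_0 (n+1)^i,\quad
C_i = C_0\,\varphi^{i}.$$

Eliminating $i$ between $N_i$ and $R_i$ gives the mass–size power law
$N = (R/R_0)^{d_f}$ with prefactor exactly 1 and

$$d_f \;=\; \frac{3\,\ln(n+1)}{\ln\!\big((n+1)/\varphi\big)},$$

the fractal dimension (`fractal_dimension()`). It is 3 when $\varphi = 1$
(space filling), decreases with either looser packing or lower valency, and
is strictly increasing in both parameters. Because the law is exact at every
iteration, `fit_mass_size()` on `iterate_assembly()` output recovers $d_f$
to machine precision, and `invert_fit()` is the closed-form inverse of the
forward map: from a fitted slope/intercept plus the monomer mass and van der
Waals volume it returns $(\varphi, n, R_0)$ exactly.

Two corollaries carry most of the interpretive weight. First, density
becomes scale-dependent: $C(R) = C_0 (R/R_0)^{d_f - 3}$
(`concentration_at_size()`), so a condensate can be locally concentrated yet
globally dilute — the exponent $d_f - d$ is the classic signature of a
fractal embedded in $d = 3$ dimensions. Second, valency sets the percolation
threshold through Flory–Stockmayer theory, $p_{crit} = 1/(n-1)$
(`percolation_threshold()`), connecting the architecture to the network
transition observed when contact probability exceeds it.

### Iteration indexing

Iteration `i = 0` denotes the monomer throughout. Descriptions that count the
monomer as "iteration 1" are offset by one: their third iteration is this
package's `i = 2`, e.g. $N_2 = (n+1)^2 \approx 22.7$ at $n = 3.76$, the scale
of a 24-chain simulation box.

### Units

Lengths are nm, masses kDa, concentrations mM, times ns (MSD), ps (pressure
autocorrelations) or s (FRAP), viscosities mPa·s, diffusion um^2/s. All unit
conversions live in one internal table; regressions are in $\log_{10}$ so
that the intercept is the log mass at $R = 1$ nm and is unit-stable.

## Per-chain descriptors

`chain_contacts()` declares two chains in contact when any interatomic
distance (all atoms, minimum image in a cubic box) is within the cutoff,
0.35 nm by default — the conventional 3.5 Å used with simulation
minimum-distance tools. Valency is the contact-graph degree
(`valency_series()`), contact probability divides by the $N-1$ possible
partners (`contact_probability()`), and `cluster_chains()` takes connected
components, which is exactly single-linkage clustering of the chain–chain
minimum-distance matrix cut at the cutoff.

Residue-level statistics count one event per residue pair per frame however
many atom pairs qualify, so large residues do not dominate. Intramolecular
events require sequence separation of at least 2. Enrichment compares
observed unordered-pair frequencies with a composition-based null; the
heterotypic expectation uses $2 f_A f_B$ (homotypic $f_A^2$) so that the
expected table, like the observed one, sums to 1 — with the plain
$f_A f_B$ product for unordered pairs the null would not normalize and every
heterotypic enrichment would carry a hidden factor of 2.

Analysis windows default to the trailing 30% of frames, the portion of a
relaxation trajectory usually treated as stationary. The representative
interaction mode picks the four chains at the (round-half-even) system-mean
valency whose 1D interaction profiles are mutually most correlated —
exhaustively among $\binom{k}{4}$ subsets for up to 20 eligible chains,
greedily beyond that — and reports the Pearson correlation against the
all-chain mean with a pass mark at $R > 0.6$.

Compactness combines a voxelized union-of-spheres van der Waals volume
(Bondi radii; 0.05 nm grid by default, refine for sub-percent accuracy on
small objects) with a hydrodynamic radius. The default estimator is the
Kirkwood double sum $R_h^{-1} = N^{-2}\sum_{i\neq j} r_{ij}^{-1}$; an
empirical $R_h = R_g/\rho$ alternative (default $\rho = 1.3$, a typical
disordered-chain ratio) is provided because published pipelines rarely state
their estimator. $\varphi > 1$ raises a warning rather than an error: it
flags an inconsistent estimator pair, not an impossible input.

## Transport and droplet observables

Diffusion coefficients come from the linear MSD regime,
$\mathrm{MSD} = c + 6 D^{PBC} \tau$, fitted inside an explicit window
(defaults 20–40 ns, the crowded-system choice; single molecules relax faster
and typically use 5–15 ns). The cubic-lattice finite-size correction
$D_t = D^{PBC} + k_B T \xi / (6\pi\eta L)$ with $\xi = 2.837297$ undoes the
hydrodynamic drag of periodic images, and `rescale_diffusion()` maps to the
experimental solvent viscosity (0.69 mPa·s for 0.1 M salt water at 310 K).

Green–Kubo viscosity integrates the autocorrelation of the six deviatoric
pressure components, $\eta_{ij} = \tfrac{V}{k_B T}\int_0^\infty C_{ij}\,dt$:
trapezoid on $[0, 1]$ ps, then the analytic integral of a double-exponential
fitted on $[1, 5]$ ps. Two numerical choices matter and were made after
observing how the estimator fails without them. (1) The fitted decay times
are bounded above by the fit-window end: a slower component cannot be
identified from a 5 ps window, and, fitted to the correlated noise floor of
an empirical ACF, it occasionally extrapolates to an arbitrarily large (or
negative) integral. (2) The tail *shape* is fitted once on the average of
the six component ACFs — they are statistically equivalent, so pooling
suppresses the noise floor by $\sqrt{6}$ — after which each component scales
the shape to its own tail and is integrated separately; the reported
viscosity averages the six integrals (averaging after integration). On
planted-viscosity fixtures this estimator is unbiased with a worst-case
error under 5% at the default series length.

FRAP recovery is fitted to $C(t) = 1 - a e^{-t/\tau_a} - b e^{-t/\tau_b}$ by
bounded Levenberg–Marquardt with at least five seeded starts; components are
ordered $\tau_a \le \tau_b$ and vanishing amplitudes are flagged degenerate
rather than rejected. The half-time solves
$C(t_{1/2}) = C(0) + \tfrac{1}{2}(1 - C(0))$ — half of the bleached depth —
which reduces to the plain $C = 0.5$ crossing when $a + b = 1$ and stays
well-defined for partial bleaches; the fitted curve is monotone, so the root
is unique. Circularity is $4\pi\,\mathrm{area}/\mathrm{perimeter}^2$ on
precomputed area and perimeter.

### What FRAP parameters can(not) be recovered

At realistic acquisition settings (32 frames over 20 min, 2% intensity
noise) the four double-exponential parameters are only weakly identified:
the Cramér–Rao bound at $(a, b, \tau_a, \tau_b) = (0.6, 0.3, 50, 300)$ gives
relative standard deviations of roughly 7%, 16%, 12% and 15%. No estimator
can return every parameter within 10% on every noisy realization. The test
suite therefore checks *mean* recovery (bias) across 50 seeded curves, plus
per-curve recovery of the half-time, which is a well-conditioned functional
of the curve even when the two components trade off against each other.

## Reconstructing aggregates

`build_aggregate()` produces explicit particle configurations with a
prescribed $d_f$ and prefactor 1, by hierarchical tunable cluster–cluster
aggregation: particle-cluster growth to subclusters of about $\sqrt{N}$
particles, then pairwise cluster–cluster merging. At every sticking event
the center-of-mass separation is solved from the scaling law
$R_g = a N^{1/d_f}$ ($a$ = mean particle radius), a random orientation is
drawn, and the exact touching contact is located by root-finding on a
rotation angle — so the minimum inter-particle gap is exactly zero at
contact, no overlaps occur (relative tolerance $10^{-3}$), and the contact
graph stays connected.

One geometric fact shapes the construction: with prefactor 1 and low $d_f$
the law is unattainable for very small clusters (three touching spheres
cannot reach $R_g = a\,3^{1/1.63}$; the collinear chain bounds $R_g$ by
$a\sqrt{(N^2-1)/3}$). Placement radii are therefore clamped to the feasible
contact range and the construction converges onto the exact law as soon as
geometry allows — from $N \approx 5$ at $d_f = 1.63$, immediately at
$d_f \gtrsim 2.4$. Recorded subcluster $(N, R_g)$ pairs above that threshold
satisfy the law to within 5%, and regressing them recovers the target slope
to two decimals.

`measure_df()` estimates the dimension of any particle configuration from
the mass–radius relation $N(r) \propto r^{d_f}$. The naive version — counts
about the single center of mass — has seed-to-seed scatter of $\pm 0.5$ at
1024 particles and is not usable as a check. The implemented estimator
averages cumulative counts over *interior* reference particles (within half
the maximal center-of-mass distance) and never counts beyond a center's
distance to the aggregate envelope, suppressing edge truncation; on built
aggregates it recovers $d_f \in \{1.63, 2.09, 2.42\}$ within $\pm 0.2$ with
a standard deviation of about 0.03.

`decorate()` replaces each particle by the library conformer with the
nearest radius of gyration (random tie-break), randomly rotated, center of
mass on the particle center; a conformer must match the particle radius
within 25% or the mismatch is reported. Steric clashes between neighboring
chains are permitted, as in visual condensate models. Note the two radius
conventions touching here: primary-particle radii are chosen as mean chain
$R_g$ values, while contacts during construction use those radii as hard
spheres.

## Synthetic fixtures

Every analysis path has a seeded generator emitting its ground truth
(`ground_truth()`, or a `.truth.json` sidecar via `write_fixture()`):

* `gen_polymer()` — self-avoiding bead-per-residue walks (bond 0.38 nm,
  exclusion 0.35 nm, 4 pseudo-atoms per residue with carbon radii), either
  confined so $R_g$ falls below the disordered-coil reference
  $0.254\,N^{0.522}$ nm, or persistent and extended above it. Pseudo-atomic
  chains exercise the contact/volume/Rg code paths at a fraction of the cost
  of full chemistry; they carry no sequence-specific energetics.
* `gen_scene()` — crowded periodic boxes with an exactly planted contact
  graph: bonded chains touch within 0.30 nm, all others stay beyond 0.6 nm,
  margins on both sides of the 0.35 nm cutoff so descriptor output is
  invariant for cutoffs in $[0.33, 0.40]$ nm. Chains are rigid core-plus-arm
  constructs placed by force-directed layout and verified by brute force.
  Graphs must be geometrically realizable (vertex degrees up to ~5).
* `gen_frap()` — the double-exponential model on an acquisition-style
  schedule (frame spacing doubling in four blocks to 20 min) with Gaussian
  noise.
* `gen_msd()` — the linear MSD model with Gaussian noise.
* `gen_pressure()` — sums of Ornstein–Uhlenbeck processes whose ACF is a
  planted multi-exponential; defaults (10 ns at 10 fs output; decay times
  0.2 and 1.0 ps carrying 80%/20% of the Green–Kubo integral) represent
  solvent-like pressure decorrelation matched to the numeric-plus-fitted-tail
  integration protocol.

What passing tests on these fixtures shows is that the estimators are
correct and well-calibrated on data obeying their stated models; it does not
validate force fields, sampling, or microscopy pipelines, and real
trajectories add slow correlations and anisotropies that none of the
generators emulate.

## Problem sizes in the test suite

The suite runs at desk scale by choice: oracle comparisons use scenes of 5
chains × 50 atoms; builder/estimator closure uses 1024-particle aggregates
(5 seeds × 3 dimensions); FRAP calibration uses 50 seeded curves;
Green–Kubo closure uses 3 seeded 10-ns series. Everything completes in a
few minutes on one core.

## Known limitations

* The formalism assumes scale-free valency and packing; real condensates may
  cross over between regimes (e.g. reaction- vs diffusion-limited
  aggregation) and have a finite fractal range.
* `cluster_chains()` reports cluster radii from coordinates as stored;
  clusters wrapped across periodic images are not re-imaged.
* The builder is a geometric generator, not an aggregation kinetics
  simulator; it prescribes $d_f$ rather than predicting it from dynamics.
* PDB output is limited by the format's fixed fields; µm-scale decorated
  aggregates fall back to XYZ automatically.
* The isocurve helper estimates the monomer van der Waals volume from mass
  (1.21 nm^3/kDa, typical protein density) unless given explicitly.
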