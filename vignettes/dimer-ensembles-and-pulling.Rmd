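---
title: "Methods: dimer ensemble analysis and Monte Carlo pulling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer ensemble analysis and Monte Carlo pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerpull)
```

# Scope and model

`dimerpull` implements the analysis chain used to characterize
conformational ensembles of small peptide dimers — the motivating system
is the amyloid-beta (1–40) dimer with an N-terminal Cys anchor on each
chain, 41 residues per monomer — and to decide, by simulated force
spectroscopy, which candidate dimer conformation is compatible with an
experimental rupture dataset. Nothing in the package requires that
specific peptide: every stage operates on generic chains.

The package deliberately separates three layers:

1. **Ensemble analysis** of conformations (secondary structure, RMSD
   clustering, dihedral PCA landscapes, contact maps, shape
   descriptors). These are deterministic functions of coordinates.
2. **Monte Carlo pulling (MCP)** on a structure-based energy model,
   producing stochastic rupture forces and rupture positions.
3. **Statistics** that compare rupture datasets (Gaussian mixture peaks,
   contour-length-normalized interaction patterns, two-sample
   Kolmogorov–Smirnov decisions).

A synthetic-data module generates inputs with known ground truth for all
three layers, because no reference trajectories are distributed with the
package.

# Secondary structure from dihedrals

The dihedral criterion labels a *pair* of consecutive residues helical
when both lie in the box $-80^\circ \le \phi \le -48^\circ$,
$-59^\circ \le \psi \le -27^\circ$, and strand-like for
$-150^\circ \le \phi \le -90^\circ$, $90^\circ \le \psi \le 150^\circ$;
bounds are inclusive (the criterion is printed with $\le$ throughout).
Because the two $\phi$ intervals are disjoint, a residue can never be
$\alpha$ and $\beta$ in the same frame — an invariant the tests assert.

Two readings of "the pair is helical" exist: mark both residues, or only
the leading one. We mark **both** (`pair_rule = "both"`), the natural
symmetric reading; the alternative is exposed as an option and changes
only the bookkeeping, not the box logic. Terminal residues, whose
$\phi$ or $\psi$ is undefined, are never imputed and therefore never
labeled.

Windowed fractions are plain indicator means over a window
$[s, s+\Delta)$ with $\Delta = 1$ ns by default; the per-residue
indicators $\delta_{i,\alpha}, \delta_{i,\beta}$ are averaged over both
residues and frames. An optional running-average filter (default 10
windows) is provided for display only; the raw series is always
retained, since the filter width is a presentation choice.

The hydrogen-bond assigner is a reduced DSSP: backbone H-bonds by the
Kabsch–Sander electrostatic criterion ($E < -0.5$ kcal/mol, amide H
placed 1.01 Å from N anti to the preceding carbonyl, prolines donate
nothing), helix H from two consecutive $i \to i+4$ turns, strand E from
the canonical parallel/antiparallel bridge patterns, coil otherwise.
The full 8-class DSSP alphabet (3–10/π helices, turns, bends, isolated
bridges) is out of scope. Both fixtures used in the tests — an ideal
12-residue helix and an antiparallel two-strand sheet — were validated
once against an independent reference DSSP implementation run on the
identical coordinates, and the resulting labels are frozen in the test
suite.

# GROMOS clustering and RMSD

Pairwise RMSD uses Kabsch superposition on backbone atoms (N, CA, C, O
by default). Clustering is the GROMOS neighbor-count algorithm: pick the
frame with the most neighbors within the cutoff (default 0.45 nm =
4.5 Å) as a center, remove it and its neighbors, repeat. Ties in
neighbor count are broken toward the lowest frame index, which makes the
output deterministic; clusters are reported in descending population.
The optional `progressive_fit()` pre-step mirrors trajectory
de-drifting; clustering itself always uses pairwise minimal RMSD, so the
pre-step cannot change cluster assignments.

# Dihedral PCA and free-energy landscapes

Features are $(\cos\phi_i, \sin\phi_i, \cos\psi_i, \sin\psi_i)$ for
every residue with both angles defined — the established dPCA
convention, which avoids angular periodicity artifacts. PCA is plain
mean-centered covariance PCA; component signs are fixed by making each
component's largest-magnitude loading positive, so fits are reproducible
to the sign.

The landscape over (PC1, PC2) is a 2-D histogram (default $64 \times 64$
bins) with $\Delta G = -\ln(n_{bin}/n_{max})$ in units of $k_BT$: the
modal bin is 0 and empty bins are reported as missing (infinite), never
interpolated — a finite cap would fabricate barriers. Temperature only
labels axes.

Minima detection uses persistence: occupied bins are processed in
increasing $\Delta G$ with union-find merging over 8-neighborhoods; a
basin survives as a separate minimum only if it is at least `min_depth`
(default 0.5 $k_BT$) deep at the level where it would merge into a
deeper basin, and at least `min_separation` (default 2) bins from any
deeper kept minimum. Two numerical guards matter in practice:

* **Occupancy floor** (`min_count`, default 5): on a log scale the
  difference between 1 and 2 counts is already $\ln 2 \approx 0.69\,k_BT$,
  larger than any sensible depth threshold, so isolated low-count tail
  bins would always masquerade as minima. Bins below the floor are shown
  in the landscape but never reported as minima.
* The global minimum is always reported, so a single-bin landscape has
  its one trivial minimum.

Representative structures are the frames nearest (in PC space) to each
minimum's bin center.

# Contact maps and shape descriptors

Contact probability maps are indicator means of CA–CA distances within a
cutoff. The criterion names no cutoff; we default to **0.8 nm**, the
standard residue-contact convention, and make it configurable.
Intra-chain maps are symmetric and may mask $|i-j| \le 2$ for reporting;
difference maps are monomer 1 minus monomer 2 (the sign convention is
not otherwise fixed, so it is stated here and in the docs). Because maps
are indicator means, concatenating ensembles averages maps with frame
weights *exactly* — a property test, not an approximation.

Shape descriptors: mass-weighted radius of gyration; solvent accessible
surface area by Shrake–Rupley (960 deterministic golden-spiral points,
probe 0.14 nm, Bondi-type van der Waals radii keyed by element); volume
as the convex hull of atom centers (an in-package incremental 3-D hull;
a convention choice documented as such — other tools report grid or
voxel volumes).

# The Monte Carlo pulling engine

The total energy during pulling is

$$E_{tot}(x, t) = E(x) + \tfrac{k}{2}\,\bigl[L(x) - L_0 - v\,t\bigr]^2,$$

where $E(x)$ is the conformational energy, $L(x)$ the instantaneous
distance between the two anchor atoms (the CA of each chain's N-terminal
residue by default), $L_0$ its initial value, $k$ the virtual-spring
constant and $v$ the anchor-target speed. Time $t$ advances one unit per
MC **sweep** (one attempted move per mobile bead). The published
per-step speed of 0.083 fm maps to 500 nm/s as a pure unit conversion
(`velocity_mapping()`); per sweep it is multiplied by the number of
mobile beads.

$E(x)$ is a CA-level structure-based (Gō-type) model built from the
input conformation: 12-10 wells of depth $\varepsilon$ (kT) at each
native contact (CA pairs within 0.8 nm; intra-chain $|i-j|\le2$
excluded), stiff harmonic pseudo-bonds at observed consecutive CA
distances, and $r^{-12}$ excluded volume elsewhere. This backend is a
deliberate substitution for the original implicit-solvent force field of
the source method: the scientific content — rupture forces and
interaction patterns that depend on the *conformation* being pulled — is
preserved exactly because the attractive interactions are defined by
that conformation, while a full force-field reimplementation is neither
documented nor desk-scale. The energy backend is a narrow interface
(`go_energy()`) so an alternative can be plugged in.

Moves are single-bead Gaussian displacements (sigma auto-tuned to
~40% acceptance before production) mixed 4:1 with crankshaft rotations;
Metropolis acceptance uses energies in kT. The trace records
$F = k\,(L - L_0 - v t)$, which is negative while the chain resists the
receding target — the recomputation-exact convention the tests assert.
**Rupture** is the maximal force magnitude before the inter-chain native
contact count stays zero for a dwell window (default 100 sweeps; a
contact counts as formed while $r \le 1.5\,\sigma_{native}$). Runs that
never separate within `max_sweeps` are reported as censored, never
silently dropped into the statistics.

Defaults with units: $k = 35$ pN/nm (AFM-cantilever-like), $T = 300$ K,
$v = 0.083$ fm/step. The source protocol states neither $k$ nor $T$;
both matter only through the ratio of spring stiffness to thermal energy
and are configurable.

Two calibration notes, verified by the test suite:

* With $v = 0$ and a single free bead on the spring, the sampled
  extension is Boltzmann for a 1-D harmonic well. The test tethers the
  free bead at $L_0 = 50$ nm so the radial Jacobian $(L/L_0)^2$ is
  negligible, and thins to every 10th sweep to de-correlate samples
  before the chi-square comparison.
* The "rupture force within 25% of the maximal well slope" oracle is
  only physically meaningful in the near-deterministic regime: at modest
  well depths, thermally activated escape lowers rupture forces well
  below the static maximum (the Bell–Evans picture), which is correct
  behavior, not an engine defect. The oracle experiment therefore uses a
  deep single contact (150 kT) and a finite ramp; the measured mean is
  ~0.85 of the static maximum.

# Rupture statistics and validation

Positions are normalized by a contour length (default 41 residues
x 0.4 nm/residue = 16.4 nm, configurable); events outside $[0,1]$ after
normalization are flagged and excluded, never clipped. Peak structure is
fitted with a 1-D Gaussian mixture by EM (kmeans-seeded, deterministic
under a seed) with BIC choosing the component count; peak centers are
mapped to N-terminal / central / C-terminal thirds of the pulling
coordinate.

`ks_compare()` is the two-sided two-sample KS test (exact p for small
samples, asymptotic for large, following the standard implementation);
"similar" means $p > \alpha$. `validation_report()` compares every
candidate with the reference on forces **and** normalized positions and
flags a candidate similar only if both tests pass at the Šidák-adjusted
per-test level $1-(1-\alpha)^{1/2}$, so the familywise error over the
two variables equals the user's $\alpha$. A plain per-test conjunction
at $\alpha$ would make even the true twin of the reference fail ~10% of
the time, which contradicts the intended meaning of "similar at the 5%
level". The conjunction is configurable (`adjust = "none"`, or
force-only via `variables`). Candidates are ranked by Fisher-combined p.

One consequence worth stating plainly: for a candidate that *does* share
the reference's generating distribution, the probability of being
flagged similar is ~0.95–0.96 by construction. Any experiment that
repeats the decision 100 times and demands at least 95 successes is
sampling a Binomial(100, ~0.956) count and will occasionally observe 93
or 94. The acceptance machinery reports the observed count; it does not
adjust anything to force it over the line.

# The synthetic-data generators

`sample_dihedral_chain()` draws a per-residue state
(alpha / beta / coil) from a propensity profile independently per frame,
assigns $(\phi,\psi)$ uniformly inside the corresponding criterion box
(coil: uniformly outside both boxes), and rebuilds the backbone (N, CA,
C, O, CB stubs) at ideal bond geometry with $\omega = 180^\circ$. This
emulates exactly what the downstream stages consume — dihedral
statistics and CA geometry — and nothing else: there is no physical coil
ensemble, no side chains, no solvent, and no frame-to-frame kinetics
(frames are i.i.d.). Green tests therefore establish correctness of the
analysis code, not realism of the ensemble.

A steric filter rejects frames with any non-bonded atom pair closer than
0.25 nm (atoms of the same or adjacent residues are exempt — even ideal
geometry places O$_i$ and N$_{i+1}$ at ~0.23 nm) and resamples up to 50
times, keeping the least-clashing frame with a warning if exhausted.
Because rejection conditions the state distribution, statistical
recovery tests against the i.i.d. enumeration oracle disable the filter
(`min_separation = 0`).

`build_dimer()` docks the second chain by best-of-K random rigid
orientations scored on satisfaction of requested inter-chain CA contact
pairs plus a clash penalty — simple, seedable, and sufficient to realize
prescribed contact architectures (e.g. C-terminal/C-terminal corners) in
$\ge 90\%$ of frames. `sample_rupture_data()` draws i.i.d.
(force, position) pairs from a Gaussian mixture with rejection at the
physical boundaries (force $\ge 0$, normalized position in $[0,1]$).
Default experiment-like parameters used throughout tests and the
acceptance script are the printed dissociation-force statistics
56.6 ± 20.5 pN (experimental reference), 36.5 ± 18.4 pN and
61.7 ± 27.5 pN (simulated candidates).

All generators are bit-identical under a fixed seed.

# Known limitations

* No trajectory formats beyond multi-model PDB (no XTC/DCD reader in
  the supported dependency set); no mmCIF writing; no solvent or ions.
* The Gō backend cannot reproduce absolute rupture forces of any
  specific force field; it targets the protocol and the
  conformation-dependence of rupture patterns.
* The coil ensemble is statistical, not physical; H-bond assignments on
  generated coil frames are meaningful only as negative controls.
* Cluster populations, per-residue probabilities, SASA ranges and
  absolute dissociation forces reported for the original
  microsecond-trajectory study are not reproducible here: those depend
  on trajectories that were never deposited.
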