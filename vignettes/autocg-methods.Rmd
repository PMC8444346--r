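---
title: "autocg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{autocg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

autocg builds Martini-2-compatible coarse-grained (CG) models of organic
molecules from SMILES strings, and extracts membrane--water partition
coefficients from free-energy profiles.  This vignette explains the models
and procedures, the tunable parameters, the numerical choices, and what the
synthetic fixtures used in the test suite do and do not demonstrate.

## The mapping model

A molecule is represented by its heavy-atom graph (hydrogens are implicit;
they contribute to fragment capping and bead masses only).  Atom order is
canonical — derived from the OpenBabel canonical SMILES — so the same
molecule written in any atom order produces byte-identical results.

Mapping proceeds in three stages.

**Predefined ionic fragments.**  Strongly ionic head groups are matched
first and receive fixed bead types, because the generic free-energy route
below is only defined for neutral fragments and the Martini 2 menu of
charged types is small.  The shipped patterns are organic sulfate
(SO$_4^-$ $\rightarrow$ Qa) and sulfonate (CSO$_3^-$ $\rightarrow$ Q0); the
set is extensible through `autocg_config(ionic_patterns = ...)`.

**Ring systems.**  Fused systems of five- and six-membered rings are mapped
by patterns: maximal chains of atoms belonging to a single ring are split
into beads of 2--3 ring atoms (2 at the default *trimer* resolution — three
beads per six-ring — and 3 at *dimer* resolution), mapped atoms are removed,
and the step repeats.  A chain of $k$ atoms splits as $2 \to [2]$,
$3 \to [3]$, $4 \to [2,2]$, $5 \to [3,2]$, $6 \to [2,2,2]$ (trimer), with a
unique odd bead centred whenever the flanks split evenly.  Whatever remains
when no intact ring survives (e.g. the two fusion atoms of naphthalene) is
grouped by one spectral pass limited to a path length of two bonds.  Rings
of other sizes are handled best-effort with a warning.

**Spectral grouping.**  The remaining atoms form nodes of a weighted
adjacency matrix: off-diagonal entries are 1 for bonded node pairs, and the
diagonal weight of node $i$ is $l_i \bar m_i$, the product of its internal
maximum path length (bonds) and mean heavy-atom mass.  Nodes are ranked by
the components of the leading eigenvector (centrality scores) and visited in
ascending rank; each node merges with its closest-ranked neighbour of equal
or higher rank, with two symmetry rules:

* multiple tied nodes that simultaneously pick the same neighbour merge
  together with it;
* a node whose *closest* neighbours are themselves tied (symmetry-equivalent)
  merges with all of them or not at all.

Any merge whose combined bead would exceed an internal path length of three
bonds is rejected and its constituents stay separate.  Passes repeat until
no new beads form.  The second rule is this package's reading of an
under-determined corner: it is what keeps the nitrogen of trihexylamine
single (to be resolved by postprocessing) instead of breaking the molecule's
three-fold symmetry, at the cost that a chain like hexane settles at three
two-carbon beads (its two tied ends and the centre always propose a merge
that violates the size limit together).

A note on eigen-degeneracy: the weighted adjacency matrix of a connected
node graph is non-negative and irreducible, so by Perron--Frobenius its
largest eigenvalue is simple and the leading eigenvector can be taken
strictly positive.  No degenerate-eigenspace handling is therefore needed;
the implementation asserts connectivity and normalizes the Perron vector
(unit norm, positive entries).  Score ties within a relative tolerance of
$10^{-8}$ form tie groups; residual ambiguity falls back to the lowest
canonical atom index, which makes every run deterministic.

**Postprocessing.**  Leftover single atoms take one heavy atom from their
highest-ranked non-ring neighbour bead — from all equally ranked neighbours
simultaneously, which preserves symmetry.  Beads touched by past transfers
are tagged and skipped, preventing atoms from ping-ponging.  A single atom
bonded to a terminal two-atom bead merges with it (and atoms are never taken
*from* such terminals, which would spawn unresolvable terminal singles); one
whose only usable neighbour is a ring bead is absorbed into the
highest-ranked ring bead.  If no neighbour can donate an atom without
disconnecting itself, the single atom merges into the highest-ranked
neighbour that still satisfies the size limit.  The loop is bounded by the
atom count and ends with every bead at $1 \le l \le 3$.

## Bead typing

Each bead's fragment is capped with hydrogens (every cut bond frees a
valence) and canonicalized.  Its octanol--water transfer free energy
$\Delta G_{OW}$ comes preferentially from a bundled fragment table
(~90 curated experimental log P values, keyed by canonical SMILES and
user-replaceable), falling back to a native implementation of the published
Wildman--Crippen atom-contribution method.  Conversion uses
$\Delta G_{OW} = -RT\ln(10)\,\log P$ at `temperature_K` (default 300 K;
hydrophobic fragments get negative transfer free energies).  The Martini
type with the nearest reference $\Delta G_{OW}$ wins; within
`nda_window_kj` (default $\pm$1.0 kJ/mol) of the Nda reference,
hydrogen-bond roles select Na/Nd/Nda instead.  Charged beads are typed
purely by hydrogen bonding (Qda/Qd/Qa/Q0).  Ring beads always receive the
S-variant.

Aromatic beads are typed through a standardized test ring: the bead's ring
atoms (plus absorbed substituents) are completed to a six-membered aromatic
ring — five-membered when six cannot be kekulized, as for pyrrole-type
fragments — and the candidate type minimizes
$|\Delta G_{OW}(\text{test}) - (\Delta G(\text{cand}) + n_f\,
\Delta G(\text{filler}))|$, an additive model with filler N0 at trimer
resolution and C5 at dimer resolution.  Whether the combination should be
additive or use precomputed whole-ring values was an open choice; the
additive model is used because it extends uniformly to heteroaromatics.

The bundled Martini reference ladder is a versioned configuration file.  Its
ordering follows the polarity ladder of the Martini 2 force field (Marrink
et al., J. Phys. Chem. B 2007); the absolute per-bead scale is anchored so
that benzene is best matched by an N0 trimer and a C5 dimer, which pins
N0 at $-4.08$ and C5 at $-6.10$ kJ/mol per bead.  Na and Nd carry the Nda
reference value and are marked window-only so that the nearest-distance rule
never faces a three-way tie.  Users validating against their own reference
data should replace the table rather than edit code.

## Bonded terms and conformers

Bond lengths and angles are averaged over a conformer ensemble mapped to CG
resolution (bead position = mass-weighted centre with hydrogen masses folded
onto their heavy atoms).  A bond is emitted for every bead pair joined by an
atomistic bond and an angle for every connected triplet, except when all
participating beads belong to one ring system.  Force constants default to
the standard Martini values (1250 kJ mol$^{-1}$ nm$^{-2}$ bonds,
25 kJ mol$^{-1}$ angles) and are configurable.

The ensemble itself comes from a deterministic two-step construction:

1. a reference geometry built from the graph — covalent-radius bond lengths
   with bond-order factors, tetrahedral/trigonal/linear angles by
   hybridization, and fused rings laid out as planar regular polygons
   sharing edges;
2. a knowledge-based torsion driver that resamples every rotatable bond from
   standard rotamer states (anti/gauche for sp$^3$, planar for sp$^2$-flanked
   bonds) with 8$^\circ$ Gaussian jitter, rejecting conformers whose
   nonbonded heavy atoms approach closer than `clash_dist_nm`.

There is no force-field minimization.  The idealized internal geometry
differs from a minimized one at the percent level in bond lengths, which is
below the precision at which Martini bonded parameters are meaningful; in
exchange, the whole pipeline is exactly reproducible from a seed, which a
stochastic embedder cannot provide.  The default ensemble size is 200
conformers; the suite uses 5--30 for speed, relying on the scaling property
rather than absolute convergence.  Saturated rings are treated as planar
polygons, so cyclohexane chair/boat geometry is not reproduced — acceptable
for CG bead distances, but a known limitation.

## Rigid ring frameworks

Each ring system of three or more beads is projected onto its plane (the
eigenvectors of the two smallest inertia-tensor eigenvalues).  Convex-hull
beads become *real* sites; interior beads become *virtual* sites, except
that an interior bead bonded to a substituent is promoted to real so that
bonds never act on virtual sites.

A virtual site is a weighted combination of its four nearest real sites in
the projection (three when only three exist).  For $n=3$ the weights are the
unique barycentric solution.  For $n=4$ the system is underdetermined and
the weights are chosen to balance the force redistributed onto the
constructing sites: the site is written as the intersection of two lines
spanning the quadrilateral, with edge fractions $\beta_h$ and $\beta_v$,
giving bilinear weights $\{(1-\beta_h)(1-\beta_v),\ \beta_h(1-\beta_v),\
\beta_h\beta_v,\ (1-\beta_h)\beta_v\}$ on the cyclically ordered corners.
$\beta_v$ solves the quadratic obtained by cross-product elimination of the
inverse bilinear map ($a_2\beta_v^2 + a_1\beta_v + a_0 = 0$ with
$a_2 = -B\times D$, $a_1 = p\times D - B\times A$, $a_0 = p\times A$, where
$A, B, D$ are the corner difference vectors and $p$ the shifted site).  The
root with both fractions in $[0,1]$ is taken; if both qualify, the one
minimizing the largest weight.  Weights always sum to one and reproduce the
site position to better than $10^{-9}$ nm; a site outside its constructors'
hull is an error, because a negative weight would invert the force it
redistributes.

Real sites are rigidified with the minimum interaction count: a closed ring
of distance constraints in cyclic order plus zig-zag chords that triangulate
the polygon ($2n-3$ constraints for $n$ sites, the planar rigidity minimum),
and one harmonic dihedral per hinge (adjacent triangle pair), $n-3$ in
total, keeping fused systems flat while leaving the integrator fewer coupled
constraints than a fully bonded ring.  The traversal starts at the lowest
bead index with orientation normalized by bead id, so the network is
invariant under rigid motion of the input coordinates.  Constraint lengths
and dihedral angles are measured on conformer-averaged coordinates.

## Membrane--water partitioning

The analysis module ingests free-energy (or probability) profiles
$G(z_i)$ on layers $z_0$ (membrane centre) to $z_n$ (bulk water; 100 layers
by default).  Probabilities follow by Boltzmann inversion normalized to the
bulk layer.  The membrane/water boundary is adaptive: scanning $j$ from $n$
inwards, the RMSD of $G$ over layers $j..n$ relative to $G(z_n)$ is
computed, and the cutoff $R$ is the first layer where it exceeds the
threshold (0.1 by default, in kJ/mol — the threshold is applied to the
free-energy profile, so it carries the profile's units).  Then

$$K_{MW} = \frac{\sum_{i=0}^{R} P(z_i)\,/\,M}{P(z_n)\,/\,V(z_n)}$$

in dm$^3$ kg$^{-1}$, with $M$ the leaflet mass and $V(z_n)$ the outermost
layer volume.  $G_{\text{bulk}}$ is the outermost layer's value, not an
outer-region mean, because the water reference in the partition sum is that
same layer.  A profile that never deviates from bulk returns $K_{MW} = 0$
with a `no_association` flag rather than an error, which is the useful
behaviour in screening pipelines.  `kmw_convergence()` reports
$\log K_{MW}$ across a threshold grid so users can audit sensitivity: deep
membrane wells are insensitive over thresholds 0.05--0.5 (spreads far below
1%), while for near-surface solutes with only a shallow interfacial minimum
the division is genuinely ambiguous and the spread is large — in that regime
$\log K_{MW}$ is small and its precise value matters least.

The synthetic-profile generator emulates the shapes such analyses meet in
practice: a flat bulk plateau, an optional attractive interfacial dip, a
smooth core well (tanh shoulder of 0.25 nm width), and seeded Gaussian
noise, with metadata for a 128-lipid POPC patch (6.5 nm lateral box;
leaflet mass $64 \times 760\,\mathrm{g\,mol^{-1}}/N_A \approx 8.1\times
10^{-23}$ kg; 100 layers over 5 nm at 303 K).  It does **not** emulate the
correlated noise of umbrella-sampling estimators, force-field error, or
membrane perturbation by the solute, so passing tests demonstrate the
correctness of the estimator, not the accuracy of any simulation.

## Problem sizes used in the test suite

The suite exercises mapping on a 36-molecule fixture panel, the
virtual-site solver on 1000 seeded quadrilaterals/triangles against a
numerical oracle, frameworks for 3--8 real sites, conformer ensembles of
5--30 (200 for the alkane scaling check up to C$_{50}$), and 100-layer
profiles.  These sizes keep the full suite under a minute while every
property asserted is size-independent.

## Known limitations

* Ring-system mapping is designed for fused five/six-membered rings;
  macrocycles and bridged or spiro systems are best-effort with a warning.
* Only planar ring systems gain virtual sites and hinge frameworks;
  non-planar rigid cages are out of scope.
* Bead typing assumes fragment additivity; context-dependent typing (the
  ester-linkage fragment whose capped form is formic acid is the classic
  case) is not attempted — models are starting points for refinement.
* The conformer model has no energetic weighting of rotamers beyond the
  anti/gauche prior, and no minimization.
* Martini 3, polarizable water, and charged types beyond Q0/Qa/Qd/Qda are
  not supported.
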