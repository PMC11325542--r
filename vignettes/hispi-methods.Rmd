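---
title: "hispi: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hispi: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hispi)
```

This vignette is the package's own account of its science: the geometric
model, the tunable parameters and why their defaults are what they are, the
formalization of the protonation-inference procedure, what the synthetic
generator does and does not emulate, and the numerical conventions that make
results reproducible to the digit.

## The geometric model

An aromatic ring is summarized by its centroid (arithmetic mean of the ring
atoms) and its plane normal, fitted by least squares (the singular direction
of smallest variance of the centered ring coordinates). Ring membership: His
imidazole (CG, ND1, CE1, NE2, CD2); Phe/Tyr benzene; Trp the full 9-atom
indole by default, switchable to the 6-membered sub-ring
(`ring_spec(trp_ring = "six")`) — the indole centroid is the convention we
adopt because CH–π and stacking contacts engage the fused system as a whole.
Rings with out-of-plane RMSD above `planarity_tol` (default 0.1 Å, roughly
three times a typical crystallographic deviation) are treated as distorted
and skipped with a warning rather than silently contributing bad normals.

Ring–ring pairs are described by the centroid distance $D$, the folded
inter-normal angle $P = \min(\alpha, 180^\circ - \alpha) \in [0^\circ,
90^\circ]$, and two unsigned elevation angles
$T\theta_i = \arcsin(|\hat d \cdot \hat n_i|)$. Normals have no physical
sign, so every reported angle is folded; elevations are unsigned (above vs
below a ring plane is not distinguishable without a reference frame), which
matches the $[0^\circ, 90^\circ]$ ranges the descriptors are plotted over.
Arcsine arguments are clamped to $[-1, 1]$ before evaluation.

Cation–π pairs use the distance $D$ from the cation's heavy charge center
to the ring centroid and the off-axis angle $\theta_1$ between ring normal
and the centroid→cation vector. Charge centers: Lys NZ; Arg CZ (the
guanidinium carbon — the paper-level description shows the plane but names
no atom, and CZ is the center of the delocalized charge); for a doubly
protonated His acting as cation, whichever ring nitrogen is closer to the
partner centroid, ties to NE2, recorded in `chosen_nitrogen`. Planar cations
(Arg guanidinium over NE/CZ/NH1/NH2; His⁺ over its ring) additionally get
$\theta_2$, the folded angle between the cation-plane normal and the $D$
vector; Lys has no plane and reports `NA`.

## Mining and exclusions

Aromatic pairs are found by the minimum ring-carbon-to-ring-carbon distance,
inclusive at the cutoff. The default `cc_cutoff = 5.0` Å: the upstream
Phe–Phe criterion this generalizes is cited but its numeric value is not
reprinted in the source, so 5.0 Å — the conventional aromatic-contact
cutoff — is an explicit, configurable decision that the CLI writes into its
output header. Only ring carbons participate (the criterion is stated for
the aromatic rings, not CB). `cation_centroid_cutoff = 7.0` Å is chosen to
cover the populated $D \le 6$ Å region of cation–π density maps with
margin. Inter-chain pairs are included; intra-residue pairs never.

Runs of ≥ 5 consecutive same-chain His are excluded as engineered His-tags;
an intervening residue number or a chain break interrupts the run. A His
with *any* atom within 5 Å of a configured metal (default list ZN, CA, MG,
MN, FE, CO, NI, CU, NA, K — a superset of the biologically named cations,
configurable) is excluded from mining; using any atom rather than only the
ring nitrogens is deliberately conservative.

`mine()` returns one row per unordered residue pair with a `families`
annotation, because a close His–aromatic contact qualifies simultaneously
as a ring–ring candidate and as a potential cation–π candidate; the
per-family finders (`find_aromatic_pairs()`, `find_cation_pi_pairs()`)
retain one row per family and role assignment, including both role
assignments of a His–His pair.

## Interaction classification

Labels form a *set*, not a partition — slipped stacks legitimately satisfy
both the stacked and the CH–π criteria. Defaults
(`geometry_thresholds()`), all configurable and recorded in outputs:

| class | rule | default |
|---|---|---|
| π-stacked | $D \le$ `stack_max_D`, $P \le$ `stack_max_P` | 5.5 Å, 30° |
| cation–π | $D \le$ `catpi_max_D`, $\theta_1 \le$ `catpi_max_theta1` | 6.0 Å, 60° |
| CH–π | donor C–centroid ≤ 4.5 Å, in-plane H-projection offset ≤ 1.8 Å, C–H⋯centroid angle ≥ 120° | |
| H-bond | donor–acceptor ≤ 3.5 Å, D–H–A ≥ 120°, and ≤ 45° elevation of the bond vector above the His ring plane when a ring N participates | |

These are the standard literature criteria for each class. The His-plane
elevation constraint encodes that the imidazole lone pair and N–H both lie
in the ring plane, so a candidate H-bond arriving steeply out of plane is
geometrically implausible and rejected. The exact numeric cutoffs of the
source study live in supplementary material that is not reprinted; the
defaults here are the literature-standard values and an optional
`stack_min_T_theta2` knob (off by default) exists because it is unstated
whether the stacked definition also bounds the elevation.

One documented divergence: the source applied these rules to QM-optimized
pair geometries. This package applies the same rules to crystal and
synthetic geometries (and to energy-annotated inputs when a table is
supplied). Binding energies are opaque inputs: `filter_by_energy()` keeps
pairs strictly below −1 kcal/mol, and `summarize_energies()` reports
mean ± sample SD per (family, label, phase), with single-member cells
reported as SD 0 and `n = 1`.

When a residue lacks explicit hydrogens, CH–π and H-bond classification run
only after `add_ideal_hydrogens()` under an explicit scenario (His: HID /
HIE / HIP), and the scenario used is recorded. Ideal geometry: aromatic C–H
(1.08 Å) and ring N–H (1.01 Å) in-plane along the external bisector; Lys NZ
three tetrahedral H staggered against CE–CD; Arg guanidinium H in-plane;
Tyr O–H in-plane at 109.5°.

## Protonation inference

Deuterium route (neutron structures): a D atom within 1.3 Å of a ring
nitrogen marks that site protonated (the distance stands in for bonds since
neutron files may lack CONECT records); D on NE2 only ⇒ ε-tautomer, ND1
only ⇒ δ-tautomer, both ⇒ imidazolium, neither ⇒ not determinable. The
δ-tautomer is supported throughout even though the source adopts ε for its
comparisons.

H-bond route (X-ray structures): ideal hydrogens are placed under each of
the three scenarios (ND1-H, NE2-H, both), and hydrogen bonds between the
ring nitrogens and all neighbor atoms within a 4.0 Å heavy-atom prefilter
(side chains, backbone, waters; the search radius is a stated decision, the
source does not define one) are censused. The qualitative rule — "an
accepting N is deprotonated; two donating N mean the cation" — is
operationalized as constraint intersection: each observed bond constrains
one nitrogen (accepting ⇒ deprotonated, donating ⇒ protonated), each
scenario's evidence admits a set of compatible states among {ε⁰, δ⁰,
His⁺}, scenarios without evidence are vacuous, and a call is made only when
the intersection across scenarios is a single state *and* some scenario has
at least two supporting bonds. Anything else — empty intersection,
ambiguity, sparse evidence — is `undetermined`.

One subtlety forced this formalization: a neighbor hydroxyl pointing its
hydrogen at ND1 is evidence that ND1 *accepts*; under the ND1-protonated
scenarios the hypothetical ND1–H would point straight back at that hydroxyl
and pass the distance/angle tests as a *donor* bond, poisoning the
intersection. A steric veto resolves this: a scenario hydrogen that would
come within 1.2 Å of an explicit hydrogen of the would-be acceptor moiety
invalidates that candidate bond. Waters participate as donors and
acceptors; H-less waters are acceptor-capable and donor-eligible with an
orientation-free distance-only test, which is lower-confidence evidence by
construction.

Metal-coordinated His (a ring N within 3.0 Å of a configured metal — the
typical coordination distance, deliberately distinct from the 5 Å mining
exclusion radius) are called `neutral_metal` up front: a coordinating
nitrogen must be deprotonated, and H-bond inference is skipped.

pKa values are consumed, never computed: low < 5.3, 5.3 ≤ medium ≤ 7.3
(boundaries inside the medium group), high > 7.3.
`pka_group_fractions()` normalizes interaction counts within each
(family, label) cell so the per-category fractions sum to one.

## Clustering and density maps

Geometry vectors (aromatic: $D, P, T\theta_1, T\theta_2$; cation–π:
$D, \theta_1[, \theta_2]$) are clustered with a full-covariance Gaussian
mixture — full covariance because the populated regions of descriptor space
are elongated and correlated, not spherical. EM starts from a seeded
k-means partition, covariances carry a $10^{-6}$ diagonal regularizer, and
$k$ is chosen by minimum BIC over 2–12 per family when `k = "auto"` (the
source states neither its $k$, scaling, nor covariance type; its 72
representatives arose from its data, not from a stated $k$). Angles enter
in degrees unscaled; a z-score flag exists but is off by default, because
the descriptor units are already commensurate within a family and scaling
would silently reweight distance against angle. Each component's
representative is the *member* nearest the component mean by Mahalanobis
distance under that component's covariance, so exported representatives are
always real observed pairs. Identical seed ⇒ identical assignments and
representatives.

Density maps use fixed half-open bins $[a, b)$, defaults 5° for angles and
0.25 Å for distances. For homotypic families (His–His) the reference/partner
assignment is arbitrary, so symmetrization adds each pair's
$T\theta_1 \leftrightarrow T\theta_2$ swapped observation, exactly doubling
homotypic totals — the count-conservation property the tests assert.

## The synthetic generator: what a green test establishes

`make_residue_template()` builds idealized planar side chains (His ring
edge 1.37 Å, benzene 1.39 Å, Trp as a fused regular hexagon + pentagon);
`place_aromatic_pair()` and `place_cation_pair()` produce two-residue
structures whose recomputed descriptors hit the targets to 10⁻³, with every
unconstrained rotation fixed by a zero-twist convention so identical
targets give identical coordinates. Feasibility of a constrained aromatic
triple is approximately $|T\theta_1 - T\theta_2| \le P$ and is verified
numerically; $P = 0$ forces the elevations equal. `make_fixture_structure()`
assembles designed units — pairs at exact geometries, His-tag runs, metal
sites, deuterated His with designed tautomers, H-bond micro-environments,
waters — on an adaptive grid keeping units ≥ 15 Å apart so designed pairs
are the only minable ones.

The generator emulates *geometry*, not crystallography: no backbone beyond
what fragments need, no thermal motion, no altloc disorder (altloc handling
is tested on hand-built tables), no solvent shells, no density maps, no
sequence context. A green test therefore establishes that the pipeline's
measurements, filters, classifications and inferences are algorithmically
correct against ground truth — not that any biological distribution is
recovered. The headline counts of the source study (tautomer censuses over
the PDB, protonation-call totals, binding-energy tables) require the full
corpus and external QM engines and are out of reach by design; the
acceptance suite is property-based for exactly this reason.

## Numerical conventions and tie-breaks

* Altlocs resolve to highest occupancy, ties to the lexicographically first
  altloc id; the operation is idempotent.
* Missing resolution/R-factor metadata fails its filter check unless that
  check is disabled — conservative, matching a curated-input workflow.
* Only the first model of multi-model files is used.
* Author residue numbering is kept exactly as read; no renumbering.
* His⁺ cation nitrogen ties (exactly equidistant) go to NE2.
* Fragment model compounds follow the "functional group + one methyl
  carbon" rule: 4-methylimidazole/-ium, toluene, 4-methylphenol,
  3-methylindole, and — by extension of the same rule, since the source
  names only the His and Phe compounds — methylammonium for Lys and
  methylguanidinium for Arg. Retained heavy atoms keep source coordinates
  to 10⁻⁹ Å; caps are ideal (C–H 1.09 Å).
* Deuterium is written as element D with D-prefixed hydrogen names
  (DD1/DE2).

## Known limitations

* The PDB/mmCIF readers are minimal by design (ATOM/HETATM, altlocs,
  headers needed by the filters); exotic dialect features (multiline mmCIF
  values, CONECT-dependent chemistry) are out of scope.
* H-bond candidate enumeration considers N/O donors and O / H-free ring-N
  acceptors; sulfur and weak C–H donors are not censused.
* Backbone N–H donors into His π faces are counted only through the
  generic donor rules; there is no dedicated N–H⋯π class.
* Binding energies are opaque table inputs; nothing energetic is predicted.
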