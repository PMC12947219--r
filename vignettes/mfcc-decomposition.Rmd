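---
title: "Per-residue interaction energies by molecular fractionation with conjugate caps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-residue interaction energies by molecular fractionation with conjugate caps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfccr)
```

## The method

Receptor–ligand binding is dominated by a modest number of pocket residues,
but a single total binding energy hides which ones.  The molecular
fractionation with conjugate caps (MFCC) scheme decomposes the total into
per-residue contributions by a divide-and-conquer construction.  The
receptor is cut at its peptide bonds; for residue $R_i$ the flanking
residues act as *conjugate caps* $C_{i-1}$ and $C_{i+1}$ that preserve the
local bonding environment, and every dangling valence created by a cut is
saturated with a *link hydrogen*.  The interaction energy between the
ligand $L$ and residue $R_i$ is then the four-term difference

$$
E(L\!-\!R_i) \;=\; E(L\,C_{i-1}R_iC_{i+1}) \;-\; E(L\,C_{i-1}C_{i+1})
\;-\; E(C_{i-1}R_iC_{i+1}) \;+\; E(C_{i-1}C_{i+1}),
$$

in which the internal energies of the ligand, of the caps and of the capped
residue cancel, leaving the ligand–residue interaction.  Summing
$E(L\!-\!R_i)$ over all residues whose nearest atom lies within a pocket
radius $r$, and sweeping $r$ in 0.5 Å steps ($r = R/2$, $R = 1, 2, 3,
\dots$) up to 10 Å, gives the cumulative total binding energy as a function
of pocket size.  The sweep is declared converged at the smallest radius
from which the change between consecutive radii stays below 10% of the
current total through the end of the schedule — a transient dip below 10%
that breaks again later does not count.  Residues are ranked by energy
(strongest attraction first, repulsive contributions last, ties broken by
residue number), and each residue is attributed to the chemical region of
the ligand atom it approaches most closely, so that region-wise sums
attribute the binding energy to ligand moieties.

The energy functional applied to the four fragments is pluggable.  The
reference protocol in this field is a dispersion-corrected DFT single point
(B97D/6-311+G(d,p)) in a conductor-like continuum (CPCM) at relative
permittivity $\varepsilon$ of 10 and 40; the package writes those input
decks and parses the resulting SCF energies, but never executes an engine.
For everything that must run at desk scale it provides a classical backend:

$$
E \;=\; \sum_{i<j}\; \frac{332.0637\, q_i q_j}{\varepsilon\, r_{ij}}
\;+\; \epsilon_{ij}\!\left[\left(\frac{r^{min}_{ij}}{r_{ij}}\right)^{12}
 - 2\left(\frac{r^{min}_{ij}}{r_{ij}}\right)^{6}\right],
$$

with geometric-mean well depths, summed half-$r^{min}$, and 1-2/1-3 bonded
pairs excluded.  The uniform $\varepsilon$ screening is a stand-in for the
continuum solvent, not an approximation claim about it.  Because this
backend is *strictly pairwise additive*, the MFCC combination has an exact
algebraic value — the ligand–residue cross energy plus the ligand
interaction with the link hydrogens of the capped-residue system minus that
with the link hydrogens of the caps-only system — which the package
recomputes independently by brute-force pair enumeration
(`brute_force_reference()`).  This oracle identity is the central
correctness test: the four-term combination and the direct enumeration must
agree to 1 nano-kcal/mol on every synthetic complex.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cap_extent` | `whole_adjacent_residue` | each cap is the full neighbouring residue, cut at its distal peptide bond; `backbone_only` is a cheaper variant |
| `nh/ch/sh_bond_length` | 1.01 / 1.09 / 1.34 Å | link-hydrogen bond length by kept-atom element (N, C, S) |
| `cut_disulfides` | `TRUE` | S–S bridges are cut and SG capped, so CYS residues remain independent fragments |
| `link_charge` | 0.09 e | partial charge of link hydrogens in classical mode (the table's generic aliphatic-H charge) |
| `epsilon` | 40 | relative permittivity of the uniform screening (10 and 40 are the conventional choices) |
| `r_max`, `step` | 10 Å, 0.5 Å | radius schedule of the pocket sweep |
| convergence `threshold` | 0.10 | fractional change between consecutive radii |

Cap extent and link-hydrogen geometry are genuinely open choices: the
method's definition says only "conjugate caps" and "hydrogens added to
preserve the valence".  Whole-residue caps are the conservative reading and
the default; backbone-only caps are offered where fragment size matters.
The link-hydrogen partial charge deserves a note: in the exact pairwise
algebra the caps' own terms cancel, but the ligand still sees the link
hydrogens that differ between the capped-residue and caps-only systems, so
the classical MFCC value depends (weakly) on `link_charge`.  It is therefore
explicit, documented and configurable rather than hidden.  One consequence
worth knowing: a fragment plus its link hydrogens carries a small net
charge (±0.18 e for an interior neutral residue), so the screened Coulomb
tail of a +1 ligand against a fragment decays only as $1/r$ — at 500 Å
separation the residual is still of order $10^{-3}$ kcal/mol, and the
separation-limit tests use a far larger displacement where the limit holds
to $10^{-6}$.

Pocket inclusion uses the *minimum atom–atom distance* between residue and
ligand, hydrogens included, rather than a centroid distance: small radii
are meant to select residues in direct contact, which nearest-approach
captures and centroids do not.  Whether hydrogens should count is not
settled; it is the default here and configurable in the sense that the
distance operation is exposed directly.  Region assignment is
single-valued: the residue inherits the region of its closest ligand heavy
atom (a closest hydrogen delegates to the heavy atom it is bonded to);
multi-region contacts are not split energetically.

## Parameterisation

The classical backend needs partial charges and Lennard-Jones parameters
per atom.  These arrive as a CSV table keyed by (residue, atom); a built-in
table ships with the package covering the eight residue types the synthetic
generator emits plus the synthetic ligand.  Its charges are CHARMM-style
group charges that sum *exactly* to each residue's formal charge (ASP −1,
LYS +1, ligand +1, others 0) — self-consistency, not fidelity to any
particular published set, is what the correctness guarantees rest on.
Parameters for real ligands are user-supplied through the same format.
Assignment is strict: any atom without a table entry is an error naming the
atom, and per-residue charge sums are checked against the template formal
charge to $10^{-6}$ e.

## The synthetic generator

`generate_toy_complex()` builds the test universe: a peptide of 3–30
standard residues (GLY, ALA, SER, VAL, CYS, PHE and the charged ASP/LYS in
a configurable fraction) wrapped around a small polar ligand bearing a
protonated amine (+1), the charge pattern that dominates recognition in
aminergic binding pockets.  The chain is a self-avoiding random walk of
rigid idealized residue templates: peptide C–N bonds are exactly 1.33 Å,
intra-residue bond lengths are standard, and every residue's nearest
approach to the ligand is constrained to the requested window (2–10 Å by
default, matching the contact-distance range over which pocket residues
act).  Placement uses depth-first backtracking with bounded retries;
infeasible specifications fail loudly rather than silently degrade.  The
generator also returns a ground truth — each residue's direct ligand–residue
cross energy and minimum contact distance computed by plain double-loop
enumeration, independent of all pipeline code — and emits the complex as
PDB + parameter CSV + regions JSON so the same readers used for real
structures are exercised.

What the generator does *not* emulate: relaxed physical geometry (no
minimisation — backbone junction angles are wrong even though bond lengths
are right), real rotamers, secondary structure, waters, and above all DFT
energetics.  Passing tests therefore demonstrate that the fragmentation,
bookkeeping, accumulation and aggregation machinery is exact under a
pairwise-additive energy model — they do not validate the quantum-chemical
energies themselves, which enter only through the deck/parse interface.

## Numerical choices

* Constants are centralised: Coulomb 332.0637 kcal Å mol⁻¹ e⁻²,
  hartree → kcal/mol 627.5095.
* Interatomic distances below 0.1 Å are a hard error (near-singular
  geometry), not a warning.
* The four-term combination subtracts totals of order $10^2$–$10^5$
  kcal/mol, so its accuracy is limited by the ulp of the largest fragment
  total.  The generator therefore enforces ordinary non-bonded clearance
  (≥ 1.5 Å between non-adjacent residues; ≥ 1.25 Å between adjacent
  residues for everything except the five 1-2/1-3 pairs across the peptide
  junction).  Under these constraints the observed agreement between the
  four-term value and the brute-force oracle is at the $10^{-11}$ kcal/mol
  level, comfortably inside the 1 nano-kcal/mol assertion.
* Minimum-distance ties are broken deterministically towards the lowest
  atom ids.
* A sweep step with zero cumulative total is treated as non-convergent
  unless its difference is also zero (0/0 counts as stable).
* Machine-readable CSVs print doubles with 17 significant digits so
  re-reading reproduces the in-memory values bit-exactly; only the
  human-readable table rounds to two decimals.
* Terminal residues have one cap; a residue with no neighbours yields
  empty caps and a warning rather than an error.
* Regional group sums and the cumulative sweep totals are floating-point
  sums in fixed deterministic order; "exact" partition identities hold to
  addition-reordering round-off ($\lesssim 10^{-12}$ relative), which is
  the tolerance the tests assert.

## Problem sizes

The validation suite runs entirely at desk scale by design: oracle
equivalence is asserted over 20 seeded complexes of 8–30 residues
(~350 fragment quadruples), the sweep/conservation and dielectric-scaling
properties on 6–12-residue complexes, and the regional-aggregation worked
examples on the published rankings of the three α1A-adrenoceptor complexes
(11, 15 and 18 residues).  A full receptor at DFT level is an external
campaign: the package writes its decks and merges its energies via the CSV
cache, but running it is explicitly out of scope.

## Known limitations

* The classical backend has no polarisation, no charge transfer, no
  dispersion beyond LJ, and uniform rather than boundary-element
  screening; its role is to make the *bookkeeping* exactly testable, and
  as a rough desk-scale screen.
* Protonation is taken as given.  `validate_protonation()` flags missing
  hydrogens against residue templates but never rebuilds them; histidine
  tautomers and pKa shifts are upstream problems.
* Fragmentation covers polypeptides (plus disulfide cutting); nucleic
  acids and branched polymers are out of scope.
* Published per-residue energies for the α1A-adrenoceptor complexes are
  shipped as a reference input table for the aggregation layer; the
  package cannot recompute them without the external DFT campaign, and the
  corresponding whole-receptor totals and convergence radii are likewise
  outside desk scale.
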