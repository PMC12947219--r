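# mfccr

Per-residue protein–ligand interaction energies by molecular fractionation
with conjugate caps (MFCC), in R.

## The problem

A receptor's binding pocket holds dozens of residues, but a single total
binding energy says nothing about which of them do the work.  Fragment-based
energy decomposition answers that: the receptor is cut at its peptide bonds,
each residue R\_i is kept chemically sensible by retaining its flanking
residues as *conjugate caps* C\_(i−1), C\_(i+1) (link hydrogens saturate
every cut bond), and the ligand–residue interaction energy is the four-term
difference

```
E(L−Ri) = E(L·C(i−1)RiC(i+1)) − E(L·C(i−1)C(i+1)) − E(C(i−1)RiC(i+1)) + E(C(i−1)C(i+1))
```

in which all fragment self-energies cancel.  Summing these contributions over
residues whose nearest atom lies within a growing pocket radius (0.5 Å steps
up to 10 Å) gives a convergence curve of total binding energy versus pocket
size; the analysis is converged from the radius where consecutive totals
change by less than 10% and stay that way.  Residues are ranked by their
contribution, and energies are aggregated by the chemical region of the
ligand each residue approaches most closely (e.g. catechol ring versus
protonated amine arm).  This is the workflow used to dissect ligand
recognition at aminergic GPCR pockets such as the α1A-adrenoceptor.

The package is aimed at structural/computational chemists who want this
decomposition pipeline as auditable, tested code: structure I/O (PDB/mmCIF
via bio3d), fragmentation with configurable capping, a classical
dielectric-screened Coulomb + Lennard-Jones backend for desk-scale work,
Gaussian-dialect input-deck writing and SCF-energy parsing for an external
DFT campaign (B97D/6-311+G(d,p)/CPCM; the package never runs the engine),
the radius sweep/convergence/ranking/region layer, and a deterministic
synthetic-complex generator with an independent brute-force oracle that
makes every stage testable without downloads.

## Worked example

Simulate a small pocket (12 residues, half charged, around a protonated
amine ligand), run the sweep at ε = 40, and look at the ranking:

```r
library(mfccr)

toy   <- generate_toy_complex(toy_complex_spec(seed = 1, n_residues = 12,
                                               charge_profile = 0.5))
sweep <- radius_sweep(toy$model, classical_backend(40),
                      region_map = toy$region_map)
sweep
#> radius_sweep: 20 radii up to 10 A; 12 residues
#>   total energy at r_max: -4.89 kcal/mol
#>   convergence radius: 6 A

head(format_residue_table(sweep$records), 5)
#>   rank label energy min_distance closest_ligand_atom region
#> 1    1  ASP4  -2.63         3.21                 H22     ii
#> 2    2  ASP5  -0.99         5.27                 HN1     ii
#> 3    3  ASP3  -0.98         5.43                 H22     ii
#> 4    4  ALA9  -0.47         3.84                 HN1     ii
#> 5    5  VAL6  -0.38         5.04                 HN1     ii
```

The three ASP residues attract the +1 ligand most strongly (negative
energies, kcal/mol), the cumulative total over all residues within 10 Å is
−4.89 kcal/mol, and the curve stabilises (<10% change, persistently) from a
6 Å pocket radius.  `region` attributes each residue to the ligand moiety it
touches: here everything contacts the amine arm (region ii).

The same aggregation applied to the published per-residue energies for the
noradrenaline/α1A-adrenoceptor complex reproduces the reported regional
sums — −8.68 kcal/mol for the catechol ring and −17.26 kcal/mol for the
β-hydroxyethylamine group:

```r
nora <- alpha1a_published_rankings("noradrenaline")
aggregate_regional_energies(nora)
#>   region n_residues energy
#> 1     ii          5 -17.26
#> 2      i          6  -8.68
```

The numbered scripts under `analysis/` run the whole workflow end to end
(simulate → fragment/evaluate → sweep → regional aggregation) and write
their tables under `results/`.

## Scope notes

The package's own energetics are classical and self-consistently
parameterised (an embedded CHARMM-style charge/LJ table for the residue
types its generator emits); DFT-level energies enter only through the
deck-writer/parser/cache interface.  Protonation is taken as given —
structures must arrive protonated, and `validate_protonation()` only flags
implausible hydrogen counts.  See the methods vignette
(`vignettes/mfcc-decomposition.Rmd`) for the model, the parameter choices
and the numerical design.
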