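# condensateph

Electrochemical profiling of biomolecular condensates and pH-dependent
phase behaviour.

Biomolecular condensates — dense phases formed by liquid–liquid phase
separation — can buffer their internal pH towards the conditions of
minimal electrostatic repulsion, i.e. towards the isoelectric point (pI)
of their components, without any active transport. This package is for
biophysicists and computational biologists who want to quantify that
behaviour: it computes sequence-based charge electrochemistry, analyses
microdroplet phase-diagram experiments, converts ratiometric dye images
to pH maps, and solves a minimal thermodynamic model that ties the
pieces together.

## What it computes

- **Biopolymer charge** — Henderson–Hasselbalch site models: net charge
  `Q(pH)`, charge density `q = Q/N` and the repulsion proxy `q²`, pI by
  bisection of the monotone charge curve, Kyte–Doolittle hydropathy;
  RNA charge from nucleobase protonation plus diprotic phosphates.
- **Mixtures** — weighted mixture charge profiles
  `C(pH) = Σ wᵢ Qᵢ(pH)`, the mixture pI (unique zero crossing),
  RNA-mass-fraction corrections, composition-resolved neutral-pH maps,
  and the charge slope `−(ΔC/ΔpH)` at the mixture pI.
- **Condensate proteomes** — pI distributions and near-neutral window
  fractions, membership filtering for organelle- and cluster-style
  annotation tables, abundance weighting, `q²` response ranges.
- **Random proteomes** — seeded generation at prescribed residue
  composition and length model, plus a window-based bimodality
  statistic.
- **Phase maps** — buffer-fraction→pH calibration, binned
  phase-separated fraction `F_PS` grids, marching-squares phase
  boundaries, dilute-phase contour slopes `K` (tie-line proton
  partitioning), and dominance `D = 1 − R` from the dilute-phase
  response gradient, with perturbation error estimates.
- **Ratiometric pH imaging** — SNARF-type two-point calibration,
  `pH = pKa + log₁₀[(R − R_acid)/(R_base − R)·F]`, and per-feature
  dense/dilute pH from two-channel images with label masks.
- **Thermodynamic model** — a three-charge-state polymer with attraction
  `χ_f` and electrostatic repulsion `λ(z φ_p)²`; spinodals located from
  the zero contour of the free-energy Hessian determinant, swept over
  pI, `χ_f` and `λ`.
- **Synthetic data** — seeded generators for droplet scans drawn from a
  ground-truth U-shaped boundary with tie-line tilts, two-channel dye
  scenes with exact masks, and composition-controlled proteomes; every
  generator emits a machine-readable truth record.

## Worked example

```r
library(condensateph)

seqs <- read_fasta_protein(system.file("extdata", "insulin.fasta",
                                       package = "condensateph"))
isoelectric_point(seqs$insulin)            # 5.39481
isoelectric_point(seqs$insulin_glargine)   # 6.876339

# where does a droplet scan place the phase boundary?
truth <- droplet_truth(seed = 1)           # ground truth: pI 6.8
droplets <- synth_droplets(truth, 20000)
grid <- bin_phase_fraction(droplets, seq(3.5, 9, by = 0.2), seq(0, 5, by = 0.2))
boundary <- extract_boundary(grid)         # F_PS = 0.5 contour
bottom <- boundary[boundary$conc <= min(boundary$conc) + 0.1, ]
mean(range(bottom$ph))                     # 6.8

# proton partitioning from dilute-phase contours
section_dilute_contour(droplets, 0.6, 1.2, "low_pH", ph_split = 6.8, seed = 1)
#> contour_slope (low_pH): K = 2.52 +/- 0.087 (n = 796, window 0.6-1.2)

# dominance in a pH slab
slab <- synth_dominance_slab(truth, 6.1, 300)
dominance(slab, 6.1, 0.25, seed = 1)
#> dominance_fit @ pH 6.10: R = 0.541, D = 0.459 +/- 0.001 (n = 300)
```

The two hormone variants differ by three residues yet their neutral
points sit ~1.5 pH units apart; the recovered phase boundary bottoms out
at the generator's pI (6.8); the positive low-pH contour slope reads out
proton exclusion from the dense phase; and the dominance value means the
peptide contributes roughly half the free-energy gain of phase
separation at pH 6.1.

The numbered drivers under `analysis/` run the full set of analyses
(sequence charge, random proteomes, phase maps, imaging, condensate
proteomes, spinodals) and write their tables under `results/`.

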