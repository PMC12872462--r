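---
title: "Electrochemical profiling of biomolecular condensates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrochemical profiling of biomolecular condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateph)
```

## The problem

Biomolecular condensates — protein-rich dense phases formed by
liquid-liquid phase separation — can hold their internal pH away from the
surrounding solution without any energy input. The organizing idea is
charge neutralization: condensation is most favourable where the
constituent biopolymers carry the least net charge, so the dense phase
buffers itself towards the isoelectric point (pI) of its components, where
the electrostatic repulsion proxy $q^2 = (Q/N)^2$ is minimal.

`condensateph` implements the computational machinery around that idea:
site-based charge models for proteins and RNA, electrochemical
reconstitution of mixtures and whole condensate proteomes, analysis of
combinatorial microdroplet phase-diagram datasets, ratiometric pH-imaging
readouts, a minimal thermodynamic model whose spinodal explains the
behaviour, and seeded synthetic-data generators that make every stage
testable without external downloads.

## Charge models

Every ionizable site is treated independently through the
Henderson–Hasselbalch equation. A basic group with dissociation constant
$pK_a$ carries $+1/(1 + 10^{\mathrm{pH} - pK_a})$, an acidic group
$-1/(1 + 10^{pK_a - \mathrm{pH}})$. A protein contributes one N-terminal
amine, one C-terminal carboxyl, and every K, R, H (basic) and D, E, C, Y
(acidic) side chain. The default $pK_a$ set is the Bjellqvist table
(N-terminus 7.5, K 10.0, R 12.0, H 5.98; C-terminus 3.55, D 4.05, E 4.45,
C 9.0, Y 10.0) because it is the default of the standard sequence-utility
packages this field uses for pI computation; EMBOSS and IPC presets ship
for sensitivity analysis and every value is overridable.

Since every site charge is strictly decreasing in pH, the net charge
$Q(\mathrm{pH})$ is strictly monotone, its root in $(0, 14)$ is unique,
and bisection (bracket $[0, 14]$, tolerance $10^{-4}$, at most 100
iterations) finds the pI robustly. Multi-chain molecules such as insulin
are concatenated into one chain with a single pair of termini — the
convention of sequence-record-based computation; this undercounts termini
by one pair per extra chain, a documented caveat that moves the pI of a
51-residue two-chain hormone by well under the 0.1 pH tolerance used in
the tests. Ambiguity codes (X, B, Z, U, O, J) carry zero charge but count
towards $N$, so they can never silently change the normalization of
$q = Q/N$.

RNA is modelled per nucleotide as a nucleobase plus a phosphate. Bases
protonate with approximate constants (A 3.5, C 4.2, G 2.4, U none); the
phosphate undergoes two sequential deprotonations
($pK_{a,1} = 1.0$, $pK_{a,2} = 6.5$) giving the speciation-weighted charge
$-(a_1 + 2a_1a_2)/(1 + a_1 + a_1a_2)$ with $a_i = 10^{\mathrm{pH} -
pK_{a,i}}$. These constants are stated assumptions, not fitted values, and
are configurable; at neutral pH the phosphates dominate and any RNA is
strongly negative.

## Mixtures and condensate proteomes

A multi-component system is reconstituted electrochemically as
$C(\mathrm{pH}) = \sum_i w_i Q_i(\mathrm{pH})$ with non-negative weights
(molar concentrations, copy numbers or abundances). Three normalizations
are provided: the per-sequence mean (used for condensate proteomes), the
raw weighted sum, and a "bounded" display rescaling to a reference
component's maximum charge, which multiplies the curve by a positive
constant and therefore provably never moves its zero crossing. The mixture
pI is located by linear interpolation between the bracketing grid points
of the single sign change on the default 0.01-pH grid — accurate to well
under 0.005 pH for these smooth profiles, which is why no re-bisection is
performed. Systems with no neutrality in $[0, 14]$ (e.g. pure RNA) return
a sentinel `NA` rather than an extrapolation.

Protein–RNA mass composition is converted to molar weights with mean
monomer masses of 110 Da per residue and 330 Da per nucleotide (both
configurable); an RNA mass fraction of 7.5% — the middle of published
nucleolar fractionation estimates — noticeably lowers the neutral point of
a basic proteome. The local steepness of the charge profile at the mixture
pI, reported as $-(\Delta C/\Delta \mathrm{pH})_{pI}$ from a central
difference with half-width 0.05 pH, distinguishes systems that hold their
charge state across pH fluctuations from switch-like ones; it scales with
the profile normalization and is only comparable within one normalization
convention.

Condensate proteomes come from two membership-table schemas: organism- and
annotation-count-filtered tables (the nine most-annotated organelles by
default, ties broken by name) and interaction-network cluster tables kept
when strictly more than 50% of members are scaffold-flagged. The
near-neutral fraction of a pI distribution uses the strict window
$7 < \mathrm{pI} < 8$.

## Microdroplet phase-map analysis

Each microdroplet is one point in (pH, total concentration) space with a
binary phase classification. The droplet pH comes from a monotone
piecewise-linear calibration of buffer mixing fraction against measured
pH. Droplets are binned half-open $[\mathrm{left}, \mathrm{right})$ (last
bin closed) so each is counted exactly once; bins with fewer than 3
droplets are masked; the per-bin mean classification is the local
phase-separated fraction $F_{PS}$, and the phase boundary is the
marching-squares contour at $F_{PS} = 0.5$ over unmasked bin centres.

Contours of constant dilute-phase concentration approximate tie-lines in
two-component systems. Sectioning phase-separated droplets with
$a < c_{dil} < b$ on one side of the boundary minimum and regressing
$c_{tot}$ on pH gives the contour slope $K$; its sign reads out proton
partitioning ($K > 0$ at the low-pH arm: protons excluded from the dense
phase; $K < 0$ at the high-pH arm: protons taken up). Ordinary least
squares uses $c_{tot}$ (for $K$) and $c_{dil}$ (for the response gradient
$R$) as the response because flow-programmed quantities carry little
error while measured concentrations carry the noise. Dominance is
$D = 1 - R$ with $R$ the slope of $c_{dil}$ on $c_{tot}$ in a pH slab
(default half-width 0.25 pH). All uncertainties are perturbation
estimates: 200 seeded refits after adding Gaussian noise at the residual
standard deviation to the response — the closest executable reading of
error estimation by "repeated perturbation" of fitting data. Units of $K$
are concentration per pH and depend on the experiment's concentration
convention.

## Ratiometric pH imaging

SNARF-type dyes are read out as the ratio $R$ of two emission channels
(Em1 ~580 nm, Em2 ~650 nm). The two-point calibration stores the endpoint
ratios $R_{acid}$, $R_{base}$, the Em2 brightness ratio $F$ between the
two forms and the dye $pK_a$ (default 6.4, the vendor value for SNARF-4F),
and inverts via
$\mathrm{pH} = pK_a + \log_{10}\!\big[(R - R_{acid})/(R_{base} - R)\cdot F\big]$.
Values outside the calibrated range $[3.5, 9]$ are clamped and flagged
rather than extrapolated, because the calibration is defined only between
its endpoints. Per-feature pH uses the ratio of per-feature channel means
(not the mean of per-pixel ratios), matching the averaging order of the
imaging readout; the dilute phase pools all background pixels. Features
below 5 pixels are skipped. No background subtraction is applied by
default. Segmentation is an input: masks are integer label images
produced upstream.

## The minimal thermodynamic model

A polymer of $N$ monomers in a buffered solvent can be positive, neutral
or negative; fast acid–base equilibrium at proton concentration $h$ gives
state weights $h/K_+ : 1 : K_-/h$, mean charge per monomer
$z = f_+ - f_-$, and $z = 0$ exactly at $\mathrm{pH} = pI =
(pK_+ + pK_-)/2$. The free energy per lattice site is

$$f = \frac{\phi_p}{N}\ln\phi_p + \phi_h\ln\phi_h + \phi_s\ln\phi_s
      + \tfrac12\chi_f\phi_p^2 + \lambda (z\,\phi_p)^2,$$

with $\phi_s = 1 - \phi_p - \phi_h$ and $c_h = 55.5\,\phi_h$ M. The sign
convention makes $\chi_f < 0$ attractive, so "decreasing $\chi_f$"
strengthens attraction. The spinodal is the zero set of
$\det \partial^2 f / \partial(\phi_p, \phi_h)^2$, computed from symbolic
(exact) derivatives and verified against finite differences.

One genuine design choice deserves emphasis. If the chain rule is carried
through $z(\phi_h)$, the charge-response terms scale as $1/\phi_h^2$
(free protons are ~$10^{-9}$ in volume fraction) and swamp the proton
sector of the Hessian: the determinant goes negative in a broad
low-polymer band and the spinodal minimum detaches from the pI. That
regime describes a system whose local protonation tracks local proton
density fluctuations — not a buffered experiment, where the reservoir
clamps the local pH. The default Hessian therefore holds $z$ at its
reservoir value while differentiating (`charge_response = "clamped"`);
the fully differentiated variant remains available
(`"fluctuating"`) and is the one exercised by the
analytic-vs-finite-difference tests, since it is the harder
differentiation. With clamping the model reproduces the full qualitative
phenomenology: the spinodal bottoms out at the pI and tracks it under pI
sweeps, $\lambda = 0$ gives a pH-independent boundary at the classical
Flory locus $1/(N\phi_p) + 1/\phi_s + \chi_f = 0$, stronger attraction
lowers the boundary and stronger repulsion narrows the unstable pH
window. Note the determinant itself is not symmetric in
$\mathrm{pH} - pI$ (the proton entropy $1/\phi_h$ is one-sided even
though $z^2$ is symmetric); the polymer-sector curvature and the contour
location are.

Default grids: $\phi_p$ log-spaced $10^{-6}$–$0.5$ (200 points), pH 3–11
(160 points, step ~0.05); defaults $N = 100$, $\chi_f = -2$,
$\lambda = 10$, $pK_\pm = pI \mp 1$. The $pK$ gap of 2 units makes $z$
rise to ~0.5 one pH unit from the pI, which keeps the unstable window
about one pH unit wide at the default repulsion — the regime where the
window-narrowing and boundary-lowering sweeps are all resolved on the
default grid. The polymer axis is reported as molarity
$c_p = 55.5\,\phi_p/N$.

## Synthetic data: what it emulates and what it does not

The droplet generator draws stock fractions over a flow-scan range, maps
buffer fraction to pH through a synthetic monotone calibration spanning
3.5–9, classifies droplets against a ground-truth boundary
$c_{sat}(\mathrm{pH}) = c_{min}e^{\alpha(\mathrm{pH} - pI)^2}$ (a minimal
two-parameter U-shape; other families can be plugged in), and emits
dilute-phase concentrations with a tie-line tilt: the effective boundary
pH is offset in proportion to the dense-phase excess, with the per-arm
coefficient obtained by inverting the contour-slope relation
$s = 1/(c_{sat}' - k)$ at a representative arm pH so that the prescribed
slopes $k_{low} > 0$, $k_{high} < 0$ are what the analysis should
recover. Defaults ($pI = 6.8$, $c_{min} = 0.5$, $\alpha = 0.8$,
$k = \pm 2$, response gradient 0.54, noise s.d. 0.02, stock 10
concentration units) emulate the glargine-like study conditions: a
U-shaped boundary with its minimum at pH 6.8 and a dominance near 0.46 at
pH 6.1. Dominance slabs are generated as
$c_{dil} = R\,c_{tot} + (1 - R)c_{sat} + \varepsilon$, continuous with
the boundary.

The image generator renders disk-shaped dense features at prescribed
internal pH through the inverse two-state dye model (the Em2 channel
interpolates between base- and acid-form brightness with the acid
fraction, so endpoint references, forward ratio and inversion are
mutually exact), plus Gaussian channel noise and exact label masks.

What the generators do **not** emulate: illumination profiles, channel
crosstalk, droplet optics, segmentation errors, buffer-capacity
depletion, ion screening, or real classifier noise structure (flips are
independent Bernoulli events). Passing recovery tests therefore
demonstrates the correctness of the estimators under the stated
generative assumptions — not robustness to every artefact of real
microscopy data.

The randomized-proteome generator concatenates residues independently at
specified frequencies (R's Mersenne-Twister stream, seeded and restored on
exit). The "fully randomized" preset is uniform composition at fixed
length 560, the mean human protein length. One empirical note: that
preset's pI histogram is clearly bimodal (modes near 6.3 and 8.3), but
the fixed-window bimodality criterion used here — valley $(7, 8)$ against
shoulders $(4.5, 6.5)$ and $(8.5, 10.5)$, windows chosen for the mode
locations of natural proteomes — returns *false* for it, because the
uniform-composition basic mode sits at 8–8.5, inside neither window. The
human-like composition preset is window-bimodal. The criterion is kept
exactly as defined (it is descriptive and exactly assertable); the window
placement, not the charge model, is what the uniform preset fails.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale: 5,000 sequences of
length 560 for proteome sampling (the generator streams 500,000 just as
well), 100-sequence oracle comparisons at $10^{-4}$-pH grid resolution,
20,000-droplet scans binned at 0.2 pH × 0.2 concentration units, 50
seeded datasets per tie-line side, and 160 × 200 thermodynamic grids.
Degenerate inputs error early: empty sequences, non-ascending grids,
mixed-sign normalization weights, compositions off the simplex,
single-signed determinant fields and contour levels outside $(0, 1)$ all
raise informative errors rather than propagating.

## Known limitations

- Sequence-based charges only: no structure-corrected $pK_a$ shifts, no
  charge regulation or Coulomb coupling between sites, no counter-ion
  screening (salt effects are discussed qualitatively in the source
  experiments but not modelled).
- Tie-line contour slopes are a lower bound on the component ratio of
  true tie-lines; units are convention-dependent.
- The thermodynamic model draws spinodals only; binodals and tie-lines by
  common-tangent construction are out of scope.
- Phase classification and image segmentation are inputs; the package
  starts from droplet tables and label masks.
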