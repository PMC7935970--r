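---
title: "Models and methods behind ccswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccswitch)
```

# The system

`ccswitch` models a minimal protein-interaction switch built from a de novo
parallel coiled-coil (CC) heterodimer: an acidic peptide (A) and a basic
peptide (B) that are unfolded alone and fold cooperatively into a dimer when
mixed. A kinase recognition motif (RRxS) written into B places a
phospho-acceptor serine in the hydrophobic a/d interface, so phosphorylation
blocks dimerization and a phosphatase restores it. Coupling this switch to
membrane modules gives two reversible membrane-targeting devices:

* **tether mode** — a permanently membrane-anchored A fusion captures a
  soluble B "cargo"; phosphorylation releases the cargo into solution;
* **avidity mode** — both partners carry one weak amphipathic
  membrane-targeting sequence (MTS); only the dimer, holding two MTSs, is
  retained at the membrane, mimicking MinD-type avidity switching.

The package implements the sequence bookkeeping used to design such
peptides, the thermodynamic and kinetic forward models, the estimation
procedures applied to the resulting data, the confocal z-stack quantitation
used for membrane binding, and synthetic-data generators that stand in for
the instruments.

# Sequence model

Heptad registers are assigned by the pure rule
`position(i) = (offset + i - 1) mod 7` over the alphabet `a..g`, with
`offset = 0` placing residue 1 at `a`. Heptads are counted from their `a`
position; residues preceding the first `a` carry heptad index 0. Non-heptad
flanks (Gly caps, the C-terminal Trp used for concentration determination,
fusion linkers) are marked `-` and excluded from wheel and pairing logic.
These conventions are package choices; any consistent indexing would do,
but they make the motif-placement contract exact: writing `RRxS` with the
acceptor at `a` of heptad *k* puts the two arginines at `e` and `f` of
heptad *k − 1*, the positions furthest from the interface, and `x` always
keeps the parent residue.

The bundled `cc_switch_peptides()` are *reconstructions* of the
acidic/basic four-heptad family from its published design rules
(`EIAALEQ`/`KIAALKQ` repeats in `gabcdef` register, an Asn–Asn pair at `a`
of heptad 3 for register specificity, acetyl/amide termini). They are not
transcriptions of laboratory sequences; similarly `synthetic_mts()` and the
fusion constructs in `inst/extdata/synthetic_fusions.fasta` are labelled
synthetic stand-ins with the right architecture (amphipathic Trp-containing
13-mer; MTS/fluorescent-protein-sized-domain/His-tag/CC fusions). Mass or
identity comparisons against published constructs should therefore be read
as pipeline demonstrations, not as reproductions.

The helical wheel uses 3.5 residues per turn (102.857°/residue) rather than
the 100° α-helical value so that the seven register positions occupy seven
fixed angles and residues seven apart superimpose — the standard
coiled-coil depiction. The hydrophobic moment uses the same angular step
(Eisenberg consensus scale by default), making it exactly invariant under
rotation by full turns.

Masses default to **average** isotopic masses (IUPAC element weights);
monoisotopic is available. Modification deltas: acetyl +42.0367, C-terminal
amide −0.9847, phospho +79.9799 Da. Because expressed proteins may lose the
initiator methionine, `fusion_masses()` always reports Met-retained and
Met-cleaved values and takes no position on which applies.

# Pairing energies

The a–a′ table shipped in `inst/extdata/pairing_table.csv` carries
*order-calibrated placeholders*: only the ordinal structure is contractual
(Ile–Ile the most stabilizing pair; Ser–Ile the least destabilizing Ser
pairing; Ser–Ser preferred among Ser–polar pairings; Asn–Asn favourable
among polar homotypic pairs). Absolute values are not measurements and the
table is user-replaceable; `pairing_table()` validates symmetry and the
Ile–Ile minimum on load.

# Two-state bimolecular melting

For two peptides each at total concentration C, with m the free monomer and
d the dimer concentration, the model is

$$K_d(T) = \frac{m^2}{d}, \qquad m + d = C,$$

with van 't Hoff temperature dependence
$K_d(T) = K_d(T_m)\,e^{(\Delta H/R)(1/T_m - 1/T)}$ and $\Delta H > 0$ the
unfolding enthalpy. **Tm is defined as the temperature where the folded
fraction d/C equals 1/2 at the stated concentration**, which fixes
$K_d(T_m) = C/2$. The observable is
$\mathrm{MRE}_{222}(T) = b_f(T) + (b_u(T) - b_f(T))(1 - f(T))$ with linear
(default flat) baselines, −33,000 and −3,000 deg cm² dmol⁻¹ by default.

**Midpoint extraction.** `tm_second_derivative()` smooths the curve
(Savitzky–Golay, order 3, window auto-scaled to ~5 °C, 5–11 points),
locates the transition from the extrema of the second derivative, and
interpolates its zero crossing. For a *bimolecular* melt this inflection
lies systematically 1.5–2.5 °C above the half-folded temperature (the curve
is asymmetric), so when the curve carries its total concentration (as
curves from `melt_curve()`/`gen_cd_melt()` do) the estimate is refined by
fitting the two-state model above and the fitted half-folded temperature is
returned. Bare curves get the plain inflection, which is exact for
symmetric transitions. A curve whose smoothed amplitude is below ten times
the residual noise yields an explicit no-call (`NA`).

A practical identifiability note: on the default 5–90 °C grid a transition
near 81 °C is truncated (roughly a fifth of the material is still folded at
90 °C), the unfolded baseline is weakly determined, and single-curve Tm
estimates at 2% noise have a standard deviation near 1 °C. Averaging
triplicate melts — the replication structure such experiments use anyway —
brings recovery comfortably inside ±1 °C; the acceptance script does this.

# Dissociation-gated phosphorylation kinetics

The central model is the scheme

$$\mathrm{AB} \; \underset{k_\mathrm{on}}{\overset{k_\mathrm{off}}{\rightleftharpoons}} \; \mathrm{A} + \mathrm{B} \; \xrightarrow{\;k_p\;} \; \mathrm{A} + \mathrm{B}'$$

with the key assumption that **only free B is a kinase substrate** (the
recognition site is buried in the dimer), and symmetrically only free B′ is
a phosphatase substrate. Phosphorylation and dephosphorylation are
pseudo-first-order (`kp`, `kdp`, scaled by enzyme-amount multipliers);
Michaelis–Menten saturation is deliberately not modelled because ATP is in
vast excess over peptide in the experiments this emulates. Temperature
enters as a parameter-set label, not an Arrhenius law. The ODE systems are
integrated with `deSolve::lsoda` at rtol 10⁻⁸/atol 10⁻¹⁰; enzyme additions
are events handled by integration restarts; conservation of total A and of
the B family is checked after every run and stored (typical drift
≤ 10⁻¹⁰ relative).

The consequence of gating is that the observed rate is
$k_\mathrm{eff} \approx k_p \cdot f_\mathrm{free}(B)$ in the fast-exchange
limit, decreasing with the association constant and with total
concentration. The trace is not a single exponential — free A accumulates
as B is consumed and progressively suppresses the free-B pool — so fitted
rates depend on the fitting window, and calibration and recovery always
share one.

**Calibration.** No dissociation constant is available for the switch
variants; the experiments report effective rates. The presets in
`preset_kinetics()` therefore fix `kon = 10 µM⁻¹ min⁻¹` and solve for
`koff` (by `calibrate_dissociation()`/`uniroot`) so that the zero-noise
simulation, fitted exactly as the corresponding experiment is fitted,
reproduces the target effective rate: 0.20 min⁻¹ for the free peptide,
8.0×10⁻³ min⁻¹ (product formation, 50 µM equimolar), 9×10⁻³ and 8×10⁻²
min⁻¹ for the CD traces at 25 and 37 °C, 0.07 min⁻¹ for tether-mode
release and 0.10 min⁻¹ for avidity-mode release. The implied Kd ≈ 0.34 µM
(25 °C HPLC conditions) is a calibration output, not a measurement. Under
these parameters the model reproduces the observed structure without
further adjustment: a 25-fold slow-down at 50 µM, a ~9-fold re-acceleration
on dropping to 1 µM, and a sub-linear (~2.6-fold) response to tripling the
kinase, the signature of partial dissociation limitation.

An optional weakened partial complex of A with phosphorylated B (`ABp`) is
off by default. The HPLC observable counts complexed B as substrate because
acidic reversed-phase conditions dissociate the dimer on-column — a
documented assumption.

**Tether mode** fixes the anchor's total membrane density and treats all
quantities in well-mixed µM equivalents; cargo binds the anchor with the
same CC interaction (`kon_t`, `koff_t`) and is processed only in solution.
**Avidity mode** tracks eight species (A, B, AB, B′ in solution and on the
membrane): monomers exchange at `k1on`/`k1off` (default 0.05 and 2 min⁻¹,
i.e. a 2.4% monomer membrane fraction), the dimer detaches at
`k1off/avidity_factor` (default factor 100), and `avidity_factor = 1`
reproduces the monomer baseline exactly. A known limitation of this
deliberately minimal, well-mixed treatment: the membrane dimer pool drains
through dissociation followed by fast monomer detachment, because membrane
re-association is not accelerated by 2D confinement. Equilibrium membrane
enrichment with both proteins present is therefore modest (~1.4× the
monomer baseline with defaults) rather than the dramatic contrast seen on
real bilayers; the *kinetics* of phosphorylation-driven release — the
quantitative output — are unaffected. A membrane-phosphorylation flag
(`membrane_phospho`) optionally allows on-membrane processing.

# Estimation procedures

Rates are estimated by nonlinear least squares (`minpack.lm::nlsLM`) of
$y = y_0 + (y_\infty - y_0)(1 - e^{-kx})$ (rise, also used for decays to a
plateau) or $y = y_0 e^{-kx}$ (decay to zero). Initial guesses are
`y0 =` first point, `y_inf =` last point, `k = 1/(time to half range)`;
`k` is bounded to [0, 1000 min⁻¹] and flagged when it sticks at a bound
(constant input returns `k = 0`, flagged, rather than failing). Flat
reference channels use the constant fit `y = k` (the mean, with its SEM).
The membrane-binding comparisons use Student's unpaired two-tailed t test
with pooled variance by default (Welch by flag); zero-variance degeneracies
are handled explicitly (equal means: t = 0, p = 1; unequal: infinite t,
flagged).

# Imaging quantitation

A z-profile is the mean intensity of each z slice; the membrane signal at a
time point is the profile maximum (the single-max-slice rule; no local
peak fitting), and the peak-intensity time course feeds the exponential
fits. Membrane amounts are quantified as baseline-subtracted peak areas:
trapezoidal integration over a window (default argmax ± 3 slices) after
subtracting a straight line through the medians of two 3-slice flanking
windows — an automated, reproducible stand-in for manual bulk-background
subtraction. Negative areas are possible and reported. Colocalization is
judged by argmax positions agreeing within one slice by default.

# Synthetic data

Generators produce every input the pipeline consumes, with ground truth
attached: HPLC substrate/product areas (multiplicative 5% CV noise), CD
kinetic traces and melts (additive Gaussian, 2% of dynamic range), and SLB
z-stack series (Gaussian membrane peak in z, σ = 0.5 µm on a 0.25 µm grid,
uniform bulk background, Poisson-like pixel noise, coincident peaks across
channels, constant lipid channel). Noise levels are package defaults chosen
to make recovery non-trivial but achievable; the emulated instruments do
not report their noise statistics. Default problem sizes keep everything
desk-scale: 61–241 point time courses, 86-point melts, 41×16×16 stacks at
up to ~36 time points. All generators are byte-deterministic under a fixed
seed.

What the generators do *not* emulate — and hence what green round-trip
tests do not establish about real data: chromatographic peak shapes and
integration error, CD baseline drift and absorbance flattening, optical
PSFs beyond a Gaussian axial response, photobleaching, stage drift,
evaporation, enzyme inactivation, and any FRET between labels.

# Reproducing the quantitative results

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
headline quantity from scratch — design geometry, stand-in fusion masses,
the calibrated rate structure (free rate, 50 µM rate, fold-reduction,
1 µM speed-up), generator → pipeline rate recoveries for all five assay
modes, triplicate-mean Tm recoveries, a membrane-release t statistic, and
the conservation-drift bound — and writes them as JSON. The test suite
(`tests/testthat/`) holds the per-module contracts, the independent-oracle
equivalences (closed forms, Gillespie simulation, quadrature, textbook
t formula, frozen residue-mass table) and the property suites.
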