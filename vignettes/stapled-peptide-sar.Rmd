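---
title: "Models and methods for stapled-peptide SAR analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for stapled-peptide SAR analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stapleSAR)
```

# Scope

stapleSAR implements the quantitative layer of a stapled-peptide
structure-activity campaign against Mdm2/MdmX: binding affinity from
fluorescence anisotropy, cellular potency from dose-response plates,
sequence-derived physicochemical descriptors, circular-dichroism helicity,
and the library-level indices that summarize permeability, selectivity and
serum binding. This vignette records the models, the assumptions behind
them, the numerical choices, and the places where the design was genuinely
open.

# Binding models

## Direct titration

A fluorescently labeled probe peptide at total concentration $L_t$ is
titrated with protein at total concentration $P_t$. Under a 1:1 model with
dissociation constant $K_d$, exact treatment of ligand depletion gives the
bound probe fraction as the root of a quadratic, and the observed
anisotropy is

$$r = r_0 + (r_b - r_0)\,
  \frac{(K_d + L_t + P_t) - \sqrt{(K_d + L_t + P_t)^2 - 4 L_t P_t}}{2 L_t},$$

with $r_0$ the anisotropy of free probe and $r_b$ of the saturated
complex. No large-excess approximation is made: in the assay configuration
(50 nM probe, protein spanning the transition) probe depletion is
substantial and the approximate hyperbolic model would bias $K_d$.

## Competition titration

An unlabeled competitor at total concentration $L_t$ displaces the probe
(total $L_{st}$) from protein (total $P_t$, with $P_t > L_{st}$ so that
displacement is informative). Free protein $p$ is a root of the cubic
$p^3 + d p^2 + e p + f = 0$ with

$$d = K_{d1} + K_{d2} + L_{st} + L_t - P_t,\qquad
  e = K_{d1}(L_t - P_t) + K_{d2}(L_{st} - P_t) + K_{d1} K_{d2},\qquad
  f = -K_{d1} K_{d2} P_t,$$

taken in its trigonometric form
$p = \bigl(2\sqrt{d^2-3e}\,\cos(\theta/3) - d\bigr)/3$,
$\theta = \arccos\!\bigl[(-2d^3 + 9de - 27f)/(2\sqrt{(d^2-3e)^3})\bigr]$,
and the probe fraction bound is $p/(K_{d1} + p)$. $K_{d1}$, the probe's
own dissociation constant, is measured once by a direct titration and held
fixed in all competition fits.

Two numerical points. First, the trigonometric root suffers catastrophic
cancellation when the bound fraction is very small (the root is a tiny
difference of two terms of order $d$); the implementation therefore
polishes the analytic root with safeguarded Newton steps *on the same
cubic*, bracketed by the physical interval $[0, P_t]$. Second, the
$\arccos$ argument is clamped to $[-1, 1]$ when it strays by less than
$10^{-9}$ (pure floating-point jitter) and is an error beyond that,
signalling an invalid parameter regime rather than returning NaN.

The closed form is certified against an independent oracle,
`solveEquilibriumNumeric()`, which solves the free-protein mass balance
$P_t = p + L_{st}\,p/(K_{d1}+p) + L_t\,p/(K_{d2}+p)$ by bracketed scalar
root finding plus Newton refinement. The test suite demands agreement to
$10^{-9}$ relative over 1000 log-uniform parameter draws ($K_d$ from
$10^{-2}$ to $10^{5}$ nM) and mass conservation to $10^{-10}$. The two
routes share nothing but the chemistry.

## Fitting and quality control

Both models are fitted by Levenberg-Marquardt least squares
(`minpack.lm`), with the dissociation constant parameterized on the log
scale so positivity is structural, endpoints $r_0, r_b$ fitted by default
and fixable, and standard errors from the Jacobian at the optimum (delta
method for the back-transformed $K_d$). Convergence is reported honestly;
a curve whose dynamic range is indistinguishable from noise is returned as
unidentifiable with a QC flag rather than fitted.

The curve-validity checks mirror the assay conventions: a competition
baseline that falls below the free-probe anisotropy (evidence of a
probe/ligand interaction), a direct titration that does not start at the
free-probe anisotropy, and non-monotonicity beyond noise. Flag thresholds
are 3 noise standard deviations, with the noise taken from fit residuals
(or from first differences when no fit is available).

# Dose-response analysis

Raw signals are normalized to plate controls as
$100\,(raw - \min)/(\max - \min)$; the maximum controls are
assay-specific (a saturating concentration of the template peptide for the
p53 reporter, a lytic peptide for LDH release, tetracycline for the
counterscreen), and values above 100% are legal and meaningful.

EC50s come from a four-parameter logistic with the bottom fixed at 0%.
The top is free by default because reporter efficacy can exceed the
control; proliferation curves are fitted with the top fixed at 100%
inhibition. The assay itself does not disclose a fitting model; the 4PL
with these constraints is this package's choice and is recorded as such.
Censoring is explicit: when the response never crosses half of the fitted
top within the tested range, when the fitted midpoint lies above the
highest tested concentration, or when the fitted maximal effect is below
20% activity (too small to support a potency claim), the EC50 is reported
as `>` the top tested concentration. The default simulated plate design is
a 10-point, 3-fold serial dilution topping out at 50 µM in-well.

Stability half-lives use log-linear regression of $\ln(\%\,remaining)$
against time rather than a nonlinear exponential fit — at the 4-5 time
points of the homogenate/plasma assays the log-linear estimator is robust
and unbiased under multiplicative noise. A slope that is non-negative or
not significant at $p < 0.05$ yields a censored "> last time point"
half-life, matching how stable compounds are reported.

# Peptide model

Sequences are written in a strict grammar: mandatory `Ac-`/`H-` and
`-NH2`/`-OH` caps (terminal state is worth a full charge unit and is never
defaulted), one-letter codes for proteinogenic residues, bracketed tokens
for non-naturals (`[R8]`, `[S5]`, `[X]`, `[Cba]`, `[Aib]`, `[Sar]`,
`[Gla]`, `[aMeE]`, `[aMeF]`, `[hS]`, `[hR]`, `[KN3]`, `[bA]`) and `[dX]`
for D-enantiomers. Unknown tokens are errors, never skipped. Staples made
of dedicated arm residues are inferred from the tokens (R8/S5: olefin
i,i+7; S5/S5: olefin i,i+4; X/X: di-alkyne i,i+7); crosslinks between
proteinogenic side chains (Lys-Glu lactam, triazole) are declared
explicitly because the notation cannot reveal them.

The charge model at pH 7.4: Asp/Glu/α-methyl-Glu −1; Gla −2 (two
side-chain carboxylates); Lys/Arg/homo-Arg +1; His 0 (side-chain pKa ≈ 6,
so the imidazolium is mostly deprotonated at 7.4 — His counts as a
"charged" residue for substitution grouping but never contributes to net
charge); azido-Lys 0 (the azide replaces the amine); staple arms 0;
lactam-bridged Lys and Glu side chains 0 because the amide consumes both
ionizable groups; free N-terminus +1, acetyl 0; C-terminal amide 0, free
acid −1. This model reproduces the reported net charges of the library
peptides (−1 for the clinical poly-Ala-tail molecule, −4 for the
A8E/EEAAAA-tail analog).

Helical-wheel geometry uses exactly 100°/residue (ideal α-helix, 3.6
residues/turn). The hydrophobic moment is the per-residue-normalized
magnitude of the vector sum of hydrophobicities at the wheel angles, on
the Eisenberg consensus scale with non-naturals mapped to their nearest
natural analog (Cba→Leu, Aib→Ala, homo-Ser→Ser, homo-Arg→Arg, Gla→Glu,
staple arms→Leu). Only the polarity dichotomy matters for the
amphipathicity analyses, so any consistent scale would do; the moment is
invariant under global wheel rotation and near zero for compositionally
uniform sequences.

The tail helical-propensity classifier is deliberately simple: a
C-terminal extension is "low" propensity iff it contains Gly, Pro or
sarcosine anywhere, or a D-residue at a non-C-terminal position; otherwise
"high". A single C-terminal D-residue — the protease-protecting cap of the
poly-Ala tails — does not break the helix. No quantitative predictor was
disclosed for the published High/Low labels; this rule is
reverse-engineered to reproduce all 19 printed labels and is flagged as
such. D-residues share the parent residue's charge and hydrophobicity;
chirality affects only this classifier.

# CD helicity

Measured ellipticity (millidegrees) converts to mean residue ellipticity
as $MRE = \theta/(10\,l\,C\,n_b)$ with $n_b = n - 1$ peptide bonds by
default (switchable to $n$; the convention must simply match the reference
constants). Fraction helix uses the single-wavelength 222 nm estimator
$f_H = (MRE_{222} - \theta_{coil}) / (\theta_{helix}(n) - \theta_{coil})$
with $\theta_{helix}(n) = -40000\,(1 - 2.5/n)$ and
$\theta_{coil} = +640$ deg cm² dmol⁻¹, clamped to $[0, 100]$%. This
replaces full spectral deconvolution (proprietary software, out of scope),
so published helicity percentages are not point-reproduced; the estimator
is validated instead by round-tripping two-basis synthetic spectra, which
recover mixing weights to within 2 percentage points across the weight
grid $\{0, 0.25, 0.5, 0.75, 1\}$.

# Library indices and censoring

Assay tables contain bounds, not just numbers: `>50` (no midpoint below
the ceiling), `>>50` (no measurable activity at all; stored as
greater-than with a distinct display glyph, identical in arithmetic),
`<1`. All derived ratios propagate these bounds: a `>` numerator gives a
`>` ratio; a censored denominator is an error because the ratio's bound
direction would be undefined. The indices are

* **cell ratio** = cellular EC50 / binding $K_d$ (units harmonized by the
  exact factor $10^3$): a permeability proxy, large meaning impermeable;
* **on-target index** = off-target / on-target proliferation EC50;
* **serum shift** = EC50 at 10% serum, 16 h / EC50 at 0% serum, 4 h;
* **fold improvement** = reference / improved potency.

The library filter for permeability analysis keeps records with
$K_d < 10\ \mu M$ and cellular activity at least 10× more potent than both
the counterscreen and LDH EC50s. Censored `>` entries are evaluated at
their bound — an optimistic pass, consistent with how ceiling-censored
clean profiles are interpreted in practice. The filter is idempotent and
logs its before/after counts in an append-only provenance log.

The tumor-volume formula is implemented exactly as reported,
$4\pi abc/3$ with $a, b, c$ measured diameters — dimensionally this is 8×
the ellipsoid volume from diameters, so a documented `"ellipsoid"` variant
($\pi abc/6$) is provided. Tumor growth inhibition is
$100\,(1 - \Delta T/\Delta V)$ on growth from baseline to the last common
time point; published TGI percentages typically come without a printed
formula, so this growth-based definition is the package's own, stated
here. Correlations default to Pearson on log10-transformed potency-like
quantities (Spearman available); no single correlation statistic is
canonical for lipophilicity-permeability trends, so the default is
likewise recorded here as a package choice.

# Synthetic data

Every input has a seeded generator whose forward model is the same
equation the fitter assumes — so recovery tests measure estimator quality,
not model mismatch — plus the planted structure the library analyses look
for: a configurable LogD → log10(cell ratio) slope (default −0.8, scatter
0.3 log units), an exact count of planted toxic records with measurable
LDH/counterscreen potencies, and serum-shifted potencies for poorly
soluble (high-LogD) records. Noise models are Gaussian on anisotropy (2%
of the dynamic range by default; assay CVs are not published, so this is
an assumption surfaced as a parameter) and on normalized percent (3
points), with triplicate measurements per titration concentration
reflecting the reported minimum of three replicates. Competition dilution
series are centered on the displacement midpoint computed from the exact
mass balance, the way a real assay centers its series on the expected
IC50. Ground truth travels in `truth` slots and `truth_*` columns that no
analysis stage reads.

What the generators do *not* emulate: plate edge effects, compound
aggregation artifacts, probe photophysics, correlated replicate errors,
and any mechanistic link between sequence and potency beyond the planted
statistical trends. Passing recovery tests therefore demonstrates
estimator correctness and calibration under the stated noise model, not
robustness to real-data pathologies.

# Problem sizes and defaults

The calibration harnesses use 200 seeded titrations for binding recovery
(12 concentrations × 3 replicates each), 100 plates for EC50 recovery,
1000 parameter draws for the closed-form/oracle certification, and 20
simulated libraries of 200 peptides for the correlation analyses. These
sizes give stable pass/fail behavior for the stated thresholds (e.g.
median $K_{d2}$ error < 5% at 2% noise) while keeping the full suite
around a minute of compute.

# Known limitations

* Apparent, not intrinsic, dissociation constants: no correction beyond
  the exact depletion model is attempted, matching how the assay reports.
* The charge model is a formal-charge table at a single pH; no pKa
  prediction, no conformational modulation.
* The helix estimator is single-wavelength; aromatic and staple
  contributions at 222 nm are not deconvolved.
* Censored-value arithmetic is deliberately conservative: operations whose
  bound direction would be ambiguous fail loudly instead of guessing.
* The tail-propensity rule is a classifier fitted to 19 labeled examples;
  it is not a physical helix-propensity calculator.
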