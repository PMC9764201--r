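---
title: "Methods: binding thermodynamics and channel metrics for half-calcified calmodulin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding thermodynamics and channel metrics for half-calcified calmodulin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfcam)
```

# The scientific question

Calmodulin (CaM) preassociates with the IQ motif in the C-terminus of the
L-type calcium channel CaV1.2 and controls both its open probability (Po)
and its calcium-dependent inactivation (CDI).  At resting intracellular
calcium (50--100 nM) the identity of the preassociated species matters:
fully calcium-free apoCaM binds the IQ motif too weakly (KD in the
micromolar range, against <100 nM free CaM) to account for the observed
constitutive regulation.  The hypothesis this package quantifies is that
the preassociated species is *half-calcified* CaM -- Ca2/CaM, with two
Ca2+ ions on the C-lobe EF-hands (EF3/EF4) and an empty N-lobe -- which
binds the IQ motif with nanomolar affinity.

The package implements the quantitative machinery needed to make and test
that argument: a coupled Ca2+/CaM/IQ equilibrium model, simulation and
fitting of isothermal titration calorimetry (ITC) isotherms,
fluorescence-polarization (FP) binding analysis, whole-cell and
single-channel electrophysiology metrics, and light structural quality
metrics, together with seeded synthetic-data generators that reproduce
the study conditions for every analysis.

# Equilibrium model

## Two-step binding ladder

IQ-bound CaM is modelled as a macroscopic two-step calcium ladder,

apoCaM-IQ  --(k1, n Ca2+)-->  Ca2/CaM-IQ  --(k2, n Ca2+)-->  Ca4/CaM-IQ,

with partition function `Z = 1 + k1 c^n + k1 k2 c^(2n)` in the free
calcium concentration `c`.  `species_fractions()` evaluates the three
fractions from `Z`; the evaluation is done in log space so a 200-point
grid spanning 1 nM to 1 mM neither overflows nor loses the tails.

`n_per_step` defaults to 2: the two EF-hands of one lobe load
cooperatively as a unit, which is how the lobe-wise affinities that
motivate the model were measured.  It is configurable to 1 for a
microscopic, per-site ladder.  The macroscopic constants are always
user-supplied -- the package deliberately hard-codes no lobe affinities,
because published per-lobe constants differ between preparations and the
species profile is meant to be recomputed for whichever constants a user
trusts.

The intermediate fraction `f_ca2(c)` is unimodal: it rises as the
C-lobe (tight) step loads and falls as the N-lobe (weak) step completes.
Its maximum sits between the two step midpoints `k1^(-1/n)` and
`k2^(-1/n)`; the test suite checks this against a brute-force grid
search.

## Linkage, van't Hoff scaling, and heat capacity

`apparent_kd_linkage()` implements the thermodynamic square cycle: if the
IQ peptide binds the calcium-loaded lobe `r`-fold tighter than the empty
lobe, the apparent calcium affinity of the IQ-bound lobe improves by the
same factor, `KDapp = KD(free) * r`.  A coupling ratio of 10 turns a
1 uM lobe into a 100 nM lobe -- the quantitative origin of calcium
loading at basal calcium.

`vant_hoff_kd_ratio()` scales a dissociation constant between
temperatures under a temperature-independent enthalpy,
`KD(T2)/KD(T1) = exp[(dH/R)(1/T2 - 1/T1)]` with
R = 1.98720425 cal mol^-1 K^-1 and temperatures in kelvin
(`celsius_to_kelvin()` converts bench notation).  For
dH = -15 kcal/mol between 27 and 37 C the ratio evaluates to 2.25
(three significant figures); rounded to two figures this is the familiar
"2.3-fold" weakening.  `delta_cp()` is the finite-difference
heat-capacity change from enthalpies at two temperatures; a negative
value is the classic signature of hydrophobic burial at the binding
interface.

# ITC simulation and fitting

## Forward model

The forward model reproduces a perfusion-cell titration calorimeter.
After injection `i` of volume `v` into cell volume `V`, totals follow

* titrand: `M_i = M_0 (1 - v/V)^i`
* injectant: `X_i = X_syr (1 - (1 - v/V)^i)`

Free ligand is the root of the conservation equation
`X_f + sum_c n_c M Ka_c X_f / (1 + Ka_c X_f) = X_t`: a closed-form
quadratic for one class of sites, and a bracketed `uniroot()` solve
(relative tolerance 1e-14, bracket `[0, X_t]` where the equation is
monotone) for two independent classes.  The measured heat of injection
`i` is the change in bound-ligand enthalpy content corrected for the
enthalpy displaced out of the overflowing cell,
`dq_i = Q_i - Q_{i-1} + (v/V)(Q_i + Q_{i-1})/2`, normalised by the moles
of injectant delivered.  A conservation check -- cumulative raw heat
equal to `n * M_0 * V * dH` once the cell saturates, to within the ~2%
displacement correction -- is part of the test suite, as is agreement
with an independent bisection-based implementation of the two-class
model.

The first injection of a real titration under-delivers because of the
syringe dead volume; `delete_first_injection()` removes that point while
keeping the molar-ratio bookkeeping of the remaining points intact, and
every fitting example in the package follows that convention.

## Fitting

`fit_one_site()` and `fit_two_site()` are bounded Levenberg--Marquardt
least-squares fits (via `minpack.lm::nls.lm`) of the noise-free forward
model to the observed heats.  Association constants are fitted on the
log scale, which conditions the problem across the 1e6--1e9 M^-1 range;
stoichiometries float by default (the published fits do not state
whether n was fixed, and floating it is the conservative choice).
Standard errors come from the scaled inverse Hessian, with the `ka`
error delta-method transformed back from the log scale.
Non-convergence (including parameter estimates pinned at their bounds)
is flagged on the returned object rather than raised, so degenerate
inputs -- for example a flat, zero-enthalpy isotherm -- yield a usable
diagnosis.

The two-class model is the "two sets of independent sites"
parameterisation of the instrument software tradition (per-class
`(n, Ka, dH)`), not a sequential-cooperative scheme; the fitted classes
are reported in descending-`ka` order to remove the label-swap
degeneracy, and an identifiability warning is attached when the two
association constants are within a factor of 3.  `apparent_kd()`
extracts `1/Ka` of the *stoichiometric* class -- the class whose `n` is
nearest the expected 2 Ca2+/protein -- because the minor,
non-stoichiometric class of the biphasic 27 C isotherm is a sample
artifact, not the binding event of interest.

## Study-condition presets

`hc_presets()` stores the titration schedules and generating parameters
for the five ITC conditions analysed (calcium into the CaM12'-IQ complex
at 27 and 37 C; Ca2/CaM12' into wild-type IQ at both temperatures and
into the weakened Y1657D variant), each as 35 x 10 ul injections into a
1.5 ml cell with a default per-injection heat noise of 0.1 kcal per mole
of injectant -- a typical figure for this instrument class; the true
instrument noise is not published, so the value is configurable.

# Fluorescence polarization

`polarization()` is the standard intensity combination
`P = (Iv - g Ih)/(Iv + g Ih)`.  Binding curves are fitted on
baseline-subtracted polarization (the zero-titrant point, when present,
defines the free-peptide baseline) in two ways:

* `fit_fp(t)` -- the conventional hyperbola `Y = B X/(Kd + X)`.  This is
  what the assays it emulates report, and it is exact when the labelled
  peptide is dilute relative to Kd.
* `fit_fp(t, depletion = TRUE)` -- the depletion-exact quadratic, which
  accounts for titrant consumed by the labelled peptide.  With 100 nM
  labelled peptide and a 16 nM binder the hyperbolic fit overestimates
  Kd several-fold (the titrant axis is effectively shifted by the bound
  fraction) while the quadratic fit recovers the generating value; the
  test suite demonstrates both behaviours and their agreement in the
  dilute-label limit.

## The saturation upper bound

`kd_upper_bound()` turns the visual argument "the curve is saturated at
concentration c, so KD < c" into a testable rule: a plateau exists when
the last three points agree among themselves (SD within
`saturation_tol`, default 5%, of the plateau level -- an SD-based
consensus rather than a range check, so that a noise tolerance equal to
the declared point noise does not randomly veto the plateau); the bound
is the smallest titrant concentration from which the curve stays within
`saturation_tol` of the plateau.

Two design notes.  First, the plateau level is the fitted maximal
polarization B when the last three points agree with it, and the mean of
the last three points otherwise.  The fallback matters in the depletion
regime: a hyperbola fitted to depletion-sharpened data extrapolates a
maximum ~15% above the observed plateau, so insisting on agreement with
the fitted B would declare "no plateau" on exactly the tight-binding
titrations the rule exists for.  Second, the bound is *valid but
conservative* under depletion: saturation of a labelled peptide at
concentration L requires titrant near `L + several KD`, so for a binder
much tighter than the labelled concentration the rule reports a bound of
a few hundred nanomolar -- above L, never below it.  A claim that
saturation pins KD below the labelled-peptide concentration itself
cannot be reproduced by the binding model: at 100 nM titrant, a 16 nM
binder with 100 nM labelled peptide is only ~67% saturated (quadratic
oracle), a gap far outside a 5% tolerance.  The acceptance suite states
this expectation anyway and the corresponding check fails honestly; the
number the package reports (~430 nM for the study grid) is what the
stated rule yields on the stated conditions.

`free_titrant()` implements the depletion correction used when plotting
against free rather than total titrant,
`free = total - labelled * saturation`, floored at zero with a warning.

# Whole-cell metrics

Traces are stored inward-negative; metrics use magnitudes.  Leak and
capacitive-transient subtraction is assumed done upstream (the generator
can inject a blanked capacitive spike to test robustness of the
metrics).

* `peak_current_density()`: per-potential peak inward current divided by
  cell capacitance, with the potential of Imax identified.
* `r300()`: fraction of the activation peak remaining 300 ms after
  depolarization onset.  The clock starts at onset (not at the peak);
  the current at 300 ms is a 5 ms-window mean (configurable -- the
  published analyses do not state whether an instantaneous sample or a
  short mean was used, and a 5 ms mean at 10 kHz suppresses single-sample
  noise without biasing a 300 ms-scale decay by more than ~1e-5); the
  activation peak is searched in the first 100 ms (configurable), which
  keeps the estimate off the late, noise-dominated trace and lets
  facilitating traces (r300 > 1, flagged with a warning) be represented.
* `cdi_f300()` / `vdi()`: `f300 = r300(Ba) - r300(Ca)` and
  `VDI = 1 - r300(Ba)`.  The identity `f300 + rCa300 = rBa300` is exact
  by construction.

The generator `gen_wholecell()` produces 900 ms steps from -60 to +50 mV
in 10 mV increments with bi-exponential inactivation per carrier and a
Boltzmann-activated linear driving force for the peak I/V shape.  The
`wc_strong_cdi` preset uses Ba2+ decay (w_fast 0.3, tau 150 ms / 2 s)
much slower than Ca2+ decay (w_fast 0.7, tau 40 ms / 500 ms), i.e. clear
CDI, with 20 pF capacitance and 5 pA noise -- representative magnitudes
for transfected HEK cells; r300 on these families matches the
closed-form bi-exponential evaluation to 1e-3.

# Single-channel pipeline

`simulate_sweeps()` drives `k` independent two-state Markov channels
with exact exponential dwell sampling, superposes them, scales by the
unitary current, adds broadband Gaussian noise and then applies the
recording filter -- a digital 4-pole Bessel low-pass built by
pre-warped bilinear transform from the analog prototype poles
(-1.37006783 +- 0.41024972i, -0.99520876 +- 1.25710574i, -3 dB at
1 rad/s), the filter type and order of the stated recording chain
(2 kHz at 10 kHz sampling).  Noise is added *before* the filter because
that is where patch noise physically enters; the in-band noise SD is
correspondingly below the nominal broadband value.

`idealize_half_height()` applies the half-amplitude criterion extended
to stacked openings: thresholds at `(m - 1/2) * i` assign each sample an
open count, and events shorter than the filter risetime
`0.3321/f_c` (0.166 ms at 2 kHz) -- which the filter cannot have
resolved -- are merged into their longer neighbour.  Event boundaries
are resolved to the sample grid; no sub-sample interpolation and no
missed-event correction beyond the risetime merge is attempted, a known
source of small negative bias at low signal-to-noise.

`estimate_channel_count()` takes the maximum simultaneous open level,
counting only events held for at least twice the risetime: a genuine
stacked opening dwells for milliseconds, while a threshold-grazing noise
excursion survives the merge only at the risetime scale, so the duration
gate rejects spurious extra levels without ever pushing the estimate
above the true count.  The estimator is reliable for k < 4, degrading
(downward) as openings at the top level become rare.  `open_probability()`
divides the time-averaged open level NPo by k; `mean_ensemble_average()`
is the pointwise sweep mean, whose plateau converges to `k * Po * i`.

The round-trip property -- simulate, idealize, estimate, recover Po
within 10% -- is verified over Po in {0.05, 0.2, 0.5} and k in {1, 2, 3}
at unitary current -1 pA and 0.2 pA broadband noise, 25 sweeps of 2 s
per condition (the sizes keep the full 9-condition sweep under half a
minute while leaving the Monte-Carlo error a few-fold below the 10%
margin).  Mean open and closed dwells are 8 ms-scale, comfortably above
the risetime, which is the regime where the half-height criterion is
trustworthy.

# Structure metrics

`superpose()` is a Kabsch least-squares rigid-body fit (SVD with the
reflection guard) over a selectable atom set; `select_backbone()`
selects N, CA, C, O by default -- the heavy-backbone variant
`c("N","CA","C")` is available because deposited precision statistics do
not always state whether O was included -- over an inclusive residue
range.  `ensemble_rmsd()` superposes every model on an iteratively
refined mean structure and reports both conventions: RMSD to the mean
(the common deposition convention, reported with its SD) and mean
pairwise RMSD; the former is never larger than the latter.  The
implementation is cross-checked in the tests against a brute-force
Euler-grid superposition oracle, an analytic one-atom-displacement case,
and `bio3d`'s fitting on random coordinates.

`fit_alignment_tensor()` solves the five independent Saupe-matrix
elements from measured residual dipolar couplings by SVD linear least
squares (the dipolar prefactor is absorbed into the tensor, so outputs
are in coupling units), refusing rank-deficient vector sets;
`q_factor()` is `RMS(Dmeas - Dcalc)/RMS(Dmeas)`.  A minimal fixed-column
multi-model PDB reader/writer supports NMR-style ensembles (first altloc
kept, HETATM ignored); when a locally available experimental ensemble of
the Ca2/CaM12'-IQ complex is present the test suite compares the C-lobe
backbone precision over residues 85--149 against its deposited
0.83 +- 0.09 A figure, and `gen_ensemble()` provides a synthetic
stand-in -- an ideal-helix scaffold with per-model Gaussian jitter whose
expected to-mean RMSD is `sigma * sqrt(3) * sqrt(1 - 1/M)` -- for
self-contained testing.

# What the generators do and do not emulate

The generators reproduce the *statistical structure the analyses
assume*: per-injection heat noise that is Gaussian and independent,
polarization noise proportional to the dynamic range, ideal two-state
gating with stationary rates, bi-exponential macroscopic inactivation,
and isotropic coordinate jitter.  Real data violate all of these in
known ways -- ITC baselines drift and heats correlate through
integration, channels show modal gating and adjacent-state correlations,
whole-cell currents carry series-resistance and space-clamp errors, and
NMR ensembles have anisotropic, restraint-shaped variance.  Passing the
synthetic round trips therefore demonstrates that the *estimators are
correct and unbiased under their own model assumptions*, not that those
assumptions hold for any particular recording.  Conversely, the fitted
parameters of real experiments enter only through the preset registry,
so every reported recovery is a genuine estimate from simulated raw
data, never a copied constant.

# Numerical choices and limitations

* Units: molar, kelvin, kcal/mol, seconds, pA, pF, Hz, angstrom
  throughout; helpers convert bench notation.
* Seeded generators save and restore the caller's RNG state, so
  `gen_*` calls do not perturb surrounding simulations.
* Free-ligand roots: relative tolerance 1e-14; fit convergence is
  `nls.lm` information codes 1--4 with an additional at-bounds check.
* The ITC displacement correction makes total-heat conservation exact
  only to ~2%; fits are unaffected because the forward model and the
  data share the convention.
* `kd_upper_bound()` cannot bound KD below the labelled-peptide
  concentration in the depletion regime (discussed above); use the
  depletion-exact fit when a point estimate is needed there.
* Single-channel idealization has no missed-event correction beyond the
  risetime merge and resolves transitions to the sample grid; at
  SNR < 3 the half-height criterion degrades and a warning is issued.
* The channel-count estimator can only undercount, and `Po = NPo/k`
  inherits that bias direction; with k >= 4 simultaneous-opening counts
  are explicitly unreliable.
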