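---
title: "Modelling CHRONO as a second repressor channel of the circadian clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CHRONO as a second repressor channel of the circadian clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoclock)
```

## The scientific problem

The mammalian circadian pacemaker is a transcription–translation feedback
loop (TTFL): the BMAL1–CLOCK heterodimer activates E-box genes (*Per1*,
*Per2*, *Cry1*, *Cry2*, *Rev-erb*), whose protein products feed back to
repress BMAL1–CLOCK; an accessory loop lets REV-ERB repress *Bmal1*
transcription. CHRONO is a comparatively recently recognized clock
component: an E-box-driven gene whose product represses BMAL1–CLOCK
through a pathway independent of the cryptochromes — it binds BMAL1 and
PER2 (not PER1 or CRY1), and its loss lengthens the free-running
behavioural period, much like loss of *Cry2*.

`chronoclock` implements a mechanistic ODE model of this architecture
with **two independent stoichiometric repression channels** acting on the
activator — canonical PER–CRY sequestration, and a CRY-independent
PER2-routed CHRONO channel — together with an in-silico genetics engine
(knockout, fractional knockdown, constitutive overexpression) and the
rhythm-analysis stack used for behavioural and bioluminescence
recordings. All wet-lab inputs are replaced by seeded synthetic
generators, so the entire pipeline runs from code alone.

## The reduced model

State variables (concentrations in arbitrary units, time in hours):

* mRNAs $M_g$ for $g \in \{Per1, Per2, Cry1, Cry2, Chrono, Rev,
  Bmal1\}$;
* cytoplasmic proteins: a lumped PER pool, CRY1, CRY2, CHRONO; nuclear
  REV-ERB; the nuclear activator pool $A$ (lumped BMAL1–CLOCK);
* cytoplasmic heterodimers PER·CRY1, PER·CRY2, PER·CHRONO, their nuclear
  counterparts (the repressor pools), and the sequestered activator
  complexes $A$·PER·CRY1, $A$·PER·CRY2, $A$·PER·CHRONO.

E-box transcription uses Michaelis activation by the **free** activator,
with no explicit repression term:

$$\frac{dM_g}{dt} = \mathrm{basal}_g + v_g \frac{A_{\rm free}}
{K_{tx} + A_{\rm free}} - d_g M_g ,$$

and all repression emerges dynamically from mass-action sequestration
$A + R \rightleftharpoons C$ — the defining nonlinearity of
protein-sequestration (stoichiometric) clock models. *Bmal1* is the one
exception, repressed by nuclear REV-ERB:
$dM_{B}/dt = v_B K_R / (K_R + \mathrm{REV}) - d_B M_B$.

Two constraints are hard-wired from the biochemistry of CHRONO:
its mRNA decay rate is tied to *Per2*'s (the same parameter symbol, so a
perturbation of one is a perturbation of both), and CHRONO reaches the
nucleus only via the PER2-bound route, imported at the same rate as the
PER–CRY complexes. CHRONO–CRY2 and CHRONO–DEC2 binding are deliberately
not represented in the oscillator: repression by CHRONO does not require
CRY2, and no DEC species exist in the model. The full
co-immunoprecipitation pattern (CHRONO binds BMAL1, PER2, CRY2, DEC2 but
not PER1, CRY1, DEC1) is retained as a binding-rule set
(`defaultChronoBindingRules("interaction")`) used by the rule-based
complex enumerator and by detailed-mode model extension.

## How the three channels are parameterized

The committed parameter set `default_reduced_v1` treats the three
repressor channels as kinetic variants of one another:

* **CRY1 channel — strong/slow.** Lower dissociation from the activator,
  lower degradation of the repressor pools. Slow repressor kinetics
  lengthen the period of the mixture, so *removing* CRY1 shortens the
  period.
* **CRY2 channel — weak/fast, self-sustaining.** Its kinetics alone
  support a limit cycle: a *Cry1* (or *Cry1*+*Chrono*) knockout remains
  rhythmic at a shorter period.
* **CHRONO channel — same complex kinetics as CRY2, subcritical gain.**
  CHRONO complexes bind, import and degrade like CRY2 complexes, but the
  CHRONO production flux is below the Hopf threshold of a
  single-channel loop. Three consequences follow, each matching the
  in-silico genetics: (i) with only CHRONO left (*Cry1*,*Cry2* double
  KO) the oscillation is *damped* rather than sustained; (ii) because
  its kinetics do not differ from CRY2's, deleting *Chrono* on a
  *Cry1*-KO background barely moves the period; (iii) on a wild-type
  background, deleting *Chrono* frees PER for the slow CRY1 channel and
  lengthens the period slightly — the *Cry2*-like knockout phenotype.

The period itself is calibrated, not fitted: uniformly scaling every
rate constant by $c$ rescales time exactly (period $\to$ period$/c$)
without changing the orbit, so after qualitative tuning the wild-type
period is set to 23.8 h by one exact rescaling
(`calibratePeriod()`). This preserves every period *ordering* across
genotypes by construction.

Overexpression (paper-silent magnitude) defaults to a constitutive
production of roughly twice the wild-type mean production flux of the
target protein, configurable per run.

## Rhythm classification

After discarding a transient, per-cycle peak-to-trough relative
amplitudes are computed from spline-interpolated peaks (minimum
separation 12 h):

* **sustained** — the last five cycle amplitudes vary by less than 2%
  and exceed $10^{-3}$ of the mean level;
* **damped** — at least two peaks exist and the amplitudes decay with a
  fitted exponential rate $\lambda > 10^{-3}\,h^{-1}$;
* **arrhythmic** — otherwise (including monotone relaxation).

With fewer than three peaks the classifier falls back on a damped-cosine
fit instead of raising an error. Knockout runs start from the stored
wild-type limit-cycle snapshot (state at a *Per2* mRNA peak) with the
deleted transcripts zeroed at day 0, so the pre-steady-state damping
transients are visible, which is exactly what the damped/arrhythmic
distinction needs.

## The analysis stack

**Chi-squared periodogram** (Sokolove–Bushell). For trial period $P$
with $K$ bins per cycle and $N$ complete cycles,
$Q_P = KN \sum_h (M_h - M)^2 / \sum_i (x_i - M)^2$, tested against the
upper-$\alpha$ $\chi^2_{K-1}$ quantile. Defaults: 6-min bins (1-min
recordings are rebinned 6:1 to stabilize sparse counts), trial grid
20–28 h in bin-width steps, $\alpha = 0.05$, no multiplicity correction
(the common actogram convention; Bonferroni is available as a flag).
Free-running periods are estimated from the first 7 days of constant
darkness, mirroring standard practice for wheel-running data.

**Detrending** subtracts a centred 24-h running mean and trims half a
window at each edge; it is linear and idempotent up to edge effects.

**Damped-cosine fitting** minimizes least squares for
$b + A e^{-\lambda t}\cos(2\pi t/P + \phi)$ with a deterministic
multi-start grid (periods 18–32 h, damping 0–0.1 h$^{-1}$); at each grid
node the linear parameters are solved exactly, and the best node seeds a
Levenberg–Marquardt refinement constrained to $\lambda \ge 0$. Flat
input returns an `identifiable = FALSE` flag instead of an error.

**Phase conventions.** For model trajectories CT 0 is anchored at the
*Bmal1* mRNA peak and one cycle is normalized to 24 CT hours (the
mapping is configurable); phases are interpolated peak times, not
centres of mass; phase differences are reported in $(-12, 12]$ h.
Under this convention the model's *Chrono* mRNA peaks in antiphase to
*Bmal1* — as the tissue qPCR data show, with *Chrono* peaking near
CT 12 — and with a larger relative amplitude and earlier peak than
*Cry2* mRNA.

## Synthetic data

* **Actograms** emulate infrared beam-break counts in 1-min bins:
  inhomogeneous Poisson events whose rate follows a two-level day/night
  profile with 1-h sigmoidal transitions (nocturnality ratio 5 by
  default), entrained to lights-off under LD 12:12 and free-running at
  the requested period in DD. The smooth profile was chosen so that
  expected counts have a closed form against which the generator is
  tested.
* **Bioluminescence traces** are damped cosines on a drifting baseline
  with Gaussian noise, in kcpm — the drift is what makes the detrending
  step meaningful.
* **qPCR time courses** sample a settled model trajectory every 4 h
  from CT 0 in triplicate, with multiplicative lognormal noise, and
  normalize the maximum replicate mean to 100.

All generators are pure functions of (parameters, seed); per-replicate
streams are split deterministically from the single seed. What passing
these tests does **not** show: real recordings have non-Poisson
bursting, ultradian structure, missing bins and cage disturbances, none
of which the generators emulate — the synthetic data validate the
analysis pipeline's logic, not its robustness to every artefact of real
telemetry.

## Numerical choices

Integration uses `deSolve::lsoda` (adaptive, stiff-capable — the
network mixes fast binding with slow transcription) at relative
tolerance $10^{-8}$ and absolute tolerance $10^{-10}$; period estimates
are required to move by less than 0.01 h under tenfold tolerance
tightening. States are clamped at zero within solver round-off when
rates are evaluated. Peak interpolation uses cubic splines with ties
broken toward the earlier time. Default problem sizes — 30 settle days
plus 10 observation days for limit-cycle characterization, 40 simulated
days per genotype in the battery — were chosen as the shortest windows
at which classification and period estimates are stable to well under
the 0.01-h reporting resolution.

## Detailed mode

`buildDetailedModel()` augments an externally supplied serialized base
model with *Chrono* mRNA dynamics and every CHRONO-containing complex
the binding rules permit, recording the count of newly added state
variables. The published 181-variable base model is not redistributed
with this package, so detailed mode requires the user to supply it;
without it the function raises an explicit error and the scenario
runner marks detailed-mode quantities as requiring the external base
rather than failing. The package's tests exercise the extension logic
against a synthetic stand-in base and an independent brute-force
complex enumerator.

## Known limitations

* The reduced model is a surrogate: it reproduces the qualitative
  genotype ladder and phase/amplitude structure, not quantitative
  periods of specific mutants beyond the calibrated wild type.
* DEC1/DEC2 dynamics, chromatin state (the HDAC arm of CHRONO
  repression is abstracted into the sequestration channel), light
  input, and re-entrainment dynamics are out of scope.
* The lumped PER pool means PER1/PER2-specific phenotypes cannot be
  distinguished in reduced mode.
* Stochastic (single-cell) simulation is not provided; all rhythms are
  deterministic ODE solutions.
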