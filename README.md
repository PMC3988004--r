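# chronoclock

In-silico genetics of the mammalian circadian clock with the CHRONO
repressor.

## What this is for

The mammalian circadian pacemaker is a transcription–translation
feedback loop: the BMAL1–CLOCK activator drives E-box genes (*Per1*,
*Per2*, *Cry1*, *Cry2*, *Rev-erb*), whose products repress it. CHRONO
is a CRY-independent repressor in this loop: it binds BMAL1 and PER2
(not PER1 or CRY1), and its loss lengthens the free-running period —
a *Cry2*-like phenotype produced through a separate pathway.

`chronoclock` is for researchers who want to interrogate this
architecture computationally. It provides:

* a reduced mechanistic ODE model of the clock with **two independent
  stoichiometric repression channels** on the activator $A$ (free
  BMAL1–CLOCK): PER–CRY sequestration and a PER2-routed CHRONO channel.
  E-box transcription is
  $dM_g/dt = \mathrm{basal}_g + v_g\,A_{\rm free}/(K_{tx}+A_{\rm free}) - d_g M_g$,
  with repression emerging purely from mass-action sequestration
  $A + R \rightleftharpoons C$; *Bmal1* is repressed by REV-ERB via
  $v_B K_R/(K_R + \mathrm{REV})$;
* an in-silico genetics engine: knockout (`gene:ko`, transcript zeroed
  from day 0), fractional knockdown (`gene:kd:0.3`), constitutive
  overexpression (`gene:oe`), freely composable;
* limit-cycle detection and classification (sustained / damped /
  arrhythmic), exact time-rescaling period calibration, and rule-based
  enumeration of CHRONO-containing protein complexes;
* the rhythm-analysis stack used on behavioural and bioluminescence
  recordings: Sokolove–Bushell chi-squared periodogram
  $Q_P = K N^2 \sum_h (M_h-\bar M)^2 / \sum_i (x_i-\bar M)^2$ against
  the $\chi^2_{K-1}$ upper-$\alpha$ quantile, running-mean detrending,
  damped-cosine fitting $b + A e^{-\lambda t}\cos(2\pi t/P+\phi)$, and
  phase/amplitude summaries in circadian time;
* seeded synthetic-data generators for locomotor actograms (1-min
  infrared beam-break counts under LD 12:12 then constant darkness),
  bioluminescence traces (kcpm, with baseline drift) and qPCR time
  courses (4-h sampling, triplicates, max = 100 normalization).

Concentrations are in arbitrary units, time in hours.

## Worked example

```r
library(chronoclock)

model <- buildReducedModel()        # committed set default_reduced_v1
findCycle(model)
#> CycleVerdict: sustained, period 23.80 h, rel. amplitude 1.371 (10 peaks)

report <- runScenarioBattery(model) # the full genotype battery
print(report)
#> Scenario report (default_reduced_v1, reduced mode)
#>               genotype classification period_h relative_amplitude damping_rate
#> 1                   WT      sustained    23.80             1.3709           NA
#> 2            Chrono_KO      sustained    24.03             1.3967           NA
#> 3              Cry1_KO      sustained    22.78             1.2491           NA
#> 4      Chrono_Cry1_dKO      sustained    22.89             1.2426           NA
#> 5            Cry2_kd30      sustained    24.33             1.4375           NA
#> 6    Cry2_kd30_Cry2_OE      sustained    23.51             1.3096           NA
#> 7  Cry2_kd30_Chrono_OE      sustained    24.06             1.3969           NA
#> 8        Cry1_Cry2_dKO         damped    22.97             0.1872      0.08835
#> 9 Cry1_Cry2_Chrono_tKO     arrhythmic       NA             0.0000           NA
#> Phenotype ladder: 10/10 checks pass
```

Reading the table: knocking out the strong/slow repressor *Cry1*
shortens the period (23.80 → 22.78 h) while knocking out *Chrono*
lengthens it (→ 24.03 h); deleting *Chrono* on top of *Cry1* barely
moves the period (22.89 vs 22.78 h — the two act through independent
channels); knocking *Cry2* down to 30% lengthens the period (24.33 h)
and constitutive overexpression of either *Cry2* or *Chrono* shortens
it back (23.51 / 24.06 h); with both cryptochromes gone the CHRONO
channel alone sustains only a decaying oscillation (damped,
$\lambda \approx 0.09\,h^{-1}$); removing *Chrono* as well abolishes
any residual rhythm.

The analysis stack round-trips its synthetic inputs:

```r
act <- genActogram(period = 23.96, daysLD = 7, daysDD = 10, seed = 5)
estimateFreeRunningPeriod(act, windowDays = 7)$period   # first week of DD
#> [1] 24    # one 6-min grid step from the generating truth

bl <- genBioluminescence(period = 27.29, amplitude = 8, dampingRate = 0.004,
                         driftSlope = 0.15, noiseSd = 0.3, days = 7, seed = 31)
d <- detrendSeries(bl$time_h, bl$value_kcpm, window = 24)
fitDampedCosine(d$time, d$value)$period
#> [1] 27.29795
```

A thin command-line interface over the same functions lives at
`inst/scripts/chronoclock` (subcommands `simulate`, `scenarios`,
`periodogram`, `fit-damped`, `fixtures`; each accepts `--seed`,
`--config`, `--out`, `--log-level`).

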