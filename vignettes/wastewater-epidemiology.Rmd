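---
title: "Methods: wastewater-based epidemiology of pharmaceutical use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wastewater-based epidemiology of pharmaceutical use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbepi)
```

## The problem

During an influenza pandemic the use of a narrow set of drugs — a
neuraminidase-inhibitor antiviral, respiratory antibiotics, decongestants —
surges over a few weeks. Almost all of that mass is excreted into sewers,
passes through wastewater treatment plants (WWTPs) and enters rivers.
Wastewater-based epidemiology reads this chemical signal in two directions:

* **forward** — from prescription statistics to the concentration a WWTP
  influent should show, and
* **backward** — from a measured influent mass load to the number of people
  actively taking the drug, and hence to compliance with what surveillance
  says was dispensed.

`wbepi` implements both directions plus the supporting arithmetic: hourly
concentration-to-load conversion, daily aggregation under left-censoring,
the influent/effluent removal mass balance, per-capita normalisation,
river-site loads and the population–load regression, and pandemic versus
non-pandemic period summaries. A synthetic-data generator reproduces the
statistical structure of a 24-h composite sampling campaign so the whole
pipeline can be validated against known truth.

## Units and core arithmetic

All concentrations are ng/L, flows m³/h (hourly) or m³/d (daily), loads
mg/d or mg/h, per-capita loads µg/cap/d. The conversions are:

* hourly load (mg/h) = concentration (ng/L) × flow (m³/h) / 1000,
* daily load = sum of 24 hourly loads,
* per-capita load (µg/cap/d) = daily load (mg/d) × 1000 / population,
* percent loss = 100 × (influent load − effluent load) / influent load,
  signed: a negative value is an apparent in-plant increase.

Hourly composite samples represent the preceding hour (the 18:00 sample
covers 17:00–18:00). Whether an autosampler timestamp marks the start or
the end of its interval is a convention, not a measurable; fixing it makes
maximum-load clock times reproducible.

## Censoring

Concentrations below an analyte's limit of quantification (LOQ) are
reported only as "<LOQ". The package stores censoring as a flag and never
silently substitutes a number: substitution happens only inside the load
calculations, under a named policy — `zero` (default), `half_loq` or
`loq`. `zero` makes every reported load a conservative lower bound, and
the three policies bracket the truth, which the tests assert as a
monotonicity property. Above-LOQ means and standard deviations are always
computed over the uncensored samples only, alongside the detection count,
so the censoring level stays visible in every summary. Maximum-likelihood
censored estimators (Kaplan–Meier, regression-on-order-statistics) are
deliberately out of scope: the reported quantity is the above-LOQ mean.

## The forward model

For a catchment of population $P$ producing $L$ litres of wastewater per
person per day (default 230 L/cap/d), a daily prescribed mass $M$ (g/d) of
a drug with excreted fraction $E$ predicts an influent concentration

$$C_w = \frac{M \cdot E \cdot F \cdot 10^9}{P \cdot L} \ \text{ng/L},$$

where $F \in (0,1]$ corrects for prescription statistics covering more
people than the plant serves: when a Primary Care Trust (PCT) of
population $P_{pct}$ is served by several plants, $F = P / P_{pct}$
(0.389 for the small study catchment, 6,230/16,000); $F = 1$ for national
statistics and for a PCT wholly served by one plant.

Prescription masses arrive either directly in grams or as Average Daily
Quantity (ADQ) counts converted through the per-analyte ADQ mass. Annual
national statistics are raised by 9.375% before the per-day division —
half of the ~18.75% summer–winter swing in UK antibiotic consumption — so
that a November sampling week is compared against a winter, not annual-mean,
prescribing rate; monthly local statistics are used as-is.
Co-trimoxazole is split into 0.16 g trimethoprim and 0.8 g
sulfamethoxazole per ADQ. No molar-mass correction is applied between the
antiviral prodrug and its excreted carboxylate metabolite: only the 80%
excretion factor links them, and the package keeps that convention (the
uplift knob `winter_uplift` and the censor policy are the only switches).

## Back-estimation and compliance

Inverting the same mass balance, the number of active users is

$$\hat n = \frac{\text{load (mg/d)}/1000}{\text{dose (g/d)} \times E},$$

with the standard adult antiviral regime 0.075 g twice daily (0.150 g/d)
as the canonical dosing. Estimates are reported as real numbers: a small
catchment yielding ~3 "user-day equivalents" is information, not an error.
Compliance is the ratio of wastewater-estimated users to
surveillance-predicted users (population × rate); the national pandemic
dispensing rate 0.13% is the default, the influenza-like-illness rate
54.2/100,000 an alternative, and because the ILI rate declined to
~33/100,000 within weeks the pair should be read as a sensitivity range
rather than two point truths.

## The synthetic-data generator

The generator is the package's test bed, emulating what the analysis
assumes about real sampling, with these components:

* **Diurnal flow.** 24 hourly flows whose total is exactly $P \times L$,
  modulated by a mean-zero bimodal shape (morning and evening peaks)
  scaled by `diurnal_amplitude` (default 0.4, giving roughly ±40% swings
  typical of small dry-weather sewer flows).
* **Flush pulses.** Each user excretes `dose × E` per day as discrete
  toilet flushes. The flush count per user is Poisson around
  `flushes_per_user_per_d` (default 4) with a minimum of one, and the
  user's exact daily mass is split evenly across their flushes; flush
  times follow a diurnal toilet-use profile (peaks 07:00–09:00 and
  18:00–22:00). Splitting the exact mass — rather than giving every flush
  a fixed mass — keeps daily mass conservation exact while preserving the
  pulse heterogeneity that makes small catchments noisy. No quantitative
  flush model exists for these catchments, so this is a deliberately
  simple stand-in with its parameters exposed.
* **Noise and censoring.** Measurement error is multiplicative lognormal
  with mean 1 and coefficient of variation `noise_cv` (default 0.3);
  additive Gaussian noise was rejected because concentrations are
  positive and right-skewed. Values below the analyte's LOQ are censored
  exactly as a laboratory would report them.
* **Effluent.** The influent hourly load is shifted circularly by the
  hydraulic retention time (default 8 h, a small trickling-filter plant;
  circular because influent and effluent are sampled simultaneously over
  the same day), scaled by `1 − removal_fraction`, re-noised and
  re-censored.
* **River network.** Sites ordered downstream with nondecreasing upstream
  population receive the summed upstream per-capita excreted load after
  in-plant removal; the analyte is treated as conservative in the river
  (no decay, no sorption). One grab sample per site per day represents
  the day. The default network spans 5,000 to 2.3 million people with
  ~2,000 L of river flow per upstream capita per day.

Defaults describe a small catchment: population 6,230, 230 L/cap/d, and a
four-analyte roster (the antiviral metabolite at a pandemic-scale user
rate, a heavily used macrolide, a fully excreted antibiotic and a
well-removed decongestant) whose user counts scale with population at
plausible prescribing rates. Everything is seeded: identical seed and
config give byte-identical output.

What the generator does **not** emulate — rainfall and infiltration,
hydraulic routing and travel time between river sites, in-river decay,
within-day river dynamics, improper disposal, sorption to sediment —
bounds what passing tests prove: they validate the estimators against the
model's own assumptions, not against every failure mode of field data.

## Numerical choices and degenerate inputs

* Missing hours in a 24-h series are an error unless gaps are explicitly
  allowed, in which case the daily load is renormalised by the covered
  fraction of the day.
* A day whose influent is entirely censored has load 0 under the default
  policy; its percent loss against a quantified effluent is undefined and
  carried as a sentinel, rendered "<" in reports.
* The population–load regression is ordinary least squares and requires
  at least three quantified sites; below that every coefficient is `NA`.
* Display rounding (integer ng/L means, three significant figures for
  loads, integer percentages) lives only in the rendering layer;
  machine-readable outputs keep full precision, and re-parsing a rendered
  table reproduces exactly the rounded values.
* Problem sizes in the test-suite simulations — 24-h days, 8-site river
  networks, 50-replicate Monte-Carlo loops — are chosen so each property
  is measured stably in seconds on one CPU.

## Known limitations

The removal mass balance assumes drug use and retention time change
negligibly between the influent and effluent sampling days, so negative
"losses" can reflect timing as much as in-plant formation. Back-estimated
user counts inherit every upstream uncertainty — excretion fractions,
compliance, disposal, in-sewer degradation — and are most trustworthy for
a recalcitrant prodrug metabolite; for antibiotics the forward model is
known to over-predict measured loads. The grab-sample-per-day river
convention under-represents within-day variability at heavily impacted
sites.
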