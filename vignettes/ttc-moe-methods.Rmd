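---
title: "Methods: structure-based margin-of-exposure prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based margin-of-exposure prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models it implements, the
choices made where the design was genuinely open, and what the synthetic
test bed does and does not demonstrate.

## The prioritization model

The unit of decision is the margin of exposure, `MoE = PoD / E95`, where
`E95` (mg/kg-bw/d) is the upper 95% confidence bound on the median
population intake from a consensus exposure model, and the PoD is one of
three hazard surrogates expressed in the same units. MoE < 1 — strictly
less than; a margin of exactly one is not flagged — marks a chemical whose
estimated exposure reaches its hazard surrogate. Because all three PoD
routes share the same denominator for a given chemical (the newer SEEM3
estimate when available, SEEM2 otherwise), the comparison between routes
isolates the hazard side.

### Structure route: TTC assignment

Assignment is a pure function of the canonical structure, computed with
Open Babel's default aromaticity model (recorded in the run report, because
every SMARTS match depends on it). Salt and mixture inputs are expected to
be QSAR-ready; the classifier operates on the parsed graph as given.

Precedence is most-conservative-first:

1. **Genotoxic** (0.0025 ug/kg-bw/d), only when the genotoxicity filter is
   on and at least one structural alert matches. The alert table is a
   versioned CSV of named SMARTS patterns (`inst/extdata/genotox_alerts.csv`)
   covering the classic alert classes: nitroarenes, arylamines, N-nitroso
   compounds, epoxides/aziridines, azoarenes, hydrazines, activated alkyl
   halides, Michael acceptors, aromatic N-oxides and alkylating
   sulfonate/sulfate/phosphonate esters. It is a deliberate, documented
   subset of the full published mutagenicity rulebooks: each pattern is
   auditable and the table is user-replaceable, which we prefer over an
   unverifiable transcription of a larger rulebase.
2. **Anti-cholinesterase** (0.3 ug/kg-bw/d) when the structure is a
   carbamate ester (`N-C(=O)-O-C`) or an organophosphate ester (P double
   bonded to O *or S*, with at least one O/S-linked carbon arm).
   Thiophosphates count: pesticidal anti-cholinesterases are predominantly
   P=S esters, and including them is the conservative choice.
3. **Cramer class** I/II/III (30 / 9 / 1.5 ug/kg-bw/d) otherwise.

When a structure carries both a genotoxicity alert and an
anti-cholinesterase flag, the genotoxic value wins; no authoritative
tie-break exists for this case, and taking the lowest applicable threshold
is the conservative reading. Turning the filter off never changes the
assignment of alert-free chemicals (a tested invariant).

The Kroes-domain gate (organometallics: any metal/metalloid covalently
bonded to carbon; high-potency carcinogen classes: polyhalogenated
dibenzo-p-dioxin, dibenzofuran and biphenyl cores) is an annotation only.
Excluded chemicals still receive assignments and margins; screens that want
the stricter behavior can drop flagged rows themselves. Volatile chemicals
(boiling point < 260 C or vapor pressure > 0.1 mmHg) are likewise only
flagged: the oral-route TTC logic is a poor fit for them, but removal is
left to the caller.

### The Cramer classifier

`classify_cramer()` is a table-driven rendition of the original 33-question
oral-toxicity decision tree. Each node is a named structural predicate over
a fixed SMARTS battery plus three small canonical-SMILES lookup lists
(normal body constituents, common carbohydrates, common terpenes); leaves
are the classes I, II and III, and every parseable structure reaches
exactly one leaf. The classifier records the full trace of questions and
answers, and `cramer_answer()` re-evaluates any single question, so a trace
can be replayed and audited (a tested invariant).

Two honesty notes. First, the tree's exact published wiring has seen several
divergent software transcriptions; this implementation follows the published
question themes (endogenous substances; enhanced-toxicity groups; unusual
elements, with a salt-counterion escape; open-chain versus heterocyclic
versus carbocyclic branches; lactone, terpene, hydrolysable-ester, fused
aromatic and substituent-domain questions) with wiring chosen so that
well-characterized reference chemicals land in their accepted classes
(ethanol and toluene in I, allyl alcohol and saturated food lactones in II,
heteroaromatics, anilines, carbamates and polyphenols in III). Second, it is
validated against a curated exemplar panel (`template_panel()`), every
member of which was walked through the tree by hand before inclusion; no
claim is made of bit-parity with any third-party classifier binary.

### In vitro route: steady-state reverse dosimetry

The oral equivalent dose inverts a steady-state toxicokinetic model: a
continuous oral dose of 1 mg/kg-bw/d with 100% absorption produces

```
Css = (1/24) / ( GFR*fup + Q_l*fup*Clint_w / (Q_l + fup*Clint_w) )   [mg/L]
```

with renal clearance of the unbound fraction and restrictive, well-stirred
hepatic metabolism; `Clint_w = Clint * hepatocellularity * liver_mass *
60e-6` scales the hepatocyte measurement (uL/min/10^6 cells) to L/h/kg bw.
The blood/plasma ratio is assumed 1, so the plasma Css is compared directly
to the nominal in vitro AC50 (converted by `AC50 * MW / 1000` to mg/L). The
model deliberately omits gut metabolism, active transport and
non-restrictive binding; it is the standard screening-level form, not a
PBPK model.

Defaults (all configurable via `default_physiology()` or a YAML file):
GFR 0.1 L/h/kg bw, liver blood flow 1.45 L/h/kg bw, hepatocellularity
110e6 cells/g, liver mass 25.7 g/kg bw — reference-adult values — with 20%
CV on each physiological parameter and 30% on the measured `fup` and
`Clint`, lognormal, in a seeded Monte Carlo (default 1000 individuals; the
95th percentile of the resulting Css distribution feeds the OED). At zero
CVs the Monte Carlo collapses exactly to the closed form, which is the
anchor test for the sampler. Reported `fup` values of zero (assay
non-detects) would make Css infinite; they are floored at 0.005 with a
warning, mirroring common screening practice.

`OED = AC50_p5 / Css95` after unit conversion, so OED is linear in the AC50
percentile and in 1/Css — both tested properties, along with the renal-only
closed form `(1/24)/GFR` at `Clint = 0, fup = 1` and monotonicity of Css in
each clearance parameter.

### In vivo anchor: NOAEL percentile rule

NOAEL records are filtered to type "NOAEL", units "mg/kg-day", route "oral"
(case-insensitive, whitespace-trimmed — the normalization is a robustness
choice that does not change semantics; no deduplication is applied because
repeated identical NOAELs are legitimate independent records). With >= 20
values the PoD is the type-2 empirical 5th percentile; with fewer it is the
minimum. Chemicals with no conforming records are omitted from the NOAEL
MoE table with a log of their ids, never a crash.

### Quantile convention

One estimator serves every percentile in the package: the type-2 empirical
quantile (inverse CDF with averaging at discontinuities; with sorted values
and `j = floor(np)`, `g = np - j`, the result averages order statistics
`j, j+1` when `g = 0` and takes `j+1` otherwise, with a 1e-9 tolerance on
the integrality test to absorb floating-point `n*p`). The NOAEL rule
requires this convention; applying it also to the AC50 5th percentile, the
Css 95th percentile and all medians is a uniformity decision that makes
every reported percentile auditable by one rule.

## Comparison statistics

`compare_moe_tables()` restricts to common chemicals and reports strict
conservativeness fractions (ties count toward neither side, so the two
directed fractions sum to at most 1), squared Pearson correlation of log10
MoEs (identical to simple-regression R^2; chemicals with non-positive MoEs
are excluded with a logged count; zero variance yields NA with a warning),
type-2 median MoE ratios, and per-category two-sample tests: two-sided
Wilcoxon rank-sum (exact enumeration when both groups have <= 10
observations and no ties, otherwise normal approximation with continuity
and tie correction) and two-sample Kolmogorov-Smirnov via the standard
library implementations. One caveat worth knowing: at moderate equal group
sizes the KS statistic is discrete (multiples of 1/n), so the achievable
test size sits visibly below the nominal 5% — e.g. about 3.9% at n = 50 per
group — which is a property of the statistic, not an implementation error.

## The synthetic test bed

The generators exist so every pipeline stage can be exercised with known
truth and no external databases. Their defaults define the simulated study
conditions and were fixed once, up front:

* **Chemical libraries** sample from the curated exemplar panel (56
  structures across the five categories) with mix
  GENOTOXIC 0.10 / ANTICHOLINESTERASE 0.10 / CRAMER_I 0.25 / CRAMER_II 0.10
  / CRAMER_III 0.45 — Cramer III dominant, as in real environmental
  libraries. Panel members are sampled verbatim; structural perturbation is
  disabled by design because decoration can silently change a class.
* **AC50s**: lognormal, median 1 uM, logsd 1.5 (spanning the orders of
  magnitude of high-throughput screening potencies), 5-60 assays per
  chemical.
* **PK**: logit-normal `fup` centred near 0.1; lognormal `Clint` (median
  10 uL/min/10^6 cells) with a 10% point mass at zero for non-metabolized
  chemicals.
* **Exposures**: lognormal medians (median 1e-6 mg/kg-bw/d, logsd 2), a
  fixed upper95/median factor of 10, and 20% of chemicals labeled SEEM2. No
  published distributional form exists for consensus exposure estimates;
  these are pragmatic, wide-ranged choices.
* **NOAELs**: 1-40 records per chemical plus 20% decoy rows (wrong type,
  units or route) to exercise the filter. With `ttc_consistent = TRUE`, the
  generating lognormal of each chemical is anchored so its 5th percentile
  equals 100 x the chemical's truth TTC in mg/kg-d — the construction under
  which the TTC (a 5th-percentile-over-100 quantity by definition) should
  fall below the NOAEL-based PoD up to sampling noise. The package's
  headline property test runs this end to end on 500 chemicals with >= 20
  NOAELs each and the genotoxicity filter on (the setting in which "truth
  TTC" is well defined for every category) and requires the TTC PoD to
  undercut the NOAEL PoD for at least 95% of chemicals.

What passing these tests shows: the plumbing is correct, the classifier
recovers the panel truth exactly, the estimators implement their stated
definitions, and the conservativeness property holds *by construction* on
anchored data. What they do not show: real chemical libraries are vastly
more structurally diverse than a 56-exemplar panel; real NOAEL collections
are not lognormal and not anchored to TTC values; and real AC50/exposure
distributions carry assay- and pathway-level structure the generators do not
emulate. Conservativeness rates measured here are properties of the
synthetic construction, not field estimates.

## Problem sizes and runtime choices

Default test and example sizes — 500-chemical libraries for the
conservativeness property, 10^4 Monte Carlo individuals for Css
convergence checks, 10^4 null simulations for the test-size checks — were
chosen as the smallest sizes at which the checked quantities are stable to
well within their asserted tolerances on a single CPU.

## Known limitations

* The Cramer rendition is auditable but not authoritative; borderline
  structures (multifunctional acyclics, unusual heterocycles) may land
  differently than under other transcriptions of the tree.
* The genotoxicity alert table is a minimum covering set; absence of an
  alert is weak evidence of non-genotoxicity.
* The steady-state model ignores extrahepatic metabolism, transporters and
  blood/plasma partitioning; OEDs are screening quantities.
* Exposure estimates are inputs, not modeled; the package never attempts
  to fill gaps in them.
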