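---
title: "Combining a centered polygenic risk score with a clinical risk model to drive screening recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining a centered polygenic risk score with a clinical risk model to drive screening recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsscreen)
```

## The model

`prsscreen` implements the computational core of risk-based breast cancer
screening: every woman receives a 5-year absolute risk estimate built from a
clinical risk model and a polygenic risk score (PRS), and that estimate is
mapped through a threshold table to a screening recommendation (no
screening/stop, biennial mammography, annual mammography, or 6-monthly
screening alternating mammogram and MRI). Pathogenic-variant carriers bypass
the risk pathway and are screened per clinical guidelines.

### Centered multiplicative PRS

The PRS over a panel of $m$ SNPs with per-allele odds ratios $OR_j$ and
risk-allele dosages $g_j \in \{0,1,2\}$ is

$$\mathrm{PRS} = \prod_{j=1}^{m} \frac{OR_j^{\,g_j}}{\mu_j}, \qquad
\mu_j = (1-p_j)^2 + 2p_j(1-p_j)\,OR_j + p_j^2\,OR_j^2,$$

where $p_j$ is the risk-allele frequency in the woman's ancestry group and
$\mu_j$ is the Hardy–Weinberg population mean of $OR_j^{\,g_j}$. Because each
factor is divided by its own population mean and SNPs are treated as
independent, $E[\mathrm{PRS}] = 1$ exactly in a cancer-free population with
those allele frequencies — this is what lets the PRS act as a calibrated
relative-risk multiplier. The product is computed as a sum of logs; a test
asserts agreement with the per-SNP product to $10^{-10}$ relative tolerance.

Scores are tailored to four self-reported race/ethnicity groups (NH Asian/
Pacific Islander, NH Black, Hispanic of any race, NH White), with sparse
groups (Native American, other, mixed, unknown race) routed to NH White
parameters — GWAS data are too thin to fit separate scores there. An
unrecognized race label with non-Hispanic ethnicity is an error, never a
silent default.

Missing genotypes contribute a neutral factor of 1, and a participant whose
missing fraction exceeds `max_missing_fraction` (default 0) is flagged
non-scoreable rather than imputed: the design this emulates excluded
participants without the full panel rather than guessing genotypes.

### Clinical risk and the Bayesian combination

The clinical model is a configuration-driven analogue of the Breast Cancer
Surveillance Consortium (BCSC) v2 5-year risk model: a relative risk
multiplied over BI-RADS density, binary first-degree family history and
prior-biopsy pathology, applied to per-race baseline incidence hazards with
competing (non-breast-cancer death) mortality:

$$\mathrm{risk} = \sum_{t=0}^{4}
\frac{rr\,h_1(a+t)}{rr\,h_1(a+t)+h_2(a+t)}
\left[1-e^{-(rr\,h_1(a+t)+h_2(a+t))}\right]
e^{-\sum_{s<t}(rr\,h_1(a+s)+h_2(a+s))}.$$

This is the standard Gail-type cause-specific discretization on annual
intervals; it is validated in the test suite against a $10^6$-subject
simulation of the two-cause process. The shipped coefficient file
(`bcsc_coefficients_synthetic.yaml`) contains invented but plausible values
— baseline incidence rising from about 1.2/1000 at age 40 with a log-linear
slope of 0.045/year, competing mortality from 2/1000 with slope 0.07/year,
scaled per race stratum — because the published tables are external data;
they can be dropped into the same YAML structure without code change.
Family history is deliberately binary (any affected first-degree relative),
matching the model generation this reproduces.

The two estimates are combined on the odds scale: posterior odds equal prior
odds times the PRS,

$$\frac{q}{1-q} = \frac{p}{1-p}\cdot \mathrm{PRS}^{\alpha},\qquad \alpha = 1.$$

A PRS of exactly 1 leaves the clinical risk untouched; the update is
invertible and strictly monotone in both arguments. The exponent $\alpha$
exposes attenuated calibrations (for example to damp the PRS in the presence
of family history), but no attenuation and no PRS-by-family-history or
PRS-by-density interaction is applied by default — the combined model this
package mirrors did not include one.

### Screening policy

The threshold table partitions ages into bands and, within each band,
partitions risk $(0,1)$ into half-open lower-inclusive intervals; a
validator proves coverage and disjointness before any assignment runs, and
a risk sitting exactly on a cutoff resolves upward to the higher-intensity
rule (the table gives no other deterministic choice, and resolving upward
is the conservative one for screening). An extreme-density override can
escalate — never de-escalate — a recommendation to annual screening. The
shipped `thresholds_synthetic.yaml` is a placeholder with the policy's
structure: a risk-dependent start-screening rule at 40–49 and a
biennial-dominant 50–74 band whose annual cutoff lies above the typical
older woman's risk under the synthetic hazards.

## The analysis layer

`cross_tabulate()` builds the (clinical model) × (PRS-modified model)
contingency table of year-1 recommendations over non-carrier scoreable
participants; `discordance_percentage()` is its off-diagonal share and
`cell_reassignment_fraction()` the row-conditional percentage.
`mean_screens_per_woman_year()` converts a recommendation distribution into
screening encounters per woman-year (biennial = 0.5, annual = 1, 6-monthly
= 2) and reports the rounded reciprocal ("1 screen per N women/year").
Percentages are rounded half away from zero for reporting; unrounded values
are always returned alongside. `sankey_flows()` exports the nonzero
transitions for flow diagrams, conserving counts.

Group comparisons use Wilcoxon rank-sum (exact when both groups have at
most 25 untied observations) or Kruskal–Wallis; the monotone-trend test
across ordered categories (family-history extent, density) is
Jonckheere–Terpstra, enumerated exactly for total $n \le 8$ and otherwise
normally approximated with tie-corrected variance, with the all-tied
degenerate case defined as $p = 0.5$. The trend statistic had to be chosen
here — the analyses this reproduces name only "a test of trend" — and
Jonckheere–Terpstra is the standard rank test for ordered alternatives. No
multiple-testing correction is applied anywhere, matching the reproduced
analysis. Pearson correlation (as $r^2$) covers continuous pairs.

## The synthetic cohort generator

Because individual-level trial data are unreleased, the generator is the
package's study population. Its defaults are fixed at the reported baseline
composition: race/ethnicity mixture (78% NH White, 8.9% Hispanic, 4.8% NH
Asian/PI, 4.5% NH Black, 4.0% other/mixed/unknown, 0.2% NH AI/AN),
family-history strata (48/25/16/12% for none / second-degree only /
first-degree only / both), 3.1% pathogenic-variant carriage, density
mixture (4.7/35/40/8.7% for a–d plus 12% unknown), and ages 40–74 drawn
from a discretized scaled Beta(1.3, 1.9) giving median ≈ 53 and an IQR
near 45–62. Genotypes are Hardy–Weinberg draws from the participant's
group's allele frequencies; the fixture panel's odds ratios are log-normal
around 1 (sdlog 0.08) and frequencies Uniform(0.05, 0.95), which yields a
right-skewed PRS with SD ≈ 0.55, the scale reported for real panels of
this size.

Family-history extent and density are then drawn *conditional on the
realized PRS* through proportional-odds links on centered log-PRS
(`fh_prs_link = 0.6`, `density_prs_link = 0.3`). The slopes were chosen
once so that the mean-PRS gradient across family-history categories spans
roughly 1.00 → 1.13 (and a smaller density gradient), the direction and
magnitude reported for real cohorts; zero slopes give exact independence.
This is the minimal mechanism reproducing the observed associations — no
explicit relative/pedigree simulation is attempted, PRS-by-risk-factor
correlation with the clinical score emerges only through these links, and
breast cancer outcomes, screening adherence and genotyping error are not
simulated at all. Consequently, passing tests demonstrate the pipeline's
arithmetic and the direction of population-level effects, not the absolute
reassignment percentages of any real cohort, which depend on the joint
distribution of age, clinical risk and PRS in that cohort.

## Worked example

```{r example, eval = FALSE}
panel <- simulate_panel(120, seed = 7)
sim <- simulate_cohort(8000, panel = panel, seed = 11)
sc <- risk_screening(sim$cohort, sim$dosages, panel)
summary(sc)
```

On this synthetic population the PRS changes recommendations for a larger
share of the 40–49 stratum than the 50–74 stratum (the start-screening rule
at 40–49 is risk-dependent, so the PRS moves women across it), while
utilization stays near 1 screen per 2–3 women/year — the structural pattern
the pipeline is designed to expose.

## Numerical and design choices

- Quantiles (quintile cutpoints, IQRs) use linear interpolation between
  order statistics (`stats::quantile()` type 7), stated explicitly because
  the convention is otherwise ambiguous.
- PRS values are stored and compared on the natural scale (mean ≈ 1) and
  computed internally as sums of logs.
- Strand-ambiguous (A/T, C/G) panel SNPs are flagged by the VCF reader but
  scored by default; callers can exclude them.
- VCF matching is by rsid first, then chromosome/position plus allele pair.
- The per-group panel sizes of the emulated design ranged 118–126; the
  engine accepts any positive panel size, and 120 is used as the fixture
  size.
- Problem sizes in the test suite were chosen so statistical assertions are
  sharp at desk scale: 200,000 simulated women per group for the centering
  check (Monte-Carlo SE ≈ 0.0013, asserted within 3 SE of 1), $10^6$
  subjects for the competing-risk oracle, and 20,000 for gradient-recovery
  power.

## Known limitations

- The coefficient and threshold fixtures are synthetic placeholders; all
  absolute risks and assignment shares produced with them are illustrative,
  not clinical estimates.
- Genetic-ancestry inference, imputation, LD between panel SNPs, and
  multi-ancestry PRS methods are out of scope; ancestry routing follows
  self-report only.
- The Bayesian combination assumes the centered PRS is a valid
  likelihood-ratio multiplier independent of the clinical covariates;
  miscalibration in subgroups (for example from reference allele
  frequencies that do not transfer) propagates directly into posterior
  risks.
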