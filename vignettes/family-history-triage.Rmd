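---
title: "Family-history triage for Lynch syndrome and familial CRC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-history triage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhtriage)
library(dplyr)
```

## The clinical problem

Fifteen to twenty percent of colorectal cancers (CRC) arise on a familial
or hereditary background — mostly familial colorectal cancer (FCC), a
family-history-based diagnosis without a known genetic cause, and to a
smaller extent Lynch syndrome, the autosomal dominant mismatch-repair
(MMR) deficiency syndrome. Both matter clinically because recognizing
them triggers genetic counseling and colonoscopy screening or
surveillance for the patient and at-risk relatives. In routine practice
only a minority of eligible patients are referred, largely because the
referral criteria are detailed and the family history is rarely explored
to full depth.

`fhtriage` implements an automated triage of a structured family history
against the thirteen Dutch nationwide referral criteria, together with
the machinery needed to evaluate such a tool in a stepped-wedge cluster
trial: sample-size and design-effect calculations, a switching-schedule
builder, a synthetic cohort generator with a controllable intracluster
correlation, and the logit-linear fixed-effects analysis of the binary
primary outcome.

## The data model

A `family_history` is proband-centric and reaches exactly two kinship
degrees — the depth a self-administered questionnaire can cover reliably.
Kinship is encoded by relation codes (`parent`, `sibling`, `child`;
`grandparent`, `aunt_uncle`, `half_sibling`, `niece_nephew`,
`grandchild`) rather than a general pedigree graph: the degree is
derivable from the code alone and nothing in the criteria needs paths
longer than two meioses. Each relative carries a lineage. Second-degree
relatives must sit on one parental side (`maternal` / `paternal`);
the proband's own siblings and children are `direct` — genetically
related to both sides — and therefore satisfy a same-lineage constraint
with either side. A parent may be entered with a side (the mother *is*
the maternal line) or as `direct` when the questionnaire did not say.

Diagnoses carry a site from a closed vocabulary, a histology
(`carcinoma` / `adenoma`), an age at diagnosis, and a chronology
(`first`, `synchronous`, `metachronous`) relative to an earlier CRC of
the same person. Two conventions are load-bearing:

* "colorectal cancer" always means colorectal *carcinoma*; colorectal
  adenomas are recordable but never count toward any criterion;
* the Lynch-associated spectrum is carcinoma of the endometrium,
  stomach, small intestine, pancreas, bile ducts, renal pelvis, ureter,
  ovary or brain, plus carcinoma *or adenoma* of the sebaceous gland.

**Unknown ages.** The questionnaire cannot force respondents to know a
relative's age at diagnosis. The deployed tool's handling of missing
ages is not documented anywhere we could rely on, so the package makes
its own choice and applies it uniformly: an unknown age fails every
age-bounded condition, so no criterion ever fires on missing data.
`validate_history()` flags unknown ages at `"note"` severity so a caller
can prompt for completion; they are not validity errors.

## The thirteen criteria

Criteria 1–8 indicate a Lynch suspicion, 9–12 FCC, and 13 is a
discretionary referral when prior genetic testing is unclear. The
package reads the criteria literally, and three readings deserve
explanation because the source wording is compact:

* **Age bounds.** "< X" is strict; "50–70" is inclusive on both ends.
  Hence a diagnosis at exactly 70 satisfies 50–70 but not "< 70", and a
  diagnosis at 50 misses "< 50". The boundary suite pins all four edges
  (49/50 and 69/70/71).
* **Double counting.** A relative with more than one CRC or
  Lynch-associated tumor counts as *two* affected relatives — capped at
  two, however many tumors they had. Criteria that count affected
  relatives (4 and 8) sum these capped tallies; criteria that count
  *persons* with one qualifying diagnosis (9 and 10) do not double
  count.
* **"A person" vs "a patient".** Criteria 4, 9 and 10 apply to "a
  person": someone healthy, someone whose CRC or Lynch-spectrum tumors
  were all diagnosed over 70, or someone with only other cancer types at
  any age. This routes older-onset probands to the family-count criteria
  while probands with their own qualifying tumor under 70 go through
  criteria 5–8 and 11–12. Criterion 8's "all < 70" is applied to the
  proband's qualifying diagnosis as well as the relatives': the "person"
  definition routes over-70 probands to criterion 4, which implies the
  patient-facing criterion 8 addresses the under-70 case. That reading
  is ours; the source text does not spell it out.

Two further readings: criterion 2 (first-degree relative with CRC or
endometrial cancer under 50) holds irrespective of the proband's own
status, and endometrial cancer in relatives is not restricted by the
relative's recorded sex — the deployed tool's behavior on that point is
unknown, and restricting would silently drop referrals on data-entry
conventions. Criteria 9–12 count colorectal cancer only; the wider
Lynch spectrum enters only where the source attaches it (4, 6, 7, 8).

A history can match several criteria, and all matches are reported
(the evaluation trial tallied 97 matched criteria over 63 indicated
patients). The single recommendation field takes Lynch referral over FCC
referral, as the clinically stronger action; the discretionary
criterion 13 surfaces as `refer_other` only when nothing else matched.
The "grey referral area" — e.g. multiple relatives with CRC above 70 —
is deliberately *not* detected, matching the evaluated tool.

## The brute-force oracle

`oracle_evaluate()` re-answers every criterion by literal enumeration:
expand each relative into at most two countable units, loop over all
subsets of the required size, test pairwise lineage compatibility, loop
over diagnosis pairs for the synchronous/metachronous criteria. It
shares only the domain types with the engine — its site lists, degree
table and "person" predicate are restated independently — so a
transcription error in one implementation cannot hide in the other.
This mechanizes the verification protocol used for the deployed tool,
where 350 completed questionnaires were scored by hand and compared
with the automated recommendation until no discrepancy remained. The
test suite runs both implementations on 350 generated histories per
seed across three seeds (a cancer-enriched parameter set is mixed in so
the rare criteria are exercised) and requires zero disagreements.

## The synthetic cohort

`generate_history()` emulates a CRC outpatient cohort completing the
questionnaire: Poisson family sizes (means 4 first-degree and 5
second-degree relatives), independent per-relative lifetime risks of
CRC and of an extracolonic Lynch tumor, truncated-normal ages at
diagnosis, a proband whose CRC (probability 0.97, as in a CRC clinic)
is diagnosed at the current age drawn from a normal with mean 67 and SD
9.9 truncated to the observed range. No pedigree-level distributions
were reported for the evaluated cohort, so these are calibration
choices with one target: with default parameters about 27% of generated
completers meet at least one criterion, the indication rate observed in
practice. The per-relative CRC probability (0.058) was fixed once
against that target. The generator does **not** model Mendelian
transmission, penetrance, or correlated risks within families; passing
tests therefore show the rule logic and trial machinery are correct,
not that the generator is a demographic model of Dutch families.

`generate_trial_cohort()` layers the trial on top: the switching
schedule assigns each hospital-period cell a strategy, each cell
enrolls a fresh cross-sectional sample (default 26 patients, which
over 30 cells gives a cohort of 780, the scale of the real trial), and
the binary primary outcome follows a logistic model
$\mathrm{logit}\,p = \mathrm{logit}\,p_0 + \log(\mathrm{OR})\cdot z +
\beta_{period} + u_h$, with a hospital intercept $u_h \sim N(0,\sigma^2)$
and $\sigma^2 = \rho\,\pi^2/3\,/(1-\rho)$ so the latent-scale
intracluster correlation equals $\rho$. Tool-flow booleans (offered,
used, indicated, counseled) are drawn per the observed rates (58%, 81%,
27%, 59% / 4.8%) and describe process measures; the primary outcome is
generated from the marginal logistic model rather than through the flow
chain, a simplification that keeps the outcome model identifiable and
exactly matched to the analysis model it is used to validate. With
`with_histories = TRUE` the indication instead comes from evaluating a
generated history, tying the whole pipeline together at modest cost.

## Design math

`two_proportion_sample_size()` uses the normal approximation with
pooled variance under the null and unpooled under the alternative.
With the planning inputs (4% control referral rate, 15% anticipated,
two-sided $\alpha = 0.05$, 80% power) it returns 111 per strategy —
this specific variant reproduces the planning chain exactly, while
continuity-corrected or arcsine variants do not. The suite also checks
the formula against an *exact* power computation (full binomial
enumeration of the pooled z-test): the exact power at $n = 111$ is
0.836, comfortably above the target — the normal approximation is
conservative at these rates, so attainment, not equality of the search
result, is the asserted property.

`sw_design_effect()` implements the published stepped-wedge correction
factor
$$DE = \frac{1+\rho(ktn+bn-1)}{1+\rho(\frac12 ktn+bn-1)}
\cdot \frac{3(1-\rho)}{2t(k-1/k)}$$
for $k$ steps, $b$ baseline periods, $t$ measurement periods per step
and $n$ subjects per cluster-period. The factor is defined per
recruitment period: multiplying it by the number of periods $b+kt$
gives the equal-total-size GLS variance ratio of the stepped wedge
against an individually randomized parallel trial, and the test suite
verifies that identity against a direct GLS computation (exchangeable
cluster-period covariance, period fixed effects) to $10^{-10}$ across
a parameter grid. The published planning value of 0.45 (ICC 0.10) is
treated as a stated input to the 222 → 100 recruitment chain, not a
reproduction target: the cluster-period size behind it was never
reported (with $k=5$, $b=1$, $t=1$ the formula returns 0.45 at
$n \approx 15$, which is plausible but unverifiable).

## The analysis model

The primary analysis is the conventional one for a cross-sectional
stepped wedge: maximum-likelihood logistic regression of the outcome on
an intervention indicator plus hospital and calendar-period fixed
effects, dummy-coded against the first level. Period enters by calendar
period index; the alternative (time-since-switch) is not what the
evaluated trial adjusted for. `fit_logit_linear()` authors the fit
directly as iteratively reweighted least squares with a QR solve per
iteration, stopping when the largest absolute coefficient change drops
below $10^{-8}$ (at most 100 iterations); `glm()` serves as an
independent cross-check in the tests, never as the implementation.
Numerical choices: fitted probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ inside the weight computation; separation
(a fitted probability within $10^{-10}$ of 0 or 1 together with a
coefficient beyond 10 in absolute value) sets a `separation` flag on
the result instead of failing or silently reporting a Wald interval
that means nothing; single-level factors are dropped (a one-hospital
dataset reduces to intervention + period); any remaining rank
deficiency is an error naming the collinear columns.

The intervention effect is reported as a conditional odds ratio with a
two-sided 95% Wald interval, matching the reporting style of the
evaluated trial (conditional OR 0.76, 95% CI 0.29–2.00 — not itself
reproducible without the unpublished per-cell counts). Hospital and
period blocks get single p-values from likelihood-ratio tests against
the reduced model. `itt_analysis()` runs the intention-to-treat fit and
the sensitivity fit excluding histologically non-CRC lesions side by
side. The group-comparison helpers are deliberate about their variants:
the 2×2 chi-square carries no continuity correction and the exact test
is the Freeman–Halton conditional test, because those are the variants
that reproduce the published p-values (0.25, 0.89, 0.23; exact 0.64)
from the printed counts; the t-test is pooled, a choice the printed
values cannot discriminate. One printed value does not reproduce: the
tumor-location comparison prints p = 0.64 where the exact test on the
printed counts gives 0.31 — likely a transcription artifact in the
source table, and not used anywhere.

**Calibration evidence.** Simulating 500 trials at the true conditional
OR 0.76 and ICC 0.10 (five hospitals, 26 patients per cell), the Wald
interval covers the truth about 94% of the time; under no effect the
Wald test rejects at about 5% over 1000 simulations. Both checks run in
the acceptance suite at exactly these problem sizes, chosen so a single
simulated trial matches the real trial's scale (~780 patients) while
the whole calibration stays inexpensive.

## Serialization

Histories travel as versioned JSON (`schema_version` "1.0") with a
fixed field order, explicit empty arrays and `null` for unknown ages,
so equal histories serialize byte-identically; rosters travel as RFC
4180 CSV with histories inlined as compact JSON. Roster invariants
(unique patient ids; `used_tool` implies `offered_tool`; a history
present exactly when the tool was used) are enforced on both read and
write. Non-participation reasons use a small controlled vocabulary
(`not_interested`, `not_feeling_like_participating`, `other`) seeded
from the reasons patients actually gave.

## Known limitations

* Polyposis-syndrome referral criteria are out of scope, as they were
  for the evaluated tool; so are "grey area" referrals, risk
  probabilities, and treatment advice.
* The generator's independence assumptions understate within-family
  risk correlation; it is a test harness, not an epidemiological model.
* Only fixed-effects analysis is provided; random-effects or GEE
  stepped-wedge models are out of scope.
* The exact test is restricted to small tables (r·c ≤ 12); larger
  tables would need Monte-Carlo approximation, which is not
  implemented.
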