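---
title: "Methods: interference statistics for two-species tick surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interference statistics for two-species tick surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickRI)
```

## The scientific problem

*Amblyomma variegatum* and *A. hebraeum* are three-host ticks of cattle
whose ranges abut in south-east Africa. Both species use
attraction–aggregation–attachment pheromones (AAAPs) emitted by attached
males to find hosts and to cluster, and the pheromone blends are similar
enough that cross-species attraction, aggregation and mating occur. Since
hybrid eggs are inviable, cross-mating wastes reproductive effort in
proportion to the local frequency of the other species (satyrisation),
which can make established populations resistant to invasion and explain
parapatric range boundaries.

`tickRI` implements the statistical toolkit used to quantify these
interactions from field surveys of adult ticks on cattle: where ticks
attach, whether the species segregate or aggregate at three spatial
scales, how often females mate with the wrong species, and how
con-specific mating depends on the local composition of males and
females. A seeded synthetic-survey generator reproduces the hierarchical
structure these analyses assume, so every stage of the pipeline can be
exercised against known ground truth.

## Data model

One row per adult tick: site, animal, inspection mode (`laid_down` with
full detail, or `corridor` with species/sex only), species (`Av`/`Ah`),
sex, one of eight body regions, a cluster id (ticks within a 5 cm
radius), and — for females — the species of the mating partner or
`single`. A companion table records per-animal acaricide-treatment
history; `eligibility_filter()` drops animals treated with amitraz less
than 8 days or pyrethroids less than 15 days before the visit (the
residual-effect windows of those products).

One deliberate relaxation: laid-down rows may carry a missing
`cluster_id`, because field protocols record cluster structure on a
subset of animals only. Cluster-level analyses drop such rows with a
warning rather than refusing the file.

## Attachment-site overlap (Schoener's D)

For proportions \(p_i, q_i\) over the eight regions,
\(D = 1 - \tfrac12\sum_i |p_i - q_i|\). `overlap_heterospecific()`
compares the two species on co-infested, laid-down animals (\(D_H\));
`overlap_coinfestation()` compares one species on singly infested versus
co-infested animals (\(D_C\)). Both are reported per sex and per host
burden stratum (total adults \(< 30\), \([30, 70)\), \(\ge 70\)). No
smoothing is applied: zero-region proportions are exact zeros and the
index is well defined without pseudo-counts. Strata with fewer ticks than
`min_ticks_stratum` are flagged unavailable instead of being reported as
0 — an unavailable overlap and a zero overlap mean very different things.

## Co-occurrence (checkerboard C-score)

Presence matrices are binary units × groups incidence matrices at one of
three unit levels — host animal, attachment site (animal × body region),
or cluster — for the four species × sex groups. For a group pair
occupying \(r_i\) and \(r_j\) units and sharing \(S\), the normalized
Stone–Roberts score is \((r_i - S)(r_j - S) / (r_i r_j)\): 0 for complete
co-occurrence, 1 for complete segregation.

Three permutation null models are available. `fixed_fixed` (the default,
generated by vegan's quasiswap) preserves both unit richness and group
occupancy — the standard conservative choice for incidence data;
`fixed_rows` preserves group occupancy with units equiprobable;
`equiprobable_rows` only preserves total fill. Two-sided p-values use the
add-one rule \(p = 2\min(\#\{C^* \ge C\} + 1, \#\{C^* \le C\} + 1)/(n+1)\)
capped at 1, with ties counted toward the extreme tail.

Two methodological points discovered while validating the engine are
worth flagging:

* **`fixed_fixed` is structurally degenerate for two-group matrices.**
  With only two columns, preserving row sums pins each unit's richness,
  so the shared-unit count \(S\) — and hence the C-score — is identical
  in every permutation. Pairwise tests must therefore be run on the full
  four-group matrix (as `c_score_tests()` does), where the other groups
  provide the degrees of freedom. The engine detects degenerate nulls and
  reports \(p = 1\) with a warning rather than a spurious significance.
* Under `fixed_rows` with two groups, \(S\) is hypergeometric, which
  gives an exhaustive oracle used by the test-suite to validate the
  Monte-Carlo p-values.

Each group pair gets an independent child seed derived from the master
seed and the pair's label, so adding or removing pairs never perturbs
another pair's null stream.

## Sexual isolation on 2×2 mating tables

With observed pairs \(O_{ij}\) (male species i × female species j),
\(T = \sum O\), and expectations from random mating among mated
individuals \(E_{ij} = O_{i\cdot} O_{\cdot j} / T\):

* \(PSI_{ij} = O_{ij} / E_{ij}\);
* \(PTI_{ij} = O_{ij} / \hat E_{ij}\) with expectations from *all*
  sampled individuals (requires population totals, which surveys do not
  always provide);
* \(I_{PSI} = (PSI_{11} + PSI_{22} - PSI_{12} - PSI_{21}) / \sum PSI\),
  from −1 (fully hetero-specific) to 1 (complete isolation);
* \(IA_{PSI}\) = ratio of the larger to the smaller hetero-specific PSI.

Inference follows the JMating convention: 10,000 bootstrap replicates of
the pair distribution (multinomial over the four cells), standard errors
as the replicate standard deviation, and two-tail probabilities of
deviating from the null value (0 for \(I_{PSI}\), 1 for the others) by
the percentile-crossing rule with add-one correction, ties toward the
null. Replicates with an empty margin (where PSI is undefined) are
redrawn so the replicate count stays exact, and the number redrawn is
reported. Replicates with a zero hetero-specific PSI have infinite
\(IA_{PSI}\); they are excluded from its moments and counted.

**Point estimates: plug-in versus bootstrap mean.** The reference
JMating software reports *bootstrap means* as point estimates. For
near-linear indices the two agree closely, but for the ratio index
\(IA_{PSI}\) the bootstrap distribution is strongly right-skewed and the
bootstrap mean sits well above the plug-in ratio; the same effect shifts
a skewed hetero-specific PSI visibly in the second decimal. `tickRI`
reports both (`$psi`/`$ipsi`/`$iapsi` and `$boot_mean`). Because the
bootstrap expectation is a deterministic functional of the table,
`bootstrap_expectation()` also computes it *exactly* by enumerating all
\(\binom{T+3}{3}\) cell compositions with multinomial weights under the
same margin-validity rule — removing Monte-Carlo error entirely from
reported point estimates (feasible for \(T\) up to a few hundred; the
published tables have \(T \le 100\)).

A subtlety the test-suite documents: the bootstrap mean does *not*
converge to the plug-in estimate as replicates grow. It converges to the
bootstrap expectation, which differs from the plug-in value by a
second-order term of order \(1/T\) — that term is precisely why the
bootstrap-mean convention matters.

## Beta-binomial regression of con-specific mating

The observation unit is an (animal, mated-female-species) pair: `trials`
mated females, `successes` of them mated con-specifically. Published
descriptions of this model leave the unit ambiguous ("within-cattle
correlation" alongside a female-species effect); this choice keeps both
the correlation and the species effect definable. Covariates are the animal's proportions of con-specific males
and of con-specific females, centred on 0.5. The mean follows
\(\mathrm{logit}(\mu) = \beta_0 + \beta_1 \mathbb 1[\text{Ah}] +
\beta_m x_m + \beta_f x_f + \beta_{mf} x_m x_f\), and counts are
beta-binomial with intraclass correlation \(\rho\) (shapes
\(\mu(1-\rho)/\rho\), \((1-\mu)(1-\rho)/\rho\)), so \(\rho \to 0\)
recovers the binomial.

Numerical choices: optimization over \((\beta, \mathrm{logit}\,\rho)\)
keeps constraints interior (Nelder-Mead, then BFGS polish); covariance
from the observed information; the Wald test of \(\rho\) is computed on
the logit scale because the natural scale has a boundary at zero; fits
with all trials equal to 1 flag \(\rho\) as unidentifiable and fall back
to the binomial. Likelihood-ratio tests compare nested fits with
\(\chi^2\) degrees of freedom equal to the parameter difference. The
prediction surface evaluates \(\mu\) on a grid over
\([0,1]^2\) (101 × 101 by default) of the two uncentred proportions; its
coefficient of variation comes from 1000 parametric draws of the
coefficients from their asymptotic normal distribution.

## Herd-level detection probability

The exact formula used by the original study's supplementary method is
not published; the standard freedom-from-infection calculation is
implemented with the study's stated assumptions as defaults: design
prevalence 0.20, detection sensitivity 1 for laid-down and 0.6 for
corridor inspections, so
\(P = 1 - (1 - 0.2\,se_L)^{n_L} (1 - 0.2\,se_C)^{n_C}\),
classified "high" when strictly above 0.7. A finite-herd hypergeometric
variant (infested count \(\max(1, \mathrm{round}(pN))\), sampling
without replacement) is available when herd size is known and converges
to the binomial form for large herds.

## The synthetic world

`generate_survey()` draws, per animal: species burdens from a negative
binomial (defaults: means 6 and 3 adults with dispersion 1 — the low,
aggregated burdens of contact-zone sites, where co-infested animals
carried a handful of ticks each); sex with a 0.6 male fraction; male body
regions from per-species preference vectors placing >90% of mass on the
perineum/inguinal/axillary regions; male cluster membership by weighted
preferential attachment (`w_con`/`w_het` per resident male, `w_new` for
founding; `w_het = 0` strictly forbids joining hetero-male clusters);
female settlement by attraction to male clusters (`a_con`/`a_het`); and
partner choice among the males of the female's cluster with odds
`m_con : m_het` (6:1 by default, yielding cross-mating around the
10–15% observed where species are equi-abundant), with a 0.15
probability of remaining single. `generate_mating_counts()` bypasses the
mechanism and draws regression datasets from exact beta-binomial ground
truth (defaults \(\rho = 0.37\), strong male-proportion effect, negative
interaction) for recovery and calibration tests.

What the generator does **not** emulate: spatial landscape structure and
dispersal, seasonal phenology, acaricide dynamics, within-season
attachment/detachment turnover, and any satyrisation population
dynamics. A green pipeline test therefore establishes statistical
correctness of the estimators on data with the assumed hierarchical
structure — not ecological realism of any particular parameter value.

**A pooling caveat worth knowing.** Even with completely unbiased mate
choice (`m_con = m_het`, all weights equal), mating tables pooled over
hosts of *variable* species composition show positive isolation indices:
males and females on the same host share its composition, so
con-specific pairs are over-represented in the pooled table — a direct
analogue of the Wahlund effect. The null-calibration test therefore uses
hosts with high, weakly dispersed burdens (stable 50:50 composition).
Real surveys pooled across heterogeneous hosts inherit this bias, which
is one reason the within-host regression model complements the pooled
indices.

## Known limitations

* PTI requires population totals that published tables often lack; it is
  exercised on synthetic tables only.
* The C-score engine is pairwise; multi-group community metrics are out
  of scope.
* The exact bootstrap expectation enumerates compositions and is
  impractical for tables beyond a few hundred pairs (the Monte-Carlo
  bootstrap has no such limit).
* The beta-binomial model treats units as independent given the host
  covariates; site-level random effects are not modelled.
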