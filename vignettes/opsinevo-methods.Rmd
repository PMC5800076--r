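---
title: "Models and methods behind opsinevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind opsinevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`opsinevo` implements an analysis chain for testing whether a gene family's
molecular evolution carries the footprint of an ecological transition — its
motivating application being the "nocturnal bottleneck" question for the
mammalian opsins: did early mammals pass through a prolonged dim-light phase?
The chain has four stages: codon-level selection tests, omega-tree
construction and lineage scanning, ancestral reconstruction of
photic characters, and rule-based spectral-tuning classification. This
vignette documents the models, the tunable parameters, the numerical choices,
and what the bundled synthetic scenarios do and do not establish.

## Codon substitution model

Substitution between sense codons follows a Goldman–Yang-style model. For
codons $i \neq j$ differing at exactly one position,

$$
q_{ij} = \pi_j \cdot \kappa^{\,[\text{transition}]} \cdot
          \omega^{\,[\text{nonsynonymous}]},
$$

and $q_{ij} = 0$ for multi-nucleotide changes. Here $\kappa > 0$ is the
transition/transversion rate ratio, $\omega = dN/dS \ge 0$ measures selective
pressure on amino-acid change, and $\pi$ are stationary codon frequencies.
The genetic code is fixed to the universal code; the 61 sense codons are
ordered lexicographically over (A, C, G, T) with the three stops removed, and
this ordering is a documented, stable package contract.

Codon frequencies default to the F3x4 convention (products of
position-specific nucleotide frequencies estimated from the alignment,
renormalized over sense codons), with an empirical F61 option. Both floor
frequencies at $10^{-5}$ before renormalizing: a codon absent from a small
alignment must still carry positive stationary mass, otherwise the
reversible-generator similarity transform used for matrix exponentials
degenerates.

The generator is normalized so that one unit of branch length equals one
expected substitution per codon. For site-class mixtures the normalization is
computed **at the mixture** (a single common scale across classes), so class
likelihoods stay comparable; for branch-heterogeneous models every branch is
normalized at its own $\omega$, which makes the branch length itself the
expected substitutions per codon on that branch and keeps $dN/dS$ equal to
the branch's $\omega$ exactly in the per-branch bookkeeping.

## Site-class models and tests

The site models are the standard beta family:

* **M7**: $\omega \sim \mathrm{Beta}(p, q)$ on $(0,1)$, discretized into
  $K$ equal-probability classes represented by their conditional means
  (computed in closed form through the incomplete-beta identity, not by
  quadrature). $K = 10$ by default, configurable; the desk-scale test and
  acceptance runs use $K \in \{3, 4, 5\}$, stated with each run.
* **M8**: M7 plus an extra class of proportion $p_1$ with
  $\omega_s \ge 1$. The lower bound at 1 makes the M8a-vs-M8 comparison a
  boundary test.
* **M8a**: the extra class pinned at $\omega_s = 1$ (neutral).

Likelihoods are computed by Felsenstein pruning over the 61-state space
(compiled core), with per-message rescaling against underflow; missing codons
(gaps, ambiguities, in-frame stops) contribute partial likelihood one.
Likelihood-ratio tests use $2\Delta\ell$ against an upper-tail chi-squared;
degrees of freedom default to the free-parameter difference but can be pinned
(analyses of this design are conventionally reported with df = 1, including
comparisons where parameter counting says otherwise, so the override is
explicit rather than implicit).

Positively selected sites are identified by **naive empirical Bayes** at the
maximum-likelihood estimates: the posterior of the selected class is
$w_c L_c(\text{site})$ normalized over classes, flagged above 0.75. This is a
deliberate, documented simplification of the full Bayes empirical Bayes
machinery: NEB ignores parameter uncertainty, which matters for small
alignments, but the acceptance threshold and the decision rule are otherwise
identical.

Optimization is bounded quasi-Newton (`nlminb`) on the natural scale with
three seeded restarts by default (the first start is a fixed default point,
the rest are drawn from wide uniform/exponential ranges), convergence
tolerance $10^{-8}$ on the log-likelihood. Branch lengths are taken from the
input tree and a single global rate multiplier is optimized — full
branch-length optimization is out of scope, since the chain is designed
around a fixed species-tree topology with given lengths. Non-convergence
after all restarts is flagged on the result and warned about, never silent.

## Branch models, omega-trees and the lineage scan

Branch models (`one_ratio`, `two_ratio` with an explicit foreground set,
`free_ratios`) share the same machinery with one $\omega$ per branch group.
The free-ratios fit turns a gene tree into an **omega-tree**: the tree whose
branch values are the per-branch $dN/dS$ estimates. Because near-zero $dS$
makes ratio estimates explode, branches with $\omega > 10$ (strict
inequality; the cutoff is exposed as a parameter) are recalculated **once**
as $dN / \mathrm{median}(dS)$, the median taken over branches with positive
$dS$; the substitution is deliberately not iterated — it is a one-shot
robustness repair, not a fixed point scheme — and recalculated branches keep
their original estimates in a provenance table.

The **omega-lineage** of a species is the root-to-tip sum of branch
$\omega$ values. Lineages are standardized by $(x - \mathrm{median})/\mathrm{IQR}$
with type-7 (linear-interpolation) quartiles, so the worked example
$\{1,\dots,5\} \mapsto \{-1,-0.5,0,0.5,1\}$ is bit-reproducible. Tips with
|standardized score| above 1.5 — the box-plot whisker convention, chosen
because the source analysis reports "tendencies" without a numeric cutoff —
become candidates for the one-ratio vs two-ratio follow-up tests, which are
Bonferroni-corrected by the number of tests actually run (with an override to
pin published denominators such as 24 or 16 when replaying external data).
The linearization is known to dilute signal on internal branches; the scan
therefore targets terminal lineages, and internal-branch detection is an
explicit non-goal.

## Ancestral reconstruction on omega-trees

Discrete photic characters (activity pattern; violet- vs
ultraviolet-sensitive SWS1 pigments) are reconstructed with **Mk models**
(ER/SYM/ARD rate schemes) using the gene's omega-tree branch values as
evolutionary distance. That inherited modeling choice — distances measured in
selective-pressure units rather than time — is reproduced faithfully, not
endorsed: it makes ancestral inference sensitive to the quality of the
free-ratios estimates. Rates are optimized on the log scale; marginal state
probabilities come from the standard two-pass (postorder/preorder)
conditioning with a **flat root prior**, the least-informative reproducible
choice where the source is silent. SYM vs ARD is compared by LRT with df
defaulting to the parameter-count difference ($k(k-1)/2$), overridable to 1.

Continuous characters (orbit convergence in degrees, visual acuity in
cycles/degree) are reconstructed under **Brownian motion** via the
generalized-least-squares closed form: the root estimate is the GLS mean over
tips, interior estimates are conditional expectations, $\sigma^2$ is the
divide-by-$n$ maximum-likelihood estimator, and the reported SD combines the
conditional variance with the root-mean uncertainty. Constant tip values
degenerate gracefully ($\sigma^2 = 0$, SDs 0).

Before any continuous reconstruction is used, the trait is gated by
**Moran's I** on the gene's omega-tree with proximity weights
$w_{ij} = 1/d_{ij}$ (patristic omega-distance, zero diagonal, no row
normalization — a row-normalization flag exists for compatibility with
implementations that rescale internally). The statistic uses the
randomization-assumption variance (the Cliff–Ord moments with the sample
kurtosis) and a two-sided normal-approximation p-value; the gate threshold is
Bonferroni-corrected over the gene-by-trait comparisons actually made.
Surviving per-gene estimates are aggregated per node by unweighted mean and
**population** standard deviation (divide by $n$, documented because both
conventions are common), after excluding gene-node combinations whose clade
is represented by at most one sampled species.

The orbit-convergence/activity association uses a two-sided Wilcoxon
rank-sum test: exact enumeration when the combined sample is at most 20
without ties, otherwise the tie-corrected continuity-corrected normal
approximation.

## Spectral-tuning rules

Classification of SWS1 pigments uses the site-86 residue rule: F implies
ultraviolet-sensitive except in primates, where the rule is known to fail and
the record is deliberately left `unclassified` rather than guessed; Y, S, V,
C, L imply violet-sensitive; species with inactive SWS1 copies are excluded.
Site-93 residues are summarized as a residue-by-activity contingency table
(cathemeral and unknown records counted separately, never silently dropped)
with an optional concordance score against the literature residue sets
(T/S/A/M nocturnal-associated, P/V/C diurnal-associated) — reported as a
score, not hard-coded as a classifier, because the association is an
empirical observation rather than a mechanism. Reference numbering is
handled by a site map from alignment columns to non-gap positions of a
designated reference sequence.

## Synthetic scenarios: what they emulate, and what they do not

`simulate_study()` is the desk-scale end-to-end scenario: a 12-species
pure-birth tree rescaled to one expected substitution per codon root-to-tip,
and three 300-codon genes — one under strong purifying selection
($\omega = 0.1$) with a single foreground branch at $\omega = 3$ planted on
the longest terminal branch (a burst of adaptive substitutions must sit on a
branch long enough to register any substitutions at all; on a near-zero
branch the free-ratios estimate degenerates to a ratio of noise terms and
the omega-tree outlier repair collapses it),
one with a beta(0.5, 1.5) background plus a 15% site class at
$\omega_s = 4$, and one pure beta(0.8, 2) null. These sizes keep a full
pipeline run in minutes on one CPU while leaving the planted signals
comfortably detectable; they are properties of the scenario, fixed once.
Codon states are propagated by exact transition-probability sampling at
branch ends rather than event-level simulation — sufficient because nothing
downstream consumes within-branch event paths.

Traits evolve on the species tree: activity under a 3-state ARD chain rooted
nocturnal; the site-86 residue under a 2-state chain rooted
ultraviolet-sensitive; orbit convergence as Brownian motion (root 60°,
$\sigma^2 = 225$) plus a fixed ±20° activity effect emulating the
panoramic-vision/nocturnality association; log visual acuity as Brownian
motion (root $\log 5$, $\sigma^2 = 0.5$). `simulate_trait_study()` generates
the reconstruction stage's inputs at its natural scale (48 species), with
omega-trees drawn log-normally (median branch $\omega$ 0.15, sdlog 0.6)
around the species topology — emulating free-ratios estimates directly,
because joint codon fits at that many tips are a different computational
regime than the reconstruction stage needs.

What passing on these scenarios shows: the chain's operations are internally
consistent (oracle-verified), calibrated near nominal levels under their own
nulls, and able to recover planted parameters at realistic effect sizes.
What it does not show: robustness to alignment error, model misspecification
(e.g. synonymous rate variation, CpG effects), saturated divergences, or the
sampling structure of real 154-species data — none of which the generators
emulate.

## Numerical choices and limitations

* Transition probabilities for reversible codon generators use the
  symmetrized spectral decomposition; tiny negative entries from round-off
  are clipped to zero and logged when below $-10^{-12}$. Small Mk generators
  use a complex-safe eigendecomposition with a scaling-and-squaring fallback
  when the eigenvector basis is ill-conditioned.
* Per-site partial likelihoods are rescaled per internal message; per-class
  per-site log-likelihoods (the NEB input) retain their scalers exactly.
* Nested-fit LRTs clip small negative $2\Delta\ell$ (optimizer noise, up to
  $10^{-4}$) at zero and repair the ordering against the best nested
  optimum; larger inversions are an error, not a silent clamp.
* Polytomies are supported throughout the likelihood machinery; trees are
  used rooted as given and never re-rooted.
* The M8a/M8 comparison is a boundary test; comparing against
  $\chi^2_1$ is conservative (the measured type-I rate in the bundled null
  calibration is ~0.03 at nominal 0.05).
* Mk fits on omega-trees inherit all distortions of the omega estimates;
  near-zero branch $\omega$ collapses path distances and can make ancestral
  probabilities insensitive to parts of the topology.
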