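---
title: "Integrative species delimitation for whitefish radiations: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation for whitefish radiations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregonid)
```

Alpine lake whitefish (*Coregonus*) form young adaptive radiations in which
several endemic species per lake differ subtly in body proportions,
gill-raker counts and genetics. Delimiting such species requires combining
several weak but independent lines of evidence: size-corrected morphometric
ratios, meristic count distributions, microsatellite population structure,
and — where the question is whether a population predates human fish
stocking — sediment-core chronology. `coregonid` implements this toolkit
end to end, with synthetic-data generators standing in for museum
specimens so that every pipeline stage is testable without raw collections
data.

## Morphometric characters and standardization

The character registry holds 60 characters: 25 body, 19 head, 4 gill
(all in mm) and 12 meristic counts. Two published abbreviations collide
("LGR" is used both for the longest gill-raker length and the lower-arch
raker count), so the registry names the meristic count `LGRN` and the
combined count `totalGR`; all I/O resolves names case-insensitively.

Each measurement is taken twice; `qc_replicates()` accepts the mean when
the percent deviance $100\,|a-b| / \bar{x}$ is below 5, the working
threshold of careful calliper measurement, and otherwise flags the
character for re-measurement (after which the closest acceptable pair is
averaged). The deviance denominator is the mean of the two replicates — a
symmetric choice consistent with how average deviances are reported in
practice. What happens when the re-measured pair also fails is not
standardized anywhere; we return the flag and leave the decision to the
analyst rather than invent a rule.

For description tables, body characters are expressed as percentages of
standard length (SL) and head/gill characters as percentages of head
length (HL); meristic counts are never standardized and are summarised by
mode(s) and range rather than mean. Summaries flag `na` when no specimen
carries the character and a low-n flag when only one does; report output
is rounded to one decimal, internal values are not.

## Multivariate ratio analysis

Ratios of two measured characters are natural units for field taxonomy:
they are size-free under isometry and can be checked with callipers. The
ratio engine works in log space, where the ratio $x_i/x_j$ is the contrast
direction $e_i - e_j$.

For a two-group comparison, `lda_direction()` computes the Fisher
discriminant $w \propto S^{-1}(\mu_1 - \mu_2)$ with $S$ the pooled
within-group covariance of the log measurements. The separation of any
direction $d$ is its *standard distance*

$$D(d) = \frac{|d^\top(\mu_1 - \mu_2)|}{\sqrt{d^\top S d}},$$

the one-dimensional Mahalanobis-type distance along $d$.
`extract_best_ratios()` evaluates all $p(p-1)/2$ ratio contrasts
exhaustively and ranks them by $D$; the first- and second-best ratios may
share a character (published comparison tables do list such pairs), so the
second best is simply the second-highest $D$ rather than a
residual-projection construction. Each candidate is oriented so the
first-listed species has the larger mean ratio, and its per-group observed
ranges feed the overlap screen below.

The allometric content of the discriminant is summarised by

$$\delta = |\langle w, u \rangle|, \qquad u = (1, \dots, 1)/\sqrt{p},$$

the absolute cosine between the unit discriminant and the isometric size
axis: $\delta = 1$ means separation is carried purely by size, $\delta = 0$
means a pure shape contrast (coefficients summing to zero). The literature
behind this statistic gives it a specific derivation that is not restated
in the taxonomic sources we follow; we therefore adopt this operational
definition, keep it isolated in `delta_allometry()`, and do not claim
numeric parity with other software. Smaller $\delta$ still reads the same
way everywhere: less allometry behind the diagnosis.

When a comparison has more variables than specimens ($p > n_1 + n_2 - 2$),
the discriminant is not estimable. `select_subset()` either applies an
explicit published character preset verbatim or ranks characters by their
univariate standard distance and keeps the top $n_1 + n_2 - 2$. Whether
that heuristic matches any particular published subset choice is unknowable
without the raw data; explicit presets bypass the question. A numerically
singular $S$ receives a ridge $10^{-8}\,\mathrm{tr}(S)/p$ on the diagonal
— deterministic, scale-aware and negligible for well-conditioned input.

Because printed description tables round percentages to one decimal
(roughly 1 part in 200), bound checks against printed ranges use only
comfortably interior cases.

## Diagnostic screening and identification keys

A candidate ratio earns an asterisk — eligibility for keys and diagnoses —
when at most one specimen of one species falls inside the other species'
closed observed min–max range (`assess_overlap()`). Observed ranges rather
than density overlap are used because that is what printed range tables
support.

Identification keys are dichotomous couplet lists stored as YAML
(`read_key()`); the published key to the Lake Lucerne species ships as a
fixture. Intervals are closed on both ends; ratio quantities are computed
from mm values so that mm- and percent-based inputs agree; a specimen
falling in neither alternative is reported `undetermined` with the couplet
where traversal stopped — a normal outcome for real fish near printed
range boundaries, not an error. The key graph is validated acyclic, and a
species may be reachable by several paths (the Lucerne key reaches
*C. nobilis* twice, so the key must be followed completely).

Meristic frequency tables (species × count matrices) reproduce the
mode-in-bold diagnostics of published tables. Two published gill-raker
rows are internally inconsistent (the bolded cell does not match the
stated mode, or all counts are singletons); the reader keeps such rows but
flags them, and the shipped fixtures contain only internally consistent
rows.

## Microsatellite population genetics

Allele frequencies are per-population normalized counts over non-missing
alleles. The Hardy–Weinberg test uses the heterozygote-deficit index
$1 - H_o/H_e$ (with Nei's unbiased $H_e$) against a null generated by
re-pairing the population's allele pool, 1000 permutations by default, and
the add-one corrected two-sided p-value $(b+1)/(n+1)$. Pairwise
differentiation is Weir–Cockerham (1984) $\theta$, combining the a/b/c
variance components across loci and alleles as a ratio of sums, with a
permutation test shuffling individuals between the two populations. The
original analyses were run in Genodive, whose exact estimator variant and
HWE statistic are not fully specified in print; the conventions here are
stated so results are comparable, but exact numeric parity with that
software is not claimed.

Population distances are Cavalli-Sforza chord distances,
$D_{CH} = \frac{2\sqrt{2}}{\pi}\sqrt{\overline{f}}$ with
$f_l = 1 - \sum_a \sqrt{p_{Aa} p_{Ba}}$ per shared locus — zero for
identical frequencies, at most $2\sqrt{2}/\pi \approx 0.9003$. Trees are
Saitou–Nei neighbour joining, implemented here so that tie-breaking
(alphabetical by node label) and negative-branch handling (clamp to zero,
deficit moved to the sibling so the joined pair's path length is
preserved) are fully deterministic; `ape` provides the tree container and
newick I/O, and serves as an independent cross-check in the tests. Node
supports come from resampling loci with replacement and counting how often
each bipartition of the best tree recurs (1000 replicates by default).

## Cluster number: EM surrogate and the Evanno criterion

Bayesian admixture MCMC at the scale of the original analyses (hundreds of
thousands of sweeps) is out of scope. Instead, `fit_mixture_em()` fits a
no-admixture finite mixture — K clusters, each with its own per-locus
allele frequencies, genotype likelihoods under within-cluster
Hardy–Weinberg proportions — by EM with soft assignments. Repeated runs
from random starts produce a spread of converged log-likelihoods per K
that plays the role of the LnP(D) values of repeated MCMC runs; the
`evanno_deltaK()` calculator is agnostic about the trace source and reads
externally produced LnP(D) tables too.

The criterion itself: per interior K, with runs matched by index,

$$\Delta K = \frac{\operatorname{mean}_r\,|L_r(K{+}1) - 2L_r(K) + L_r(K{-}1)|}{\operatorname{sd}_r\,L_r(K)},$$

and the selected K is the interior argmax. A zero across-run standard
deviation makes the ratio undefined; that K is flagged and excluded with a
warning, and an exactly flat profile is reported as a tie. The criterion
can by construction never select a boundary K.

The denominator is doing real work here: it is the across-run variability
of a *noisy* likelihood estimate that penalises K values where the profile
is flat. A deterministic optimiser is a poor stand-in for that noise: runs
that always find the global optimum collapse the standard deviation to
numerical tolerance (the ratio explodes wherever the fit is most
reliable), while completely unguided runs occasionally miss a cluster at
the true K and inflate the deviation exactly where the criterion should
peak. The run protocol therefore does two things. First, each run hardens
its start with a few short random "bursts" (`n_bursts = 3` starts advanced
`burst_iter = 20` iterations, best continued to convergence — the em-EM
strategy), making catastrophic misses rare. Second, each run reports its
converged model's log-likelihood summed over an individual bootstrap
resample rather than the exact maximum (`resample = TRUE`), restoring a
noise floor that is comparable across K — the role MCMC noise plays in
LnP(D). With both in place the selection is driven by the curvature of the
likelihood profile, not by optimiser luck. The run design (`n_runs = 10`,
K = 1..7 around a four-cluster truth) mirrors the ten-runs-per-K protocol
of the original analyses.

## Synthetic data: what it emulates, what it does not

`simulate_morpho()` draws SL log-normally (default median 300 mm, log-sd
0.1 — adult whitefish) and each character as
$x = \exp(a + b\log SL + \varepsilon)$, $\varepsilon \sim N(0,
\sigma^2)$ with $\sigma = 0.03$ (~3% residual scatter, the order of
within-species variation left after measurement QC). The planted-ratio
generator (`planted_ratio_spec()`) moves one character pair's intercepts
apart by $\pm$`shift`$/2$ (default shift 0.2, a ~22% ratio contrast) on an
8-character panel with shared isometric slopes, so exactly one ratio is
strongly diagnostic. Its tighter default scatter ($\sigma = 0.012$) is
calibrated so the planted ratio's expected standard distance,
shift$/(\sigma\sqrt{2}) \approx 12$, matches the printed strength of the
published caudal-peduncle-depth / upper-jaw-width diagnostic it emulates
(standard distance 11.98) — published asterisked ratios range upward of
about 5.4 — and is consistent with the ~1.5% average replicate deviance
of careful calliper work. A contrast much weaker than that would not be
"diagnostic" in the asterisk sense this generator is meant to plant.
This emulates the size-and-shape structure the ratio analysis assumes; it
does not emulate measurement error correlation between characters,
missing-data patterns of damaged historical specimens, sexual dimorphism,
or age structure — so passing recovery tests demonstrate the machinery,
not robustness to those complications.

`simulate_genotypes()` uses the Balding–Nichols island model: ancestral
frequencies Dirichlet($\alpha$), deme frequencies Dirichlet centred on
them with concentration $(1-F)/F$, genotypes in within-deme HWE. Defaults
(4 demes, 60 diploids per deme, 10 loci, 8 alleles, $F = 0.15$) mirror a
four-cluster lake system genotyped at ten microsatellite loci with strong
but realistic differentiation — pairwise $\theta$ between independent
Balding–Nichols demes at $F = 0.15$ lands in the upper half of the 0.02-0.4
range reported for real whitefish species pairs. The model has no
mutation, linkage, or isolation-by-distance; admixed individuals are
first-generation mixtures only.

`simulate_meristics()` rounds a normal to integers with truncation at a
minimum bound — adequate for gill-raker-like counts, not for strongly
skewed or zero-inflated counts.

## Numerical and design choices

* Natural logs throughout the ratio engine; any fixed base gives the same
  distances and rankings.
* All stochastic operations take explicit seeds; derived child seeds stay
  below $2^{31}$. Permutation p-values always use the $(b+1)/(n+1)$
  correction.
* EM convergence is declared when the log-likelihood gain drops below
  `tol` (default $10^{-6}$; the cluster-number pipeline uses $10^{-4}$,
  coarse enough for speed and far below the tens-of-units differences the
  criterion consumes).
* Test and acceptance problem sizes are desk-scale by design: the
  cluster-number recovery uses 240 diploids at 10 loci with 10 runs for
  K = 1..7 over 10 replicate seeds; estimator-recovery checks use 2 demes
  of 100 diploids over 20 seeds; planted-ratio recovery uses 100 seeds of
  20 + 20 specimens. These sizes make the stochastic acceptance bounds
  (modal K, ±0.03 on $\theta$, ≥95% ratio recovery) comfortably stable.

## Known limitations

* $\delta$ is an operational definition (above); published $\delta$ values
  cannot be recomputed without the raw specimen data, so no conformance is
  claimed — only the documented interpretation (smaller = less allometry).
* Multi-group (>2 species) discriminants, PCA ratio spectra, AMOVA,
  linkage statistics and admixture-model MCMC are out of scope.
* The sediment age model is strictly linear in depth with a supplied
  reference year; compaction and radiometric modelling are inputs'
  responsibilities.
* GenePop support covers the 2/3-digit diploid dialect with `Pop`
  separators; haploid and extended dialects are not parsed.
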