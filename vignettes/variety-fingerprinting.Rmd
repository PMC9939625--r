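---
title: "SSR fingerprint databases for variety identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR fingerprint databases for variety identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrfp)
```

## The problem

Granting plant variety rights requires a distinctness (DUS) test: a
candidate variety must be shown distinct from every commonly known
variety. Morphological comparison is accurate but slow and
environment-sensitive, so registration offices maintain DNA fingerprint
databases — typically built on SSR (microsatellite) markers, which are
codominant, multiallelic and cheap to type — and use them to screen for
the most similar known varieties before any field trial. `ssrfp`
implements the full analysis layer of such a database for a diploid
crop: genotype I/O and allele calibration, per-locus diversity
statistics, pairwise discrimination assessment, core-marker and
multiplex-panel selection, population-structure inference, and
integration with coded morphological characteristics. The packaged
reference tables describe a 23-marker core panel for non-heading
Chinese cabbage (*Brassica campestris* ssp. *chinensis*, 10
chromosomes, fragment sizes 99–355 bp) characterized on a 423-variety
collection.

## Data model

A genotype is an unordered pair of allele labels per (variety, locus).
Labels are strings naming calibrated allelic bins rather than raw
fragment sizes, so a database is portable across instruments; each bin
keeps its numeric center as metadata, optionally with the reference
variety used to anchor it. Three conventions are enforced at
construction:

* pairs are canonicalized (sorted, numeric-aware), so `a/b` and `b/a`
  are one genotype and homozygotes carry the same label twice;
* a half-called genotype (one observed allele) is demoted to missing —
  conservative for distinctness claims, since a half call can neither
  confirm nor refute a difference;
* `0`, empty, `NA` and `.` all read as missing, and files are written
  as UTF-8 comma-separated text (a GenAlEx-style layout with two
  columns per locus, or a tidy long table).

Calibration assigns each raw size to the nearest bin center within a
tolerance (default half the repeat-motif length when known, else
1 bp). A size equidistant from two bins goes to the *lower* center,
deterministically, and the event is reported: reproducibility across
runs matters more than any claim about which bin is "really" right.
Sizes matching no bin open a new bin and are listed in a novel-allele
report rather than silently dropped.

## Per-locus statistics

For allele frequencies $p_a$ estimated from all typed copies:

* **MAF** is the frequency of the *most common* allele. The column
  name follows the published tables, which label it "minor allele
  frequency" while printing values up to 0.611 — the PowerMarker
  convention. The name is kept for fidelity and the meaning documented
  loudly here and in `?maf`.
* **He** is Nei gene diversity $1 - \sum_a p_a^2$, uncorrected by
  default because the reference tables were produced by GenAlEx, which
  does not apply the small-sample factor; `unbiased = TRUE` gives the
  $2n/(2n-1)$ variant.
* **PIC** is Botstein's
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, always $\le$ He.
* **Fst** per locus is Nei's $G_{ST} = (H_T - H_S)/H_T$ with $H_S$ the
  unweighted mean of subpopulation diversities and $H_T$ computed from
  unweighted mean frequencies — again the convention of the reference
  toolchain. For simulation recovery the package also provides
  Weir–Cockerham $\theta$: with only a few sampled demes $G_{ST}$ is
  biased low (for $K$ demes at differentiation $F$ its expectation is
  roughly $\frac{(1-1/K)F}{1-F/K}$, about 0.105 at $F=0.15$, $K=3$),
  whereas $\theta$'s variance-component construction is consistent for
  the model parameter. Recovery tests therefore use $\theta$.
* The morphological diversity index is Shannon–Wiener
  $H' = -\sum_i P_i \ln P_i$ over observed expression-state
  proportions (natural log).

The population partition behind any Fst is deliberately an explicit
argument: a variety collection offers several defensible partitions
(structure subgroups, cluster groups, regions) and the choice belongs
to the analyst, not to a hidden default.

## Distance, discrimination and distinctness

Two varieties are compared as populations of size one. Nei's (1972)
distance uses per-locus genotype frequency vectors (heterozygote
$\to$ 0.5/0.5, homozygote $\to$ 1), accumulates the identity sums
$J_{xy}, J_x, J_y$ over all co-typed loci *before* the ratio, and
returns $D = -\ln\!\big(J_{xy}/\sqrt{J_x J_y}\big)$. A pair sharing no
allele anywhere has $D = \infty$, capped at 10 (far beyond any
realistic value) so that clustering stays finite; the cap is reported.
The allele-difference count per locus is
$2 - |\text{multiset intersection}|$ of the two pairs; loci missing in
either variety are skipped, counting neither as same nor different.

The operational distinctness rule is a threshold on total allele
differences, default **2**: published confounded sets flag both
0-difference and 1-difference pairs as unresolved, implying that "two
or more" is the working definition of distinguished. The threshold is
configurable because crop guidelines differ. Pairs below threshold
form the edges of a graph whose connected components are the
undistinguished groups; the sub-threshold pair count $U$ feeds the
discrimination rate $(P-U)/P$ over $P = n(n-1)/2$ pairs, computed in
integer arithmetic before the division. With $n = 423$ and $U = 5$
this gives 99.994%.

UPGMA clustering uses unweighted average linkage with a deterministic
tie-break (among tied pairs, the one whose clusters contain the
lexicographically smallest leaf labels merges first). `$height` stores
merge distances; the exported Newick tree places nodes at half the
merge distance, making it ultrametric.

## Marker screening, core sets and multiplex panels

Screening filters candidates by missing rate and PIC (default bounds
0.2 and 0.5 — 0.5 being the conventional cutoff for "highly
polymorphic"); "stable and simple fluorescence peak", a judgment made
on electropherograms by eye in practice, is operationalized as a bound
on raw peaks per individual when a peak table is available. The audit
table records every failure with its reasons.

Core-set selection is formalized as greedy set cover over confounded
pairs: repeatedly add the marker resolving the most pairs still below
threshold (ties: higher PIC, then name), with partial credit for
markers that add differences to unresolved pairs without finishing
them. An iterative-deepening exact search is available for panels of
at most 20 markers; tests verify the greedy solution achieves the full
panel's discrimination and that the exact optimum is never larger.

Multiplex grouping assigns each marker a (group, dye) slot such that
same-slot size ranges are separated by at least a buffer (default
10 bp — the published five-group assignment keeps larger gaps).
First-fit-decreasing greedy packing is used, with an exhaustive
backtracking fallback for small panels; a validator independent of
both solvers checks every assignment. On the packaged 23 ranges with
4 dyes the greedy solver needs 3 groups, within the published 5.

## Population structure

The admixture model is the classic no-linkage Bayesian mixture: each
allele copy has a latent deme of origin drawn from the individual's
ancestry vector $q_i \sim \mathrm{Dirichlet}(\alpha)$, deme
frequencies carry symmetric Dirichlet priors, and a Gibbs sampler
(implemented in C++ for speed) alternates latent origins, frequencies
and ancestries. $\ln P(D)$ is estimated from the post-burn-in
log-likelihood trace as $\overline{\ln L} - \mathrm{var}(\ln L)/2$.
The correlated-frequency refinement is omitted: independent
frequencies suffice for model choice and assignment at the moderate
differentiation this workflow targets. Label switching across
replicate runs is resolved by greedy correlation matching of ancestry
columns.

Model choice reports two selectors side by side, because practice uses
both: the K maximizing mean $\ln P(D)$, and Evanno's
$\Delta K = \overline{|L(K{+}1) - 2L(K) + L(K{-}1)|}/\mathrm{sd}(L(K))$
maximized over interior K. Where replicate sd is zero $\Delta K$ is
undefined and excluded (an `sd_floor` can clamp instead). Under a flat
or linear $L(K)$, $\Delta K$ hovers near 2 — the expectation of
|second difference|/sd for pure replicate noise — so a maximum below
10 flags the choice as unreliable.

Default run lengths are desk-scale: 500 burn-in + 2,000 retained
sweeps, enough for the strong signal of marker panels selected for
discrimination; `structure_preset()` records the full-scale settings
(K = 1–10, 20 replicates, 5,000 + 50,000) used for real collections.

PCA operates on allele dosage (0/1/2 per observed allele, preserving
codominance rather than collapsing genotypes to one-hot), mean-imputes
missing dosages, and eigendecomposes the covariance of the centered
matrix. AMOVA partitions allele-level variation (0/1 mismatch per
copy) into among-population, among-individual-within-population and
within-individual strata by method-of-moments on per-locus sums of
squares; using only copies typed at each locus keeps the SS partition
exact under missingness. Negative components are clamped to zero and
the clamping recorded. Significance of $\Phi_{ST}$ comes from
permuting individuals among populations.

## Morphology integration

Coded characteristics (the packaged schema has 4 qualitative, 11
pseudo-qualitative and 15 quantitative characteristics with 1–9
codes) are one-hot encoded — the expressed state is 1, all others 0 —
and compared with the simple-matching coefficient, the "qualitative"
similarity conventional for such matrices; Jaccard and Dice are
available behind flags. Quantitative characteristics enter through
their codes like any other state, without interval scaling, exactly as
the 0/1 matrix methodology prescribes. The Mantel statistic is the
Pearson correlation of upper triangles with
$p = (1 + \#\{r_\text{perm} \ge r\})/(n_\text{perm}+1)$, permuting the
trait matrix (the direction is irrelevant to $r$; fixing it makes runs
reproducible). Because it is ambiguous whether a published
marker–morphology correlation is oriented on similarities or
distances, reports can print both orientations — they differ only in
sign.

## The synthetic-data generator

No genotype data ship with the reference tables, so every downstream
stage is validated on simulations from the F-model — the generative
model behind the admixture analysis itself, which makes parameter
recovery a meaningful test rather than a tautology. Ancestral
frequencies per locus are symmetric-Dirichlet; deme frequencies are
$\mathrm{Dirichlet}\!\big(p_\text{anc}(1-F)/F\big)$, so $F$ is the
expected differentiation; individuals draw two copies from their deme
(or via an individual ancestry vector when admixture is enabled); with
probability `selfing` the second copy duplicates the first; calls are
masked to missing at `missing_rate`. Bin centers are
`size_min + motif × index` along each marker's declared range (2 bp
motif when undeclared), with per-locus allele counts drawn from 5–40
truncated to what the range can hold.

Defaults are fixed once to emulate the reference collection: K = 3
demes, 423 varieties, 23 loci, $F = 0.13$ (the scale of the published
global differentiation), selfing 0.5 — chosen so the simulated
Ho/He deficit matches the published means (0.530 vs 0.726), with
inbred-line breeding as the biological cause, rather than genotyping
error — and 2% missing calls, a plausible figure for markers that were
themselves screened for low missingness. One profile per variety is
simulated, as a database stores one consensus profile even when DNA is
bulked from many plants.

What the generator does *not* emulate: stepwise mutation dynamics of
SSR repeats (frequencies are specified directly), linkage between
loci, genotyping error and null alleles, and the regional/market
substructure of a real collection. Passing recovery tests therefore
shows the estimators are correct for the model they assume, not that
real data meet those assumptions.

## Validation design and problem sizes

The test suite asserts closed forms exactly (PIC(0.5,0.5) = 0.375,
He(0.5,0.5) = 0.5, $H'$(uniform $k$) = $\ln k$, Nei D(identical) = 0),
checks PIC/He/allele differences/UPGMA/simple matching against
independent brute-force implementations to 1e−9 on 100+ random
instances, and uses simulation ground truth for the stochastic parts,
at sizes chosen to keep a full run at desk scale: Weir–Cockerham
recovery at $F = 0.15$ over 20 replicates of 150 varieties × 23 loci
(tolerance ±0.05 on the mean); Evanno model choice over K = 1–6 with
10 replicates per K (300 + 1,200 sweeps) in five independent study
replicates, requiring K* = 3 in at least 80% and mean assignment
accuracy ≥ 0.9; Mantel null calibration over 200 independent
trait–genotype pairs, requiring approximately uniform p-values. The
end-to-end demo simulates the full 423-variety, 23-locus collection
with five injected near-duplicates (three 0-difference, two
1-difference) and must flag exactly those five pairs, report 99.994%
discrimination, and select a core subset achieving the same
discrimination as the full panel.

## Known limitations

* Nei distance between single individuals is coarse (few distinct
  values per locus); it ranks similarity well but is not an estimate
  of divergence time.
* The greedy core-set is near-optimal, not optimal, beyond the exact
  solver's reach; the discrimination guarantee, not minimality, is the
  contract.
* $G_{ST}$-based per-locus Fst inherits the reference toolchain's
  biases; use the Weir–Cockerham option for estimation questions.
* The admixture sampler runs one chain per replicate; convergence at
  full scale should be judged across replicates (as the Evanno design
  already requires).
* AMOVA's permutation test permutes whole individuals only; no
  hierarchical (region/population) designs.
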