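---
title: "Tracing a hybrid crop lineage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing a hybrid crop lineage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixtrace)
```

## The problem

A cultivated population can carry a genome that is a mosaic of two
ancestries: most famously, the aromatic (Basmati-type) rice group of the
Indian subcontinent combines a domesticated japonica background with a
substantial fraction inherited from a local wild population. Establishing
such an origin from SNP data requires a chain of analyses, each simple on
its own but easy to get subtly wrong in combination:

1. merging genotype matrices called against the same reference but with
   inconsistent REF/ALT orientation;
2. selecting "typical" members of each named group on principal-component
   coordinates, because curated group labels always include intermediate
   and misassigned accessions;
3. classifying sites where the focal group's major allele is absent from
   the putative parent, and scoring every other individual for carriage of
   those alleles;
4. corroborating the nuclear signal with maternally inherited organellar
   haplotypes, summarized as a median-joining network;
5. painting the local ancestry of phased haplotypes with a copying model,
   and calibrating the genome-wide proportions with in-silico recombinants
   of known 50/50 ancestry.

`admixtrace` implements this chain end to end, together with a forward
simulator that generates data with the same statistical structure and
known truth, so every stage is testable without any external download.

## The copying model

The local-ancestry engine is a parsimony copying model. A query haplotype
on one chromosome is modelled as a mosaic of segments copied from the
union of two reference haplotype panels. For a copying path $k(1..T)$
through the templates, the cost is

$$\sum_t m\big(t, k(t)\big) \;+\; \lambda\,\#\{t : k(t) \ne k(t-1)\},$$

where the mismatch $m$ is 1 when the query and the copied template carry
different alleles and 0 when they agree, and $\lambda > 0$ is the switch
penalty. The minimum is found exactly by dynamic programming in
$O(TK)$ time; the per-site ancestry label is the panel that the optimal
path copies from. All template changes cost the same $\lambda$; only
between-panel changes alter the label. Tie-breaking is fixed (prefer the
incumbent template, then the lowest template index) so the output is
deterministic.

A single $\lambda$ trades false switches against swallowed short tracts,
so `paint_with_vote()` aggregates paintings over a small grid
($\lambda \in \{1.5, 2.5, 3.5, 4.5, 5.5\}$ by default) and takes the
per-site majority, with vote ties going to the first-listed (parent)
panel.

### Missing data: the expected-mismatch rule

The single most consequential numerical choice in the package is how the
mismatch treats missing alleles. Missing *query* alleles carry no
information and cost 0 against every template. For missing *template*
alleles there are two options:

* `missing_cost = "zero"`: a missing template allele is a free match.
  This looks conservative but is not: a panel with 50% missing data then
  matches any query at half of all sites for free, becomes the cheapest
  thing to copy from, and the painting *over*-assigns ancestry to the
  sparse panel. In our experiments this inflated the donor fraction from
  a true 0.37 to 0.70.
* `missing_cost = "expected"` (the default): a missing template allele is
  priced as a random draw from its own panel's allele frequency at that
  site, i.e. it costs $f$ against a query 0 and $1-f$ against a query 1,
  with $f$ the panel's alternate-allele frequency. A sparse panel is then
  neither free nor penalized, merely uninformative at its own diversity
  level.

Under the expected rule, the known depth asymmetry (a wild donor panel at
roughly 2x depth versus cultivated panels at 14x) produces a systematic
*under*-estimation of donor ancestry -- copying from the sparse donor
panel carries a small positive expected cost even inside true donor
tracts, so short tracts whose evidence does not clear the switch penalty
are swallowed by the dense parent panel. This is the direction reported
for real pipelines on such data, it is measurable, and it is exactly what
the recombinant calibration corrects.

### Calibration with in-silico recombinants

`make_recombinants()` pairs seven held-out diploids from each source and
splits every chromosome at its site-count midpoint, producing the two
complementary products per pair: 14 recombinant haplotypes whose true
ancestry is exactly 50/50 on every even-length chromosome. Painting them
with the same panels measures the estimator's bias under the data's
actual missingness structure;
`bias_factor = mean(true)/mean(inferred)` is a single multiplicative
correction (ratio of means, not mean of per-individual ratios), and
corrected per-individual fractions are capped at 1. The parents must be
held out of the panels: a parsimony painter copies an in-panel parent
verbatim and would measure no bias at all.

## The synthetic study

`simulate_study()` generates the complete study design. Its defaults are
the package's reference conditions; the methods and reasoning behind the
less obvious ones follow.

* **Sources.** Two populations diverge from a common ancestral frequency
  pool under a Balding-Nichols model: ancestral $q \sim U(0.05, 0.95)$,
  population frequency $\sim \mathrm{Beta}(q\theta, (1-q)\theta)$ with
  $\theta = (1-F)/F$ and $F = 0.3$. The expected Weir-Cockerham FST
  between the sources equals $F$.
* **Within-population haplotype structure.** Real populations have
  linkage disequilibrium: two accessions share long identical segments.
  Site-independent Bernoulli draws have none, and without LD a 30-haplotype
  panel cannot "cover" any query, which breaks the premise of a copying
  model. Each population is therefore built from a finite pool of 10 core
  haplotypes; individuals are core mosaics (junctions at 50 per Morgan)
  with a 1% per-site private-mutation rate. Per-site marginal frequencies
  remain exactly Balding-Nichols because the cores themselves are
  Bernoulli draws. The small pool also mirrors the strong homogeneity of
  predominantly selfing crops.
* **Map length.** Chromosomes are simulated at an *effective* genetic
  length of 0.2 Morgans. Rice is ~99% self-pollinating; crossovers in
  homozygous stretches leave no footprint, so the effective recombination
  that shapes ancestry tracts is an order of magnitude below the ~1.3
  Morgan map length. With the default `g = 50` generations this yields
  roughly 10 ancestry junctions per 500-site chromosome -- large,
  consistent blocks, which is what paintings of selfing crops look like.
* **The admixed lineage.** A single pulse contributes `alpha = 0.36` from
  the donor. The group is not a set of independent mosaics: it descends
  from 8 founder haplotypes resampled at that size for 10 generations
  (with recombination), then expanded to 34 sampled diploids. This
  founding bottleneck is essential, not decorative: with independent
  mosaics at $\alpha = 0.36$, no allele absent from the parent group can
  ever exceed 50% frequency in the admixed group, and the entire
  site-classification arm would have nothing to find. Drift in a small
  founding lineage is what pushes a minority of donor alleles above 50%,
  creating the strongly skewed within-group frequency spectrum that real
  domesticated groups show. Because genome-wide ancestry itself drifts
  under a bottleneck, the simulation is conditioned (rejection over
  founder draws) on a realized genome-wide truth fraction within 0.01 of
  `alpha`; a parameter-recovery experiment should measure estimator
  error, not generator drift.
* **Missingness.** Calls are masked independently per genotype at 0.5 in
  the wild donor group and 0.1 in the cultivated groups, emulating the
  2x vs 14x depth asymmetry. Both haplotypes of an individual are masked
  together, since missingness originates at the genotype level.
* **Organellar haplotypes.** Two cores differing at 8 diagnostic
  positions represent the deep maternal split between the donor lineage
  and the parent lineage; admixed individuals carry the donor type with
  probability 28/34, donor-population individuals with probability 0.82,
  and private mutations accrue at 0.05 per sequence -- slow, as
  chloroplast evolution is, and low enough that carriers are not split
  into singleton haplotypes at these sample sizes.
* **Outgroup.** A third population drawn from the same ancestral pool at
  the same $F$ plays the "related but wrong" reference group; it shares
  ancestral alleles with everyone but has no donor ancestry and never
  carries the donor organellar type.

What the generator does *not* model: genotype error and heterozygote
under-calling at low depth, LD-structured dropout, selection, explicit
demography beyond the bottleneck, and multi-allelic or indel variation.
Consequently a passing pipeline here shows algorithmic correctness and
the direction/magnitude of missingness-driven bias -- not robustness to
caller artifacts.

## Site classification and donor scoring

Group allele frequencies are computed from allele counts over non-missing
calls. A site enters the "absent" set when some allele exceeds 0.5
frequency in the focal group, the same allele is below 0.01 in the parent
group, and missingness is at most 1/3 in both groups (a heavily missing
"major variant" may in truth be a deletion). The "rare" set uses 0.05
with the same missingness rule and always contains the absent set.

Per-individual similarity is the proportion of classified sites at which
the individual carries the focal major allele. Two match rules are
provided: *presence* (at least one copy; robust when low-depth data
under-call heterozygotes) and *dosage* (dosage/2). The study pipeline
(`identify_donors()`) defaults to dosage because the simulator calls
heterozygotes perfectly; presence-mode compresses every group toward 1
and hides the donor/outgroup separation that dosage preserves. On real
low-depth data presence-mode is the safer choice, and it remains the
default of `similarity_scores()` itself.

`detect_elevated()` formalizes "a group of accessions with distinctly
higher proportions": sort the scores, find the largest gap at least
`min_gap = 0.05` wide that opens into the upper half of the score range
and leaves at least `min_group = 2` samples above it, and return the
samples above the gap midpoint. Scoring *all* non-focal individuals
(including the parent group, whose scores are near zero) anchors the
range so the upper-half rule has meaning. The explicit-threshold escape
hatch makes any published cut reproducible.

## The median-joining network

Organellar haplotypes are summarized with a median-joining network built
from complete variant profiles under Hamming distance. The implementation
iterates: (i) form the $\epsilon$-relaxed minimum spanning network (all
MST-equivalent links at $\epsilon = 0$); (ii) enumerate candidate median
vectors as column-wise majorities of triples around each link; (iii) add
the candidate that most reduces the spanning cost of the node set,
breaking ties lexicographically; stop when no candidate strictly reduces
cost, then prune degree-<=2 medians whose removal leaves the spanning
cost unchanged. Strict cost decrease guarantees termination and the
invariant that the final cost never exceeds the MST over observed
haplotypes. Missing entries are resolved before network construction:
samples join the most frequent compatible complete haplotype, and
unresolvable profiles are completed by column majority. All columns are
weighted equally; haplotypes are named `H01, H02, ...` by descending
membership.

## Numerical choices and degenerate inputs

* PCA mean-imputes missing calls with core-sample means, scales by
  $\sqrt{p(1-p)}$ (toggleable to plain centering), fixes axis signs by
  forcing the largest-magnitude loading positive, and aborts on
  zero-variance cores. Representative selection uses the sample SD
  (denominator $n-1$; a switch to the population SD is provided) with an
  inclusive boundary, so an axis with SD 0 keeps exactly the members at
  the median.
* Windowed statistics use non-overlapping, half-open windows
  `[start, start + window)` on 1-based coordinates. FST is the
  Weir-Cockerham (1984) two-population estimator aggregated as a ratio of
  sums; negative window values are reported as computed. Sites with a
  zero denominator are skipped, windows without usable sites are `NA`,
  and sites with fewer than two scored alleles contribute nothing to
  diversity.
* The missingness rule `<= 1/3` is compared with a `1e-9` tolerance so
  that a group of three with one missing call (a fraction of
  `1 - 2/3`) is not excluded by floating-point rounding.
* Merging rescues only exact and REF/ALT-swapped allele pairs; strand
  flips are deliberately not rescued because both inputs are assumed to
  be called against the same reference build.
* All generators take explicit integer seeds and are bit-reproducible;
  derived seeds stay far below $2^{31}$.

## Reference experiment sizes

The shipped tests and the acceptance script exercise the default study:
10 chromosomes x 500 sites, 30 + 30 reference haplotypes, 34 admixed
diploids, 20 outgroup diploids, missingness 0.5/0.1, seed 1. At these
sizes the full pipeline (simulation, two paintings, calibration, donor
identification) completes in a few minutes on one core. At the default
conditions the painting reaches ~0.95 site accuracy; the raw donor
fraction is under-estimated (~0.33 against a truth of ~0.36), the
recombinant-derived bias factor is ~1.06, and the corrected mean lands
within half a percentage point of the truth, with per-individual
corrected fractions spanning roughly 0.30-0.42. Donor identification
recovers 80% of the donor population at seed 1 with zero outgroup false
positives; across seeds the recovery fluctuates with the binomial
carriage of the donor organellar type (probability 0.82 per donor
individual), which bounds what any intersection-based rule can achieve.

## Known limitations

* The copying model is parsimony-based, not probabilistic: no genetic
  map, no mutation/emission model, no posterior uncertainty. This is a
  deliberate match to the class of tools it emulates.
* The bias factor is a single multiplicative constant estimated from
  half-chromosome recombinants; it transfers to shorter tracts only
  approximately, and the residual under-correction visible in the
  reference experiment (corrected ~0.35 for truth ~0.36) is the expected
  footprint of that approximation.
* The simulator's conditioning on the realized admixture fraction means
  its output is not an unconditional draw from the stated demographic
  model; for parameter-recovery testing that is a feature.
* Median-joining is a greedy heuristic here (as in the tools it mirrors);
  it guarantees cost bounds and determinism, not a provably minimal
  Steiner network.
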