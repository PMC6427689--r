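# admixtrace

Tools for tracing the hybrid origin of a crop population from genome-wide
SNP data, modelled on the population-genomic case of aromatic
(Basmati-type) rice: a cultivated group whose genome is a mosaic of a
domesticated *japonica* background and a wild donor lineage from the
Indian subcontinent.

The package covers the full chain of that style of analysis:

* **Matrix construction** — read GT-only VCFs, harmonize two call sets on
  the same reference (rescuing REF/ALT-swapped sites by flipping
  dosages), keep polymorphic sites scored in a required subset, and
  summarize the merged matrix (`read_genotypes()`, `harmonize_merge()`,
  `filter_polymorphic_with_subset_data()`, `descriptive_stats()`).
* **Representative selection** — PCA fitted on a dense core with
  projection of sparse samples, then the median ± 1 SD rule on the top
  axes to extract typical group members (`pca_fit_project()`,
  `select_representatives()`).
* **Allele-frequency evidence** — per-group frequencies, the joint allele
  frequency spectrum of two groups, classification of sites whose
  focal-group major allele is absent (<0.01) or rare (<=0.05) in the
  parent group, per-individual allele-sharing scores, and gap-based
  detection of the distinctly similar donor candidates
  (`group_frequencies()`, `joint_spectrum()`, `classify_sites()`,
  `similarity_scores()`, `detect_elevated()`, `allele_recovery()`).
* **Genome scans** — windowed nucleotide diversity and Weir–Cockerham
  FST as ratio-of-sums (`windowed_pi()`, `windowed_fst()`).
* **Organellar haplotypes** — frequency-filtered variant extraction from
  an alignment, haplotype collapsing, a deterministic median-joining
  network, per-group haplotype frequencies, and intersection of nuclear
  candidates with organellar carriers (`extract_variants()`,
  `collapse_haplotypes()`, `median_joining()`,
  `group_haplotype_freqs()`, `integrate_donor_set()`).
* **Local ancestry** — a switch-penalty copying-model dynamic program
  over two reference panels with a penalty-grid vote, in-silico
  recombinants of known 50/50 ancestry, multiplicative bias calibration,
  per-individual reports and per-gene ancestry calls
  (`paint_haplotype()`, `paint_haplotypes()`, `make_recombinants()`,
  `calibrate_bias()`, `ancestry_report()`, `locus_ancestry()`).
* **A forward simulator** with known truth — Balding–Nichols sources with
  realistic within-population haplotype sharing, a founding-bottleneck
  admixed lineage, depth-asymmetric missingness and maternally inherited
  organellar haplotypes (`sim_params()`, `simulate_sources()`,
  `simulate_admixed()`, `simulate_study()`).

The copying model minimizes, over copying paths *k(1..T)* through the
union of two haplotype panels,

    sum_t mismatch(t, k(t)) + lambda * #{t : k(t) != k(t-1)}

solved exactly by dynamic programming; the ancestry label at a site is
the panel the optimal path copies from. Missing template alleles are
priced at their expected mismatch under the panel's site frequency, so a
sparse panel is uninformative rather than artificially cheap — see the
vignette for why this choice controls the direction of the
missingness-driven bias that the recombinant calibration then corrects.

## Worked example

```r
library(admixtrace)

st <- simulate_study(sim_params(seed = 1))   # full synthetic study, known truth

## local ancestry with recombinant calibration
pnt <- paint_haplotypes(st$query_haps, st$panel0, st$panel1, st$sites)
rec <- make_recombinants(st$parents_a, st$parents_b, st$sites)
cal <- calibrate_bias(rec$truth_labels,
                      paint_haplotypes(rec$haps, st$panel0, st$panel1, st$sites))
cal
#> calibration_result: bias factor 1.065, site accuracy 0.965 (14 recombinants)

ancestry_report(pnt, cal$bias_factor)$group
#>   statistic       raw corrected
#> 1      mean 0.3266382 0.3478787
#> 2       min 0.2857000 0.3042784
#> 3       max 0.3901000 0.4154672

mean(st$truth_labels)    # simulated truth the report should recover
#> [1] 0.3532941

## donor identification from nuclear scores + organellar carriage
id <- identify_donors(st$genotypes, st$groups, st$chloroplast$alignment,
                      focal = "admixed", other = "japonica")
length(id$donor_set)
#> [1] 24
```

The report says: the raw painting under-estimates the donor fraction
(0.327 for a truth of 0.353), the 14 half-and-half recombinants measure
that bias as a factor 1.065, and the corrected mean (0.348) lands within
half a percentage point of the truth. The donor set recovers 24 of the
30 true donor-population members (the cap is the 0.82 organellar
carriage probability) with no false positives from the outgroup.

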