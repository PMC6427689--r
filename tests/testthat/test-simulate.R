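small_params <- function(...) {
  sim_params(n_chrom = 2L, n_sites = 200L, n_source0 = 10L, n_source1 = 10L,
             n_admixed = 6L, ...)
}

test_that("source simulation is reproducible and respects the model limits", {
  p <- small_params(seed = 7L)
  s1 <- simulate_sources(p)
  s2 <- simulate_sources(p)
  expect_identical(s1, s2)
  # near-zero differentiation: the two populations share frequencies
  p_low <- small_params(F_diff = 1e-4, seed = 3L)
  s_low <- simulate_sources(p_low)
  expect_lt(mean(abs(s_low$freqs$p0 - s_low$freqs$p1)), 0.01)
})

test_that("simulated differentiation matches Weir-Cockerham FST", {
  # structureless Bernoulli mode: the textbook Balding-Nichols setting
  p <- sim_params(n_chrom = 4L, n_sites = 2500L, F_diff = 0.5,
                  n_source0 = 30L, n_source1 = 30L,
                  n_core_haps = Inf, hap_mut = 0, seed = 5L)
  src <- simulate_sources(p)
  gm <- genotype_matrix(
    rbind(haps_to_genotypes(src$hap0, src$sites)$calls,
          haps_to_genotypes(src$hap1, src$sites)$calls),
    src$sites[, c("chrom", "pos", "ref", "alt")])
  fst <- windowed_fst(gm, grep("^P0_", sample_names(gm), value = TRUE),
                      grep("^P1_", sample_names(gm), value = TRUE),
                      window_bp = 40e6)
  genomewide <- sum(fst$value * fst$n_sites) / sum(fst$n_sites)
  expect_lt(abs(genomewide - 0.5), 0.05)
})

test_that("admixed mosaics carry consistent tract truth", {
  p <- small_params(seed = 2L, alpha = 0.36)
  src <- simulate_sources(p)
  adm <- simulate_admixed(src, p)
  # tracts tile each chromosome exactly
  for (h in unique(adm$truth$haplotype)) for (ch in unique(adm$truth$chrom)) {
    tr <- adm$truth[adm$truth$haplotype == h & adm$truth$chrom == ch, ]
    expect_equal(tr$start_m[1], 0)
    expect_equal(tr$end_m[nrow(tr)], p$chrom_morgans)
    if (nrow(tr) > 1)
      expect_equal(tr$start_m[-1], tr$end_m[-nrow(tr)])
  }
  # genome-wide fraction equals the length-weighted mean of tract labels
  fr <- truth_fractions(adm$truth)
  lab <- truth_site_labels(adm$truth, adm$sites)
  expect_equal(dim(lab), c(2L * p$n_admixed, nrow(adm$sites)))
  expect_lt(max(abs(fr$frac1 - rowMeans(lab))), 0.1) # site grid approximation
  # alpha = 1: every tract from source 1
  p1 <- small_params(seed = 2L, alpha = 1)
  adm1 <- simulate_admixed(simulate_sources(p1), p1)
  expect_true(all(adm1$truth$source == 1L))
  expect_equal(truth_fractions(adm1$truth)$frac1, rep(1, 2L * p1$n_admixed))
})

test_that("breakpoint counts follow the Poisson tract model", {
  p <- sim_params(n_chrom = 40L, n_sites = 20L, chrom_morgans = 1,
                  g = 1L, n_admixed = 10L, n_source0 = 5L, n_source1 = 5L,
                  seed = 9L)
  src <- simulate_sources(p)
  adm <- simulate_admixed(src, p)
  n_break <- with(adm$truth,
                  tapply(start_m, paste(haplotype, chrom), length)) - 1
  expect_lt(abs(mean(n_break) - 1), 0.15)  # g * L = 1 expected
})

test_that("missingness masking hits the requested per-group rates", {
  m <- gm_fix(matrix(0L, nrow = 20, ncol = 500))
  g <- group_map(sample_names(m), rep(c("wild", "dom"), each = 10))
  out <- apply_missingness(m, c(wild = 0.6, dom = 0.1), g, seed = 4L)
  miss <- rowMeans(is.na(out$calls))
  expect_lt(abs(mean(miss[1:10]) - 0.6), 0.02)
  expect_lt(abs(mean(miss[11:20]) - 0.1), 0.02)
  expect_identical(apply_missingness(m, 0, seed = 1L)$calls, m$calls)
  # haplotype masking removes both alleles of a genotype together
  haps <- matrix(1L, 4, 300,
                 dimnames = list(c("A_h1", "A_h2", "B_h1", "B_h2"), NULL))
  hm <- mask_haplotypes(haps, 0.5, seed = 2L)
  expect_identical(is.na(hm[1, ]), is.na(hm[2, ]))
  expect_lt(abs(mean(is.na(hm)) - 0.5), 0.06)
})

test_that("organellar haplotypes split into two divergent cores", {
  cp <- simulate_chloroplast(paste0("I", 1:300), 28 / 34, seed = 11L)
  expect_gte(length(cp$diagnostic_sites), 5L)
  expect_equal(sum(cp$cores["japonica", cp$diagnostic_sites] ==
                     cp$cores["donor", cp$diagnostic_sites]), 0L)
  # carrier fraction concentrates at the requested probability
  expect_lt(abs(mean(cp$labels == "donor") - 28 / 34), 0.06)
  cp0 <- simulate_chloroplast(paste0("I", 1:20), 0, mut_rate = 0,
                              seed = 1L)
  expect_true(all(cp0$labels == "japonica"))
  # no mutations: identical sequences within a type
  expect_equal(cp0$alignment[1, ], cp0$alignment[2, ])
})

test_that("the study scenario is reproducible and conditioned on alpha", {
  st1 <- default_study()
  expect_equal(n_samples(st1$genotypes), 30 + 30 + 20 + 34)
  expect_equal(sort(unique(st1$groups$group)),
               c("admixed", "japonica", "outgroup", "wild"))
  expect_equal(nrow(st1$panel0), 30L)
  expect_equal(nrow(st1$panel1), 30L)
  expect_equal(nrow(st1$parents_a), 14L)
  expect_lte(abs(mean(st1$truth_labels) - 0.36), 0.01)
  # per-group missingness ordering: sparse wild, dense cultivated
  miss <- tapply(rowMeans(is.na(st1$genotypes$calls)),
                 st1$groups$group[match(sample_names(st1$genotypes),
                                        st1$groups$sample)], mean)
  expect_gt(miss["wild"], 0.4)
  expect_lt(miss["admixed"], 0.2)
  st2 <- simulate_study(sim_params(seed = 1))
  expect_identical(st2$truth_labels, st1$truth_labels)
  expect_identical(st2$genotypes$calls, st1$genotypes$calls)
})
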