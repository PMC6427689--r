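test_that("group frequencies come from allele counts over non-missing calls", {
  calls <- rbind(A1 = c(0L, 2L, NA), A2 = c(1L, NA, NA))
  m <- gm_fix(calls)
  ft <- group_frequencies(m, group_map(c("A1", "A2"), c("g", "g")))
  expect_equal(unname(ft$freq[, "g"]), c(0.25, 1, NA))
  expect_equal(unname(ft$missing[, "g"]), c(0, 0.5, 1))
  expect_equal(unname(ft$n[, "g"]), c(2, 1, 0))
})

test_that("joint spectrum conserves sites and lands fixed sites in the corner", {
  calls <- rbind(F1 = c(2L, 2L), F2 = c(2L, 2L), O1 = c(2L, 2L))
  m <- gm_fix(calls)
  g <- group_map(c("F1", "F2", "O1"), c("f", "f", "o"))
  sp <- joint_spectrum(group_frequencies(m, g), "f", "o", n_bins = 10)
  expect_equal(sum(sp$counts), sp$n_sites)
  expect_equal(sp$counts[10, 10], 2L)      # both sites fixed-fixed
  expect_equal(sp$log10[10, 10], log10(3))
  # display transform: 99 sites in one bin -> 2.0, empty bin -> 0
  expect_equal(log10(99 + 1), 2)
  expect_equal(sp$log10[1, 1], 0)
})

test_that("joint spectrum counts every focal-major site exactly once", {
  set.seed(8)
  calls <- matrix(sample(c(0:2, NA), 20 * 60, replace = TRUE,
                         prob = c(0.3, 0.2, 0.4, 0.1)), nrow = 20)
  rownames(calls) <- paste0("S", 1:20)
  m <- gm_fix(calls)
  g <- group_map(sample_names(m), rep(c("f", "o"), each = 10))
  ft <- group_frequencies(m, g)
  sp <- joint_spectrum(ft, "f", "o")
  fm <- ft$freq[, "f"]
  manual <- sum(!is.na(fm) & pmax(fm, 1 - fm) > 0.5 & !is.na(ft$freq[, "o"]))
  expect_equal(sum(sp$counts), manual)
})

test_that("site classification applies the frequency and missingness rules", {
  # rows: focal group of 5, other group of 5
  mk <- function(f_calls, o_calls) {
    calls <- rbind(matrix(f_calls, nrow = 5), matrix(o_calls, nrow = 5))
    rownames(calls) <- c(paste0("F", 1:5), paste0("O", 1:5))
    gm_fix(calls)
  }
  # site 1: focal 0.6 / other 0 -> absent set
  # site 2: focal exactly 0.5 -> excluded (strict > 0.5)
  # site 3: focal 0.9 but focal missingness 0.4 -> excluded
  f_calls <- c(2, 2, 1, 1, 0,   2, 2, 1, 0, 0,   2, 2, 2, NA, NA)
  o_calls <- c(0, 0, 0, 0, 0,   0, 0, 0, 0, 0,   0, 0, 0, 0, 0)
  m <- mk(f_calls, o_calls)
  g <- group_map(sample_names(m), rep(c("f", "o"), each = 5))
  ft <- group_frequencies(m, g)
  ss <- classify_sites(ft, "f", "o", "absent")
  expect_equal(ss$pos, 100L)
  expect_true(ss$major_is_alt)
  expect_equal(ss$f_focal, 0.6)
  # absent set is nested in the rare set
  ssr <- classify_sites(ft, "f", "o", "rare")
  expect_true(all(paste(ss$chrom, ss$pos) %in% paste(ssr$chrom, ssr$pos)))
})

test_that("similarity scores follow the match rule and flag undefined targets", {
  calls <- rbind(F1 = c(2L, 2L, 2L, 2L), F2 = c(2L, 2L, 2L, 2L),
                 T1 = c(2L, 1L, 2L, 0L),   # 3 of 4 carry the allele
                 T2 = c(1L, 1L, 1L, 1L),   # het at every site
                 T3 = c(NA, NA, NA, NA))
  m <- gm_fix(calls)
  g <- group_map(c("F1", "F2"), c("f", "f"))
  gg <- group_map(sample_names(m), c("f", "f", "t", "t", "t"))
  ft <- group_frequencies(m, gg)
  ss <- classify_sites(ft, "f", "t", "rare", rare_thresh = 1)
  expect_equal(nrow(ss), 4L)
  sc <- similarity_scores(m, ss, targets = c("T1", "T2", "T3"))
  expect_equal(sc$proportion, c(0.75, 1, NA))
  scd <- similarity_scores(m, ss, targets = "T2", mode = "dosage")
  expect_equal(scd$proportion, 0.5)
  # a sample homozygous for the focal allele everywhere scores 1
  scf <- similarity_scores(m, ss, targets = "F1")
  expect_equal(scf$proportion, 1)
})

test_that("scores and site sets are invariant to ref/alt orientation", {
  set.seed(13)
  calls <- matrix(sample(c(0:2, NA), 16 * 80, replace = TRUE), nrow = 16)
  rownames(calls) <- paste0("S", 1:16)
  g <- group_map(paste0("S", 1:16), rep(c("f", "o"), each = 8))
  m1 <- gm_fix(calls)
  flip <- rep(c(TRUE, FALSE), length.out = 80)
  calls2 <- calls
  calls2[, flip] <- 2L - calls2[, flip]
  sites2 <- m1$sites
  sites2$ref[flip] <- "T"; sites2$alt[flip] <- "A"
  m2 <- genotype_matrix(calls2, sites2)
  ft1 <- group_frequencies(m1, g); ft2 <- group_frequencies(m2, g)
  s1 <- classify_sites(ft1, "f", "o", "rare")
  s2 <- classify_sites(ft2, "f", "o", "rare")
  expect_equal(paste(s1$chrom, s1$pos), paste(s2$chrom, s2$pos))
  if (nrow(s1) > 0) {
    sc1 <- similarity_scores(m1, s1)
    sc2 <- similarity_scores(m2, s2)
    expect_equal(sc1$proportion, sc2$proportion)
  }
  sp1 <- joint_spectrum(ft1, "f", "o")
  sp2 <- joint_spectrum(ft2, "f", "o")
  expect_equal(sp1$counts, sp2$counts)
})

test_that("elevated-score detection matches an exhaustive gap scan", {
  sc <- data.frame(sample = paste0("S", 1:5),
                   proportion = c(0.10, 0.11, 0.12, 0.80, 0.85))
  det <- detect_elevated(sc)
  expect_gt(det$threshold, 0.12)
  expect_lt(det$threshold, 0.80)
  expect_equal(sort(det$candidates), c("S4", "S5"))
  # oracle agreement on random score sets
  set.seed(31)
  for (i in 1:25) {
    v <- round(runif(sample(5:30, 1)), 3)
    scr <- data.frame(sample = seq_along(v), proportion = v)
    ora <- gap_oracle(v)
    det2 <- suppressWarnings(detect_elevated(scr))
    if (is.null(ora)) {
      expect_equal(length(det2$candidates), 0L)
    } else {
      expect_equal(det2$threshold, ora$thr)
    }
  }
  # equal scores: no gap, empty set with a warning
  eq <- data.frame(sample = 1:4, proportion = rep(0.4, 4))
  expect_warning(d0 <- detect_elevated(eq), "empty set")
  expect_equal(length(d0$candidates), 0L)
  # explicit threshold bypasses the scan
  dthr <- detect_elevated(sc, explicit_threshold = 0.5)
  expect_equal(sort(dthr$candidates), c("S4", "S5"))
})

test_that("allele recovery counts member alleles present in a query group", {
  calls <- rbind(F1 = c(2L, 2L), F2 = c(2L, 2L),
                 Q1 = c(2L, 0L), Q2 = c(1L, 0L),
                 O1 = c(0L, 0L), O2 = c(0L, 0L))
  m <- gm_fix(calls)
  g <- group_map(sample_names(m), c("f", "f", "q", "q", "o", "o"))
  ft <- group_frequencies(m, g)
  ss <- classify_sites(ft, "f", "o", "absent")
  expect_equal(nrow(ss), 2L)
  expect_equal(allele_recovery(ss, ft, "q"), 0.5)  # site 1 present, site 2 absent
  expect_equal(allele_recovery(ss, ft, "f"), 1)
  expect_equal(allele_recovery(ss, ft, "o"), 0)
})

test_that("donor-population members outscore an unrelated population", {
  st <- default_study()
  ft <- group_frequencies(st$genotypes, st$groups)
  ss <- classify_sites(ft, "admixed", "japonica", "absent")
  expect_gt(nrow(ss), 10)
  sc <- similarity_scores(
    st$genotypes, ss, mode = "dosage",
    targets = st$groups$sample[st$groups$group %in% c("wild", "outgroup")])
  grp <- st$groups$group[match(sc$sample, st$groups$sample)]
  expect_gt(min(sc$proportion[grp == "wild"]),
            max(sc$proportion[grp == "outgroup"]))
  # recovery of the distinguishing alleles is highest in the donor group
  expect_gt(allele_recovery(ss, ft, "wild"),
            allele_recovery(ss, ft, "outgroup"))
})
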