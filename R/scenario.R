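#' Simulate a complete two-source admixture study
#'
#' Generates every input the tracing pipeline consumes, with known truth:
#' two Balding-Nichols source populations ("japonica"-like source 0 with
#' dense data, "wild" donor source 1 with sparse data), an admixed group
#' descended from a small founder pool formed by a single admixture pulse,
#' an unrelated outgroup population, depth-asymmetric missingness, and
#' maternally inherited organellar haplotypes correlated with nuclear
#' ancestry.
#'
#' The admixed group descends from a small founding lineage rather than
#' being a set of independent mosaics: `n_founder_haps` founder haplotypes
#' are laid down as admixture mosaics at the tract scale implied by `g`,
#' the lineage is then resampled at that same small size for
#' `n_bottleneck` generations (with recombination at the effective map
#' length), and the sampled individuals are drawn from the resulting pool.
#' The bottleneck drifts local ancestry frequencies, which is what pushes
#' donor alleles above 50% within the group -- the skewed spectrum the
#' site classification relies on -- and reproduces the highly consistent
#' ancestry blocks of a predominantly selfing crop. Because genome-wide
#' ancestry itself drifts under such a bottleneck, the realization is
#' conditioned (by rejection over founder draws) to have a genome-wide
#' truth fraction within `cond_tol` of `alpha`, so that parameter-recovery
#' experiments measure estimator error, not generator drift.
#'
#' @param p A [sim_params()]; `n_admixed` is the number of sampled admixed
#'   individuals.
#' @param n_outgroup Diploid individuals in the unrelated outgroup.
#' @param n_founder_haps Haplotypes in the admixed founding lineage.
#' @param n_bottleneck Generations of resampling at the founding size.
#' @param cond_tol Tolerance for conditioning the realized genome-wide
#'   truth fraction on `alpha`.
#' @param n_parents Held-out diploids per source used as recombinant
#'   parents (excluded from the reference panels).
#' @param panel_inds Diploids per source forming the reference panels
#'   (`2 * panel_inds` haplotypes each).
#' @param cp_probs Named probabilities of carrying the donor-type
#'   organellar haplotype, per group.
#' @return A list with components `params`, `sites`, `groups` (a
#'   `group_map` with labels japonica / wild / outgroup / admixed),
#'   `genotypes` (combined [genotype_matrix()] after missingness),
#'   `panel0`, `panel1` (masked reference haplotypes), `parents_a`,
#'   `parents_b` (masked held-out parents), `query_haps` (masked admixed
#'   haplotypes), `truth_labels` (0/1 per admixed haplotype and site),
#'   `founder_truth` (tract table of the founder haplotypes),
#'   `chloroplast` (alignment + type labels).
#' @export
simulate_study <- function(p = sim_params(), n_outgroup = 20L,
                           n_founder_haps = 8L, n_bottleneck = 10L,
                           cond_tol = 0.01, n_parents = 7L,
                           panel_inds = 15L,
                           cp_probs = c(admixed = 28 / 34, wild = 0.82,
                                        japonica = 0, outgroup = 0)) {
  if (p$n_source0 < panel_inds + n_parents ||
      p$n_source1 < panel_inds + n_parents)
    stop("source populations too small for panels plus held-out parents")
  src <- simulate_sources(p)
  sites <- src$sites

  bl <- admixed_bottleneck(src, p, n_founder_haps, n_bottleneck, cond_tol)
  adm <- bl$haps
  truth <- bl$labs
  adm_names <- paste0(rep(paste0("ADM", seq_len(p$n_admixed)), each = 2),
                      "_h", rep(1:2, p$n_admixed))
  rownames(adm) <- adm_names
  rownames(truth) <- adm_names

  # unrelated outgroup from the same ancestral pool
  set.seed(p$seed + 2L)
  shape <- (1 - p$F_diff) / p$F_diff
  q <- src$freqs$anc
  p_out <- stats::rbeta(length(q), q * shape, (1 - q) * shape)
  out_haps <- draw_pop_haps(p_out, n_outgroup, "OUT", p, sites)

  # depth-asymmetric masking (per genotype, both haplotypes together)
  h0 <- mask_haplotypes(src$hap0, p$miss0, seed = p$seed + 4L)
  h1 <- mask_haplotypes(src$hap1, p$miss1, seed = p$seed + 5L)
  ho <- mask_haplotypes(out_haps, p$miss0, seed = p$seed + 6L)
  ha <- mask_haplotypes(adm, p$miss_adm, seed = p$seed + 7L)

  panel_rows <- seq_len(2L * panel_inds)
  parent_rows <- 2L * panel_inds + seq_len(2L * n_parents)
  site_cols <- sites[, c("chrom", "pos", "ref", "alt")]
  gm <- genotype_matrix(
    rbind(haps_to_genotypes(h0, site_cols)$calls,
          haps_to_genotypes(h1, site_cols)$calls,
          haps_to_genotypes(ho, site_cols)$calls,
          haps_to_genotypes(ha, site_cols)$calls),
    site_cols)
  groups <- group_map(
    sample_names(gm),
    c(rep("japonica", p$n_source0), rep("wild", p$n_source1),
      rep("outgroup", n_outgroup), rep("admixed", p$n_admixed)))

  # maternally inherited organellar haplotypes
  inds <- sample_names(gm)
  grp <- groups$group[match(inds, groups$sample)]
  cp <- simulate_chloroplast(inds, unname(cp_probs[grp]),
                             seed = p$seed + 8L)

  list(params = p, sites = sites, groups = groups, genotypes = gm,
       panel0 = h0[panel_rows, , drop = FALSE],
       panel1 = h1[panel_rows, , drop = FALSE],
       parents_a = h0[parent_rows, , drop = FALSE],
       parents_b = h1[parent_rows, , drop = FALSE],
       query_haps = ha, truth_labels = truth,
       founder_truth = bl$founder_truth,
       source_freqs = src$freqs,
       chloroplast = cp)
}

# One meiosis between pool haplotypes a and b: crossovers are Poisson
# (chrom_morgans) per chromosome, phase randomized.
recombine_rows <- function(haps, labs, a, b, sites, ix_by_ch, chrom_morgans) {
  h <- haps[a, ]; l <- labs[a, ]
  for (k in seq_along(ix_by_ch)) {
    ix <- ix_by_ch[[k]]
    nbr <- stats::rpois(1L, chrom_morgans)
    brk <- sort(stats::runif(nbr, 0, chrom_morgans))
    seg <- findInterval(sites$gpos[ix], brk) + stats::rbinom(1L, 1L, 0.5)
    use_b <- seg %% 2L == 1L
    h[ix[use_b]] <- haps[b, ix[use_b]]
    l[ix[use_b]] <- labs[b, ix[use_b]]
  }
  list(h = h, l = l)
}

# Founding-bottleneck admixed lineage: mosaic founders at tract scale g,
# n_bottleneck generations of resampling at constant size n_founder_haps,
# then 2 * n_admixed sampled haplotypes; the whole draw is rejected until
# the genome-wide truth fraction is within cond_tol of alpha.
admixed_bottleneck <- function(src, p, n_founder_haps = 8L,
                               n_bottleneck = 6L, cond_tol = 0.01,
                               max_try = 500L) {
  stopifnot(n_founder_haps %% 2L == 0L, n_founder_haps >= 4L)
  sites <- src$sites
  ix_by_ch <- lapply(unique(sites$chrom),
                     function(ch) which(sites$chrom == ch))
  pf <- p
  pf$n_admixed <- as.integer(n_founder_haps / 2L)
  for (try in seq_len(max_try)) {
    pf$seed <- p$seed + 1000L * try
    fnd <- simulate_admixed(src, pf,
                            ids = paste0("FND", seq_len(pf$n_admixed)))
    haps <- fnd$haps
    labs <- truth_site_labels(fnd$truth, sites)
    set.seed(p$seed + 3L + try)
    for (t in seq_len(n_bottleneck)) {
      nh <- haps; nl <- labs
      for (i in seq_len(n_founder_haps)) {
        ab <- sample.int(n_founder_haps, 2L)
        m <- recombine_rows(haps, labs, ab[1], ab[2], sites, ix_by_ch,
                            p$chrom_morgans)
        nh[i, ] <- m$h; nl[i, ] <- m$l
      }
      haps <- nh; labs <- nl
    }
    sh <- matrix(NA_integer_, 2L * p$n_admixed, nrow(sites))
    sl <- matrix(NA_integer_, 2L * p$n_admixed, nrow(sites))
    for (i in seq_len(2L * p$n_admixed)) {
      ab <- sample.int(n_founder_haps, 2L)
      m <- recombine_rows(haps, labs, ab[1], ab[2], sites, ix_by_ch,
                          p$chrom_morgans)
      sh[i, ] <- m$h; sl[i, ] <- m$l
    }
    if (abs(mean(sl) - p$alpha) <= cond_tol)
      return(list(haps = sh, labs = sl, founder_truth = fnd$truth,
                  n_tries = try))
  }
  stop("could not condition the admixed lineage on alpha within ",
       max_try, " founder draws")
}

#' Identify donor-population candidates from nuclear and organellar evidence
#'
#' Runs the donor-identification arm of the pipeline on a simulated or real
#' data set: classify sites whose focal-group major allele is absent from
#' the reference parent group, score target individuals for carriage of
#' those alleles, detect the distinctly elevated cluster, and intersect it
#' with carriers of the focal organellar haplotypes (haplotypes present in
#' the focal group but absent from the parent group).
#'
#' @param m A [genotype_matrix()].
#' @param groups A `group_map`.
#' @param cp_alignment Organellar alignment (character matrix).
#' @param focal Focal (admixed) group label.
#' @param other Parent group label whose alleles define "absent".
#' @param targets Samples to score (default: every sample outside the
#'   focal group -- scoring the parent group too anchors the low end of
#'   the score distribution, as scoring every individual of every
#'   reference group did in the source study).
#' @param mode Match rule for [similarity_scores()]; the default
#'   `"dosage"` uses both alleles of each called genotype, appropriate
#'   when heterozygotes are reliably called.
#' @param min_freq Organellar variant frequency threshold.
#' @param ... Passed to [classify_sites()].
#' @return List: `site_set`, `scores`, `detection`, `haplotypes`
#'   (collapse result), `focal_haplotypes`, `donor_set`.
#' @export
identify_donors <- function(m, groups, cp_alignment, focal = "admixed",
                            other = "japonica", targets = NULL,
                            mode = "dosage", min_freq = 0.005, ...) {
  ft <- group_frequencies(m, groups)
  ss <- classify_sites(ft, focal, other, label = "absent", ...)
  if (is.null(targets))
    targets <- groups$sample[groups$group != focal]
  scores <- similarity_scores(m, ss, targets = targets, mode = mode)
  det <- detect_elevated(scores)
  hm <- extract_variants(cp_alignment, min_freq = min_freq)
  cl <- collapse_haplotypes(hm)
  hf <- group_haplotype_freqs(
    cl$assignment,
    groups[groups$sample %in% cl$assignment$sample, , drop = FALSE])
  in_focal <- unique(hf$haplotype[hf$group == focal & hf$count > 0])
  in_other <- unique(hf$haplotype[hf$group == other & hf$count > 0])
  focal_haps <- setdiff(in_focal, in_other)
  donors <- integrate_donor_set(det$candidates, cl$assignment, focal_haps)
  list(site_set = ss, scores = scores, detection = det,
       haplotypes = cl, haplotype_freqs = hf,
       focal_haplotypes = focal_haps, donor_set = donors)
}
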