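#' Parameters for the forward simulator
#'
#' Bundles the knobs of the two-source admixture simulator. The two source
#' populations diverge from a common ancestral allele-frequency pool under a
#' Balding-Nichols model at differentiation `F_diff`; an admixed group is
#' formed by a single pulse `g` generations ago contributing a fraction
#' `alpha` from source 1 (the donor), and per-group missing-call rates mimic
#' the depth asymmetry of merged low-coverage wild and high-coverage
#' cultivated panels.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_sites SNP sites per chromosome.
#' @param chrom_morgans Effective genetic length per chromosome (Morgans).
#'   The default 0.2 reflects the strongly reduced effective recombination
#'   of a predominantly self-pollinating crop, where most map-length
#'   crossovers occur in homozygous stretches and leave no footprint.
#' @param chrom_bp Physical length per chromosome (bp); the physical-genetic
#'   map is linear.
#' @param F_diff Balding-Nichols differentiation of each source from the
#'   ancestral pool (also the expected FST between the sources' frequencies).
#' @param n_source0,n_source1 Diploid individuals simulated per source
#'   population (the haplotype pools are twice these).
#' @param n_admixed Diploid admixed individuals.
#' @param alpha Admixture proportion contributed by source 1.
#' @param g Generations since the admixture pulse; tract boundaries follow a
#'   Poisson process of rate `g` per Morgan.
#' @param miss0,miss1,miss_adm Per-genotype missing-call rates for source 0,
#'   source 1 and the admixed group.
#' @param n_core_haps Size of the finite core-haplotype pool per source.
#'   Individual haplotypes are mosaics of the pool, which gives the
#'   populations realistic haplotype sharing (linkage disequilibrium) while
#'   leaving per-site marginal frequencies at the Balding-Nichols values;
#'   set to `Inf` for the structureless site-independent model.
#' @param core_switch_rate Core-mosaic junction density per Morgan.
#' @param hap_mut Per-site private mutation (allele flip) probability on
#'   each individual haplotype.
#' @param seed Integer seed; all generators are reproducible under it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_chrom = 10L, n_sites = 500L, chrom_morgans = 0.2,
                       chrom_bp = 30e6, F_diff = 0.3,
                       n_source0 = 30L, n_source1 = 30L, n_admixed = 34L,
                       alpha = 0.36, g = 50L,
                       miss0 = 0.1, miss1 = 0.5, miss_adm = 0.1,
                       n_core_haps = 10L, core_switch_rate = 50,
                       hap_mut = 0.01,
                       seed = 1L) {
  p <- list(n_chrom = as.integer(n_chrom), n_sites = as.integer(n_sites),
            chrom_morgans = chrom_morgans, chrom_bp = chrom_bp,
            F_diff = F_diff, n_source0 = as.integer(n_source0),
            n_source1 = as.integer(n_source1),
            n_admixed = as.integer(n_admixed), alpha = alpha,
            g = as.integer(g), miss0 = miss0, miss1 = miss1,
            miss_adm = miss_adm, n_core_haps = n_core_haps,
            core_switch_rate = core_switch_rate, hap_mut = hap_mut,
            seed = as.integer(seed))
  stopifnot(p$alpha >= 0, p$alpha <= 1, p$F_diff > 0, p$F_diff < 1,
            p$g >= 1, p$miss0 >= 0, p$miss0 < 1, p$miss1 >= 0, p$miss1 < 1,
            p$miss_adm >= 0, p$miss_adm < 1)
  class(p) <- "sim_params"
  p
}

sim_sites <- function(p) {
  out <- lapply(seq_len(p$n_chrom), function(ch) {
    pos <- sort(sample.int(p$chrom_bp, p$n_sites))
    data.frame(chrom = sprintf("chr%02d", ch), pos = pos,
               ref = "A", alt = "T",
               gpos = pos / p$chrom_bp * p$chrom_morgans,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate two differentiated source populations
#'
#' Balding-Nichols model: an ancestral frequency `q ~ Uniform(0.05, 0.95)`
#' per site; each source's frequency drawn from
#' `Beta(q (1 - F) / F, (1 - q)(1 - F) / F)`; haplotype alleles Bernoulli at
#' the source frequency. The expected Weir-Cockerham FST between the two
#' sources equals `F_diff`.
#'
#' @param p A [sim_params()] object.
#' @return A list with `hap0`, `hap1` (0/1 integer matrices, one row per
#'   haplotype, rows named `<pop><ind>_h<1|2>`), `sites` (site table with
#'   genetic positions in column `gpos`) and `freqs` (data frame of
#'   ancestral and per-source frequencies).
#' @export
simulate_sources <- function(p) {
  set.seed(p$seed)
  sites <- sim_sites(p)
  S <- nrow(sites)
  q <- stats::runif(S, 0.05, 0.95)
  shape <- (1 - p$F_diff) / p$F_diff
  p0 <- stats::rbeta(S, q * shape, (1 - q) * shape)
  p1 <- stats::rbeta(S, q * shape, (1 - q) * shape)
  list(hap0 = draw_pop_haps(p0, p$n_source0, "P0_", p, sites),
       hap1 = draw_pop_haps(p1, p$n_source1, "P1_", p, sites),
       sites = sites,
       freqs = data.frame(anc = q, p0 = p0, p1 = p1))
}

# Sample 2 * n_dip haplotypes at frequencies `freq`. With a finite core
# pool the haplotypes are core mosaics (shared segments = within-population
# LD); marginals stay Bernoulli(freq) because the cores are.
draw_pop_haps <- function(freq, n_dip, prefix, p, sites) {
  S <- length(freq)
  n_hap <- 2L * n_dip
  nm <- paste0(prefix, rep(seq_len(n_dip), each = 2L), "_h", rep(1:2, n_dip))
  if (!is.finite(p$n_core_haps)) {
    h <- matrix(stats::rbinom(n_hap * S, 1L, rep(freq, each = n_hap)),
                nrow = n_hap, dimnames = list(nm, NULL))
    return(h)
  }
  nc <- as.integer(p$n_core_haps)
  cores <- matrix(stats::rbinom(nc * S, 1L, rep(freq, each = nc)), nrow = nc)
  h <- matrix(NA_integer_, n_hap, S, dimnames = list(nm, NULL))
  ix_by_ch <- lapply(unique(sites$chrom), function(ch) which(sites$chrom == ch))
  for (i in seq_len(n_hap)) {
    for (ix in ix_by_ch) {
      brk <- sort(stats::runif(
        stats::rpois(1L, p$core_switch_rate * p$chrom_morgans),
        0, p$chrom_morgans))
      seg <- findInterval(sites$gpos[ix], brk) + 1L
      for (s in unique(seg)) {
        at <- ix[seg == s]
        h[i, at] <- cores[sample.int(nc, 1L), at]
      }
    }
  }
  if (p$hap_mut > 0) {
    flip <- matrix(stats::runif(n_hap * S) < p$hap_mut, n_hap, S)
    h[flip] <- 1L - h[flip]
  }
  h
}

# Breakpoints of one haplotype on one chromosome, in Morgans.
sample_tracts <- function(p) {
  n_bp <- stats::rpois(1L, p$g * p$chrom_morgans)
  brk <- sort(stats::runif(n_bp, 0, p$chrom_morgans))
  bounds <- c(0, brk, p$chrom_morgans)
  labels <- stats::rbinom(length(bounds) - 1L, 1L, p$alpha)
  data.frame(start_m = utils::head(bounds, -1), end_m = bounds[-1],
             source = labels)
}

#' Simulate admixed diploids with tract-level truth
#'
#' Each admixed haplotype is a mosaic: tract boundaries follow a Poisson
#' process of rate `g` per Morgan, each tract's source is Bernoulli(`alpha`),
#' and its alleles are copied from one randomly chosen haplotype of that
#' source's pool. Haplotypes are paired into diploids.
#'
#' @param src Output of [simulate_sources()].
#' @param p The same [sim_params()].
#' @param ids Optional sample identifiers (default `ADM1..ADMn`).
#' @return List with `haps` (0/1 matrix, two rows per individual),
#'   `genotypes` (a [genotype_matrix()] of dosages), `truth` (tract table:
#'   haplotype, chrom, start/end in bp, source label) and `sites`.
#' @export
simulate_admixed <- function(src, p, ids = NULL) {
  set.seed(p$seed + 1L)
  if (is.null(ids)) ids <- paste0("ADM", seq_len(p$n_admixed))
  sites <- src$sites
  chroms <- unique(sites$chrom)
  pools <- list(src$hap0, src$hap1)
  hap_names <- paste0(rep(ids, each = 2L), "_h", rep(1:2, length(ids)))
  haps <- matrix(NA_integer_, nrow = length(hap_names), ncol = nrow(sites),
                 dimnames = list(hap_names, NULL))
  truth <- vector("list", length(hap_names) * length(chroms))
  ti <- 0L
  for (h in seq_along(hap_names)) {
    for (ch in chroms) {
      on_ch <- which(sites$chrom == ch)
      gpos <- sites$gpos[on_ch]
      tr <- sample_tracts(p)
      which_tract <- findInterval(gpos, tr$start_m)
      which_tract[which_tract < 1L] <- 1L
      for (k in seq_len(nrow(tr))) {
        pool <- pools[[tr$source[k] + 1L]]
        donor <- sample.int(nrow(pool), 1L)
        in_tr <- on_ch[which_tract == k]
        if (length(in_tr))
          haps[h, in_tr] <- pool[donor, in_tr]
      }
      ti <- ti + 1L
      truth[[ti]] <- data.frame(
        haplotype = hap_names[h], chrom = ch,
        start_bp = pmax(1, round(tr$start_m / p$chrom_morgans * p$chrom_bp)),
        end_bp = round(tr$end_m / p$chrom_morgans * p$chrom_bp),
        start_m = tr$start_m, end_m = tr$end_m,
        source = tr$source, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  dos <- haps[seq(1, nrow(haps), 2), , drop = FALSE] +
    haps[seq(2, nrow(haps), 2), , drop = FALSE]
  rownames(dos) <- ids
  gm <- genotype_matrix(dos, sites[, c("chrom", "pos", "ref", "alt")])
  list(haps = haps, genotypes = gm, truth = truth, sites = sites)
}

#' Per-site truth labels from a tract table
#'
#' @param truth Tract table as produced by [simulate_admixed()].
#' @param sites Site table with `chrom` and `gpos` (Morgans) columns.
#' @return Integer 0/1 matrix, haplotypes x sites.
#' @export
truth_site_labels <- function(truth, sites) {
  haps <- unique(truth$haplotype)
  lab <- matrix(NA_integer_, nrow = length(haps), ncol = nrow(sites),
                dimnames = list(haps, NULL))
  for (h in haps) {
    tr_all <- truth[truth$haplotype == h, , drop = FALSE]
    for (ch in unique(tr_all$chrom)) {
      tr <- tr_all[tr_all$chrom == ch, , drop = FALSE]
      on_ch <- which(sites$chrom == ch)
      k <- findInterval(sites$gpos[on_ch], tr$start_m)
      k[k < 1L] <- 1L
      k[k > nrow(tr)] <- nrow(tr)
      lab[h, on_ch] <- tr$source[k]
    }
  }
  lab
}

#' Length-weighted truth ancestry fractions
#'
#' @param truth Tract table.
#' @param by `"haplotype"` or `"individual"` (individual = mean of its two
#'   haplotypes, identified by stripping the `_h1`/`_h2` suffix).
#' @return Data frame with the source-1 genome fraction per unit.
#' @export
truth_fractions <- function(truth, by = c("haplotype", "individual")) {
  by <- match.arg(by)
  len <- truth$end_m - truth$start_m
  fr <- tapply(len * truth$source, truth$haplotype, sum) /
    tapply(len, truth$haplotype, sum)
  out <- data.frame(haplotype = names(fr), frac1 = as.numeric(fr),
                    stringsAsFactors = FALSE)
  if (by == "individual") {
    ind <- sub("_h[12]$", "", out$haplotype)
    fr2 <- tapply(out$frac1, ind, mean)
    out <- data.frame(individual = names(fr2), frac1 = as.numeric(fr2),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Mask genotype calls at per-group rates
#'
#' Sets each call independently to missing with its sample group's rate,
#' emulating depth-driven missingness asymmetry between panels.
#'
#' @param m A [genotype_matrix()].
#' @param rates Either a single rate or a named vector of rates per group.
#' @param groups A `group_map` (required when `rates` is named).
#' @param seed Integer seed.
#' @return A `genotype_matrix` with added missingness.
#' @export
apply_missingness <- function(m, rates, groups = NULL, seed = 1L) {
  stopifnot(all(rates >= 0), all(rates < 1))
  set.seed(seed)
  calls <- m$calls
  if (is.null(names(rates))) {
    if (length(rates) != 1L) stop("unnamed rates must be a single value")
    rate_by_sample <- rep(rates, n_samples(m))
  } else {
    if (is.null(groups)) stop("named rates need a group map")
    validate_group_map(groups, m)
    grp <- groups$group[match(sample_names(m), groups$sample)]
    rate_by_sample <- unname(rates[grp])
    rate_by_sample[is.na(rate_by_sample)] <- 0
  }
  mask <- matrix(stats::runif(length(calls)) < rate_by_sample,
                 nrow = nrow(calls))  # recycles by column = by sample
  calls[mask] <- NA_integer_
  genotype_matrix(calls, m$sites)
}

#' Mask phased haplotypes at a per-genotype rate
#'
#' Missingness originates at the genotype level, so both haplotypes of an
#' individual are masked together: rows are assumed paired (`_h1`, `_h2`
#' consecutive).
#'
#' @param haps 0/1 haplotype matrix, two consecutive rows per individual.
#' @param rate Per-genotype missing rate.
#' @param seed Integer seed.
#' @return The matrix with masked entries set to `NA`.
#' @export
mask_haplotypes <- function(haps, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1, nrow(haps) %% 2L == 0L)
  set.seed(seed)
  n_ind <- nrow(haps) / 2L
  mask <- matrix(stats::runif(n_ind * ncol(haps)) < rate, nrow = n_ind)
  full <- mask[rep(seq_len(n_ind), each = 2L), , drop = FALSE]
  haps[full] <- NA_integer_
  haps
}

#' Simulate maternally inherited organellar haplotypes
#'
#' Two divergent haplotype cores (donor-type and japonica-type, at least
#' `n_diag` fixed differences) stand for the deep chloroplast split between
#' the donor lineage and the japonica lineage. Each individual inherits the
#' donor-type core with its stated probability and accumulates a small
#' number of private point mutations.
#'
#' @param individuals Character vector of individual identifiers, or a tract
#'   table from [simulate_admixed()] (its individuals are used).
#' @param maternal_from_donor_prob Probability an individual carries the
#'   donor-type core. Either a single value or a vector parallel to
#'   `individuals`.
#' @param n_hap_sites Alignment length (columns).
#' @param n_diag Number of diagnostic fixed differences between the cores.
#' @param mut_rate Expected private mutations per sequence.
#' @param seed Integer seed.
#' @return List with `alignment` (character matrix of A/C/G/T, one row per
#'   individual), `labels` (named vector, `"donor"` or `"japonica"`), and
#'   `diagnostic_sites` (column indices of the fixed differences).
#' @export
simulate_chloroplast <- function(individuals, maternal_from_donor_prob,
                                 n_hap_sites = 60L, n_diag = 8L,
                                 mut_rate = 0.05, seed = 1L) {
  if (is.data.frame(individuals))
    individuals <- unique(sub("_h[12]$", "", individuals$haplotype))
  stopifnot(all(maternal_from_donor_prob >= 0),
            all(maternal_from_donor_prob <= 1), n_diag >= 5L,
            n_hap_sites > n_diag)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  core_jap <- sample(bases, n_hap_sites, replace = TRUE)
  diag_idx <- sort(sample.int(n_hap_sites, n_diag))
  core_donor <- core_jap
  for (i in diag_idx)
    core_donor[i] <- sample(setdiff(bases, core_jap[i]), 1L)
  n <- length(individuals)
  is_donor <- stats::runif(n) < rep_len(maternal_from_donor_prob, n)
  aln <- matrix(NA_character_, nrow = n, ncol = n_hap_sites,
                dimnames = list(individuals, NULL))
  for (i in seq_len(n)) {
    s <- if (is_donor[i]) core_donor else core_jap
    k <- stats::rpois(1L, mut_rate)
    if (k > 0) {
      at <- sample(setdiff(seq_len(n_hap_sites), diag_idx), min(k, n_hap_sites - n_diag))
      for (j in at) s[j] <- sample(setdiff(bases, s[j]), 1L)
    }
    aln[i, ] <- s
  }
  labels <- ifelse(is_donor, "donor", "japonica")
  names(labels) <- individuals
  list(alignment = aln, labels = labels, diagnostic_sites = diag_idx,
       cores = rbind(japonica = core_jap, donor = core_donor))
}

#' Collapse paired haplotype rows to diploid dosages
#'
#' @param haps 0/1 (or `NA`) haplotype matrix, two consecutive rows per
#'   individual named `<id>_h1`, `<id>_h2`.
#' @param sites Site table (`chrom`, `pos`, `ref`, `alt`).
#' @return A [genotype_matrix()]; a genotype is missing if either haplotype
#'   allele is.
#' @export
haps_to_genotypes <- function(haps, sites) {
  h1 <- haps[seq(1, nrow(haps), 2), , drop = FALSE]
  h2 <- haps[seq(2, nrow(haps), 2), , drop = FALSE]
  dos <- h1 + h2
  rownames(dos) <- sub("_h1$", "", rownames(h1))
  genotype_matrix(dos, sites[, c("chrom", "pos", "ref", "alt")])
}
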