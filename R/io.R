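#' Read diploid genotypes from a VCF file
#'
#' Loads GT fields from a VCF and returns alt-allele dosages. Only biallelic
#' SNP records are kept: multi-allelic records, indels and records with
#' symbolic alleles are skipped and counted. Diploid genotypes are decoded as
#' the number of ALT alleles; half-missing calls (`./1`) and fully missing
#' calls are both treated as missing.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param verbose Print the number of skipped records.
#' @return A [genotype_matrix()]. The number of skipped non-biallelic-SNP
#'   records is attached as attribute `skipped`.
#' @export
read_genotypes <- function(path, verbose = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!snp)
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  calls <- decode_gt(gt)                     # sites x samples
  sites <- data.frame(
    chrom = fix[snp, "CHROM"],
    pos = as.integer(fix[snp, "POS"]),
    ref = ref[snp], alt = alt[snp],
    stringsAsFactors = FALSE
  )
  if (verbose && skipped > 0)
    message(skipped, " non-biallelic-SNP record(s) skipped")
  m <- genotype_matrix(t(calls), sites)
  attr(m, "skipped") <- skipped
  m
}

# GT strings -> dosage; any genotype containing "." is missing.
decode_gt <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean %in% "0/0"] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% "1/1"] <- 2L
  d
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an unphased GT-only VCF (diploid `0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param m A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(m, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow = n_sites(m), ncol = n_samples(m))
  idx <- which(!is.na(t(m$calls)))
  body[idx] <- gt_code[t(m$calls)[idx] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names(m)), collapse = "\t"),
    paste(m$sites$chrom, m$sites$pos, ".", m$sites$ref, m$sites$alt,
          ".", ".", ".", "GT",
          apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Harmonize and merge two genotype matrices on a shared reference
#'
#' Keeps exactly the sites present in both inputs at identical (chrom, pos)
#' whose allele pairs match either directly or with REF and ALT swapped.
#' Swapped sites have the second matrix's dosages flipped (0 <-> 2, 1 stays)
#' so that all dosages count the first matrix's ALT allele. Sites with
#' incompatible allele pairs are dropped and counted. Strand flips are not
#' rescued: both inputs are assumed to be called against the same reference
#' build.
#'
#' @param a,b `genotype_matrix` objects with disjoint sample sets.
#' @param verbose Print drop counts.
#' @return A merged `genotype_matrix` carrying attributes `n_swapped` and
#'   `n_mismatched` (allele-incompatible sites dropped).
#' @export
harmonize_merge <- function(a, b, verbose = TRUE) {
  if (length(intersect(sample_names(a), sample_names(b))))
    stop("sample sets overlap; refusing to merge")
  ka <- site_key(a$sites)
  kb <- site_key(b$sites)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  sa <- a$sites[ia, , drop = FALSE]
  sb <- b$sites[ib, , drop = FALSE]
  direct <- sa$ref == sb$ref & sa$alt == sb$alt
  swapped <- sa$ref == sb$alt & sa$alt == sb$ref
  keep <- direct | swapped
  n_mismatched <- sum(!keep)
  if (!any(keep)) stop("no allele-compatible shared sites to merge")
  ia <- ia[keep]; ib <- ib[keep]
  swapped <- swapped[keep]
  cb <- b$calls[, ib, drop = FALSE]
  if (any(swapped))
    cb[, swapped] <- 2L - cb[, swapped, drop = FALSE]
  calls <- rbind(a$calls[, ia, drop = FALSE], cb)
  if (verbose)
    message(sum(keep), " sites merged (", sum(swapped), " allele-swapped, ",
            n_mismatched, " allele-incompatible dropped)")
  out <- genotype_matrix(calls, a$sites[ia, , drop = FALSE])
  attr(out, "n_swapped") <- sum(swapped)
  attr(out, "n_mismatched") <- n_mismatched
  out
}

#' Keep polymorphic sites scored in a required subset
#'
#' Retains sites that are polymorphic across all samples (at least two
#' distinct non-missing dosage states, or any heterozygote) and that have at
#' least one non-missing call within the given sample subset. Typical use:
#' require data in a low-depth wild panel after merging it with a deeply
#' sequenced cultivated panel.
#'
#' @param m A `genotype_matrix`.
#' @param subset Character vector of sample names (non-empty, all present).
#' @return Filtered `genotype_matrix`.
#' @export
filter_polymorphic_with_subset_data <- function(m, subset) {
  if (length(subset) == 0) stop("empty sample subset")
  miss <- setdiff(subset, sample_names(m))
  if (length(miss)) stop("subset samples absent: ", paste(miss, collapse = ", "))
  calls <- m$calls
  alt <- colSums(calls, na.rm = TRUE)
  nm <- colSums(!is.na(calls))
  poly <- nm > 0L & alt > 0L & alt < 2L * nm
  scored <- colSums(!is.na(calls[subset, , drop = FALSE])) > 0L
  subset_genotypes(m, site_idx = which(poly & scored))
}

#' Optional per-site heterozygosity filter
#'
#' Drops sites whose fraction of heterozygous calls among non-missing calls
#' exceeds `max_het`. Upstream SNP panels sometimes remove such sites (they
#' are enriched for paralog collapse); no threshold is standard, so the
#' filter is off unless called explicitly.
#'
#' @param m A `genotype_matrix`.
#' @param max_het Maximum tolerated heterozygous fraction per site.
#' @return Filtered `genotype_matrix`.
#' @export
filter_excess_heterozygosity <- function(m, max_het = 0.5) {
  het <- colSums(m$calls == 1L, na.rm = TRUE)
  nm <- colSums(!is.na(m$calls))
  frac <- ifelse(nm > 0, het / nm, 0)
  subset_genotypes(m, site_idx = which(frac <= max_het))
}

#' Descriptive statistics of a merged SNP matrix
#'
#' Summaries used to inspect a merged panel: per-site non-missingness
#' histograms per superpopulation, major-allele frequency histograms,
#' per-sample heterozygous-site proportions with group means, and SNP counts
#' per window along each chromosome.
#'
#' @param m A `genotype_matrix`.
#' @param groups A `group_map` covering the samples to summarize. Groups here
#'   are typically superpopulations (e.g. wild vs domesticated).
#' @param window_bp Window size for SNP density (default 100 kb); windows are
#'   half-open `[start, start + window_bp)`.
#' @param breaks Histogram breaks on `[0, 1]` for the non-missingness and
#'   major-allele-frequency histograms.
#' @return A list with data frames `nonmissing_hist`, `major_freq_hist`,
#'   `heterozygosity` (per sample), `het_summary` (per group, mean and SD),
#'   and `snp_density` (per window).
#' @export
descriptive_stats <- function(m, groups, window_bp = 100000L,
                              breaks = seq(0, 1, by = 0.1)) {
  validate_group_map(groups, m)
  labs <- sort(unique(groups$group))
  nonmiss <- list(); mafh <- list()
  for (g in labs) {
    gm <- m$calls[group_samples(groups, g), , drop = FALSE]
    nm_frac <- colMeans(!is.na(gm))
    h1 <- hist(nm_frac, breaks = breaks, plot = FALSE, include.lowest = TRUE)
    nonmiss[[g]] <- data.frame(group = g, bin_lo = utils::head(breaks, -1),
                               bin_hi = breaks[-1], n_sites = h1$counts)
    alt <- colSums(gm, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(gm))
    f <- ifelse(tot > 0, alt / tot, NA_real_)
    maf <- pmax(f, 1 - f)
    h2 <- hist(maf[!is.na(maf)], breaks = breaks, plot = FALSE,
               include.lowest = TRUE)
    mafh[[g]] <- data.frame(group = g, bin_lo = utils::head(breaks, -1),
                            bin_hi = breaks[-1], n_sites = h2$counts)
  }
  het_n <- rowSums(m$calls == 1L, na.rm = TRUE)
  nm_n <- rowSums(!is.na(m$calls))
  het <- data.frame(
    sample = sample_names(m),
    group = groups$group[match(sample_names(m), groups$sample)],
    n_nonmissing = nm_n,
    het_proportion = ifelse(nm_n > 0, het_n / nm_n, NA_real_),
    stringsAsFactors = FALSE
  )
  if (any(nm_n == 0))
    warning(sum(nm_n == 0), " all-missing sample(s) excluded from ",
            "heterozygosity summary")
  hs <- do.call(rbind, lapply(labs, function(g) {
    v <- het$het_proportion[het$group %in% g & !is.na(het$het_proportion)]
    data.frame(group = g, n = length(v), mean_het = mean(v),
               sd_het = stats::sd(v))
  }))
  win <- lapply(split(m$sites$pos, m$sites$chrom), function(pos) {
    idx <- (pos - 1L) %/% window_bp
    tab <- table(factor(idx, levels = 0:max(idx)))
    data.frame(start = as.integer(names(tab)) * window_bp + 1L,
               end = (as.integer(names(tab)) + 1L) * window_bp,
               n_snps = as.integer(tab))
  })
  dens <- do.call(rbind, Map(cbind.data.frame,
                             chrom = names(win), win))
  rownames(dens) <- NULL
  list(nonmissing_hist = do.call(rbind, nonmiss),
       major_freq_hist = do.call(rbind, mafh),
       heterozygosity = het, het_summary = hs, snp_density = dens)
}
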