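#' Per-group allele frequencies and missingness
#'
#' Alt-allele frequencies are computed from allele counts over non-missing
#' calls: `f = sum(dosages) / (2 * n_nonmissing)`. The missing-data fraction
#' is the fraction of samples in the group with a missing call.
#'
#' @param m A [genotype_matrix()].
#' @param groups A `group_map`; every group must be non-empty.
#' @return A list of class `freq_table`: `freq` (sites x groups alt
#'   frequency, `NA` where no data), `n` (non-missing sample counts),
#'   `missing` (missing fractions), `sites`.
#' @export
group_frequencies <- function(m, groups) {
  validate_group_map(groups, m)
  labs <- sort(unique(groups$group))
  S <- n_sites(m)
  freq <- nmat <- mu <- matrix(NA_real_, nrow = S, ncol = length(labs),
                               dimnames = list(NULL, labs))
  for (g in labs) {
    gm <- m$calls[group_samples(groups, g), , drop = FALSE]
    nm <- colSums(!is.na(gm))
    alt <- colSums(gm, na.rm = TRUE)
    freq[, g] <- ifelse(nm > 0, alt / (2 * nm), NA_real_)
    nmat[, g] <- nm
    mu[, g] <- 1 - nm / nrow(gm)
  }
  structure(list(freq = freq, n = nmat, missing = mu, sites = m$sites),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d sites x %d groups\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

# Frequency, in `other`, of the allele that is major in `focal`.
# Returns list(f_focal = major-allele freq in focal, f_other = same allele's
# freq in other, is_alt = TRUE if the focal major allele is ALT).
focal_major_in_other <- function(ft, focal, other) {
  f_foc <- ft$freq[, focal]
  is_alt <- !is.na(f_foc) & f_foc > 0.5
  is_ref <- !is.na(f_foc) & (1 - f_foc) > 0.5
  f_major <- ifelse(is_alt, f_foc, ifelse(is_ref, 1 - f_foc, NA_real_))
  f_oth_alt <- ft$freq[, other]
  f_other <- ifelse(is_alt, f_oth_alt, ifelse(is_ref, 1 - f_oth_alt, NA_real_))
  list(f_focal = f_major, f_other = f_other, is_alt = is_alt,
       has_major = is_alt | is_ref)
}

#' Joint allele frequency spectrum of two groups
#'
#' 2-D histogram of sites by the frequency of the focal group's major allele
#' (frequency > 0.5 within focal) in the focal group and of the same allele
#' in the other group. Counts are reported raw and as `log10(count + 1)` for
#' display.
#'
#' @param ft A `freq_table`.
#' @param focal,other Group names present in the table.
#' @param n_bins Number of right-closed bins per axis on `[0, 1]`.
#' @return List: `counts` (focal bins x other bins), `log10` (display
#'   values), `n_sites` (contributing sites), bin edges.
#' @export
joint_spectrum <- function(ft, focal, other, n_bins = 20L) {
  fm <- focal_major_in_other(ft, focal, other)
  use <- fm$has_major & !is.na(fm$f_other) & fm$f_focal > 0.5
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- function(v) {
    b <- findInterval(v, edges, rightmost.closed = TRUE, left.open = TRUE)
    b[b < 1L] <- 1L  # frequency 0 joins the first bin
    b
  }
  bf <- bin(fm$f_focal[use])
  bo <- bin(fm$f_other[use])
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(bf)) counts[bf[i], bo[i]] <- counts[bf[i], bo[i]] + 1L
  dimnames(counts) <- list(
    focal = sprintf("(%.3f,%.3f]", utils::head(edges, -1), edges[-1]),
    other = sprintf("(%.3f,%.3f]", utils::head(edges, -1), edges[-1]))
  list(counts = counts, log10 = log10(counts + 1), n_sites = sum(use),
       edges = edges, focal = focal, other = other)
}

#' Classify sites carrying a focal-group major allele absent or rare elsewhere
#'
#' A site enters the set iff some allele has frequency > 0.5 in the focal
#' group, that same allele's frequency in the other group is below the
#' threshold (`< absent_thresh` for label `"absent"`, `<= rare_thresh` for
#' `"rare"`), and the missing-data fraction is at most `max_missing` in both
#' groups (heavily missing sites are unreliable: the dominant variant there
#' may be a deletion).
#'
#' @param ft A `freq_table`.
#' @param focal,other Group names.
#' @param label `"absent"` or `"rare"`.
#' @param absent_thresh,rare_thresh Frequency thresholds in the other group.
#' @param max_missing Maximum tolerated missing fraction per group.
#' @return A data frame of class `site_set`: site columns plus
#'   `major_is_alt`, `f_focal`, `f_other`, and attribute `label`.
#' @export
classify_sites <- function(ft, focal, other, label = c("absent", "rare"),
                           absent_thresh = 0.01, rare_thresh = 0.05,
                           max_missing = 1 / 3) {
  label <- match.arg(label)
  fm <- focal_major_in_other(ft, focal, other)
  tol <- 1e-9   # "1/3 missing" must admit 1 - 2/3 despite rounding
  ok_missing <- ft$missing[, focal] <= max_missing + tol &
    ft$missing[, other] <= max_missing + tol
  pass_other <- if (label == "absent") {
    !is.na(fm$f_other) & fm$f_other < absent_thresh
  } else {
    !is.na(fm$f_other) & fm$f_other <= rare_thresh
  }
  keep <- which(fm$has_major & fm$f_focal > 0.5 & ok_missing & pass_other)
  out <- cbind(ft$sites[keep, , drop = FALSE],
               data.frame(major_is_alt = fm$is_alt[keep],
                          f_focal = fm$f_focal[keep],
                          f_other = fm$f_other[keep]))
  rownames(out) <- NULL
  attr(out, "label") <- label
  attr(out, "site_idx") <- keep
  class(out) <- c("site_set", "data.frame")
  out
}

#' Per-individual sharing of a focal group's distinguishing alleles
#'
#' For each target sample, the proportion of classified sites at which it
#' carries the focal group's major allele. A site is informative for a
#' sample iff its call there is non-missing. Under the default `"presence"`
#' rule a site matches iff the sample carries at least one copy of the
#' stored allele (robust to low-depth panels where heterozygotes are
#' under-called); under `"dosage"` the match contribution is dosage / 2.
#'
#' @param m The [genotype_matrix()] the site set was derived from.
#' @param ss A `site_set` from [classify_sites()].
#' @param targets Sample names to score (default: all samples).
#' @param mode `"presence"` or `"dosage"`.
#' @return Data frame: sample, `n_informative`, `n_match`, `proportion`
#'   (`NA` when no informative sites).
#' @export
similarity_scores <- function(m, ss, targets = sample_names(m),
                              mode = c("presence", "dosage")) {
  mode <- match.arg(mode)
  if (nrow(ss) == 0) stop("empty site set")
  idx <- attr(ss, "site_idx")
  if (is.null(idx))
    idx <- match(paste(ss$chrom, ss$pos), paste(m$sites$chrom, m$sites$pos))
  calls <- m$calls[targets, idx, drop = FALSE]
  # orient dosages to count the focal major allele
  flip <- !ss$major_is_alt
  calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  informative <- !is.na(calls)
  match_val <- if (mode == "presence") (calls >= 1L) * 1 else calls / 2
  n_inf <- rowSums(informative)
  n_match <- rowSums(match_val, na.rm = TRUE)
  data.frame(sample = targets, n_informative = n_inf, n_match = n_match,
             proportion = ifelse(n_inf > 0, n_match / n_inf, NA_real_),
             stringsAsFactors = FALSE)
}

#' Detect samples with distinctly elevated sharing scores
#'
#' Formalizes the visual reading of a score distribution with a clear upper
#' cluster: scores are sorted and the largest gap between consecutive values
#' whose midpoint lies in the upper half of the score range is found; samples
#' above the gap midpoint are returned. An explicit threshold overrides the
#' gap scan.
#'
#' @param scores Output of [similarity_scores()].
#' @param method `"largest-gap"` (only method currently).
#' @param explicit_threshold If given, samples with `proportion >` this value
#'   are returned and no gap scan is run.
#' @param min_gap Minimum gap width to accept (default 0.05); if no gap in
#'   the upper half reaches it, an empty set is returned with a warning.
#' @param min_group Minimum number of samples that must lie above a
#'   qualifying gap (default 2): the method looks for an elevated *group*
#'   of samples, so a gap isolating a single straggler is not a cluster
#'   boundary.
#' @return List: `candidates` (sample names), `threshold` (the cut used, `NA`
#'   when none found).
#' @export
detect_elevated <- function(scores, method = "largest-gap",
                            explicit_threshold = NULL, min_gap = 0.05,
                            min_group = 2L) {
  ok <- !is.na(scores$proportion)
  if (!is.null(explicit_threshold)) {
    keep <- ok & scores$proportion > explicit_threshold
    return(list(candidates = scores$sample[keep],
                threshold = explicit_threshold))
  }
  if (sum(ok) < 3) stop("need at least 3 defined scores")
  v <- sort(scores$proportion[ok])
  n <- length(v)
  gaps <- diff(v)
  mids <- (utils::head(v, -1) + v[-1]) / 2
  # a gap qualifies if it opens into the upper half of the score range and
  # leaves a group (not a straggler) above it
  upper <- v[-1] >= (min(v) + max(v)) / 2
  group_above <- (n - seq_len(n - 1)) >= min_group
  cand <- which(upper & gaps >= min_gap & group_above)
  if (!length(cand)) {
    warning("no score gap >= ", min_gap, " in the upper half; empty set")
    return(list(candidates = character(0), threshold = NA_real_))
  }
  best <- cand[which.max(gaps[cand])]
  thr <- mids[best]
  keep <- ok & scores$proportion > thr
  list(candidates = scores$sample[keep], threshold = thr)
}

#' Fraction of distinguishing alleles recoverable in another group
#'
#' For a classified site set, the fraction of member sites whose focal-major
#' allele segregates in a query group above a presence threshold.
#'
#' @param ss A `site_set`.
#' @param ft The `freq_table` it came from.
#' @param query Group name to interrogate.
#' @param presence_thresh Frequency above which the allele counts as present
#'   (default 0.05).
#' @return A single fraction in `[0, 1]` (sites with no data in the query
#'   group count as absent).
#' @export
allele_recovery <- function(ss, ft, query, presence_thresh = 0.05) {
  if (nrow(ss) == 0) return(NA_real_)
  idx <- attr(ss, "site_idx")
  f_alt <- ft$freq[idx, query]
  f_allele <- ifelse(ss$major_is_alt, f_alt, 1 - f_alt)
  mean(!is.na(f_allele) & f_allele > presence_thresh)
}
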