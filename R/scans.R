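#' Windowed nucleotide diversity
#'
#' Per site, diversity is the probability that two alleles drawn without
#' replacement from the group's non-missing allele pool differ:
#' `pi_site = c_ref * c_alt / choose(n, 2)` with `n = c_ref + c_alt`. The
#' window value is the sum of site diversities divided by the window length
#' in bp (per-bp diversity over non-overlapping, half-open windows
#' `[start, start + window_bp)`).
#'
#' @param m A [genotype_matrix()].
#' @param group Character vector of sample names forming the group, or a
#'   single group label if `groups` is supplied.
#' @param window_bp Window size in bp.
#' @param groups Optional `group_map` used to resolve a group label.
#' @return Data frame: `chrom`, `start`, `end`, `n_sites` (sites with at
#'   least two scored alleles), `value` (pi per bp).
#' @export
windowed_pi <- function(m, group, window_bp = 100000L, groups = NULL) {
  samples <- resolve_group(m, group, groups)
  calls <- m$calls[samples, , drop = FALSE]
  c_alt <- colSums(calls, na.rm = TRUE)
  n_tot <- 2 * colSums(!is.na(calls))
  c_ref <- n_tot - c_alt
  pi_site <- ifelse(n_tot >= 2, c_ref * c_alt / choose(n_tot, 2), 0)
  used <- n_tot >= 2
  window_sums(m$sites, pi_site, used, window_bp,
              function(s, n) s / window_bp)
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' Per site, the two-population Weir-Cockerham (1984) variance components
#' are computed from diploid genotype counts: `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals,
#' driven by heterozygosity). The window estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)`; sites where the denominator is zero are
#' skipped. Negative window values are reported as computed (a property of
#' the estimator near zero differentiation); set `clip_negative = TRUE` to
#' floor them at 0.
#'
#' @param m A [genotype_matrix()].
#' @param group_a,group_b Sample name vectors (or labels with `groups`).
#' @param window_bp Window size in bp.
#' @param groups Optional `group_map`.
#' @param clip_negative Floor negative window values at zero (default off).
#' @return Data frame: `chrom`, `start`, `end`, `n_sites` (sites entering
#'   the sums), `value` (`NA` where no valid site).
#' @export
windowed_fst <- function(m, group_a, group_b, window_bp = 100000L,
                         groups = NULL, clip_negative = FALSE) {
  sa <- resolve_group(m, group_a, groups)
  sb <- resolve_group(m, group_b, groups)
  comp <- wc_site_components(m$calls[sa, , drop = FALSE],
                             m$calls[sb, , drop = FALSE])
  valid <- comp$valid & comp$den > 0
  num <- ifelse(valid, comp$a, 0)
  den <- ifelse(valid, comp$den, 0)
  out <- window_sums(m$sites, num, valid, window_bp, NULL, den)
  if (clip_negative) out$value <- pmax(out$value, 0)
  out
}

# Weir & Cockerham (1984) two-population variance components per site,
# vectorized across sites. Inputs: dosage matrices (samples x sites).
wc_site_components <- function(ca, cb) {
  n1 <- colSums(!is.na(ca)); n2 <- colSums(!is.na(cb))
  p1 <- ifelse(n1 > 0, colSums(ca, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(cb, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(ca == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(cb == 1L, na.rm = TRUE) / n2, NA_real_)
  r <- 2
  valid <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  # nbar == 1 (one individual per pop) leaves a/b undefined
  valid <- valid & nbar > 1 & nc > 0
  a[!valid] <- 0; b[!valid] <- 0; cc[!valid] <- 0
  list(a = a, b = b, c = cc, den = a + b + cc, valid = valid)
}

resolve_group <- function(m, group, groups) {
  if (!is.null(groups) && length(group) == 1L &&
      group %in% groups$group)
    group <- group_samples(groups, group)
  miss <- setdiff(group, sample_names(m))
  if (length(miss)) stop("samples absent: ", paste(miss, collapse = ", "))
  if (!length(group)) stop("empty group")
  group
}

# Shared windowing: sums `num` (and optionally `den`) per half-open window.
window_sums <- function(sites, num, used, window_bp, value_fun, den = NULL) {
  win_id <- paste(sites$chrom, (sites$pos - 1L) %/% window_bp)
  split_idx <- split(seq_len(nrow(sites)), win_id)
  rows <- lapply(split_idx, function(ix) {
    ch <- sites$chrom[ix[1]]
    w <- (sites$pos[ix[1]] - 1L) %/% window_bp
    s_num <- sum(num[ix])
    n_used <- sum(used[ix])
    val <- if (is.null(den)) {
      value_fun(s_num, n_used)
    } else {
      s_den <- sum(den[ix])
      if (s_den > 0) s_num / s_den else NA_real_
    }
    data.frame(chrom = ch, start = w * window_bp + 1L,
               end = (w + 1L) * window_bp, n_sites = n_used, value = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
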