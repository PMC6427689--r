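#' Paint one haplotype by a switch-penalty copying model
#'
#' Models the query haplotype as a mosaic of segments copied from the union
#' of two reference haplotype panels. Over all copying paths `k(1..T)`
#' through the template haplotypes, the dynamic program minimizes
#' `sum_t mismatch(t, k(t)) + lambda * #\{t : k(t) != k(t-1)\}` where a
#' mismatch costs 1 when the query and the copied template carry different
#' alleles and 0 when the query allele is missing. A missing *template*
#' allele is scored, under the default `missing_cost = "expected"`, at the
#' expected mismatch against the template panel's allele frequency at that
#' site (`f` if the query carries 0, `1 - f` if it carries 1): an
#' unobserved template allele is treated as a random draw from its own
#' panel, so sparse panels do not become artificially cheap to copy from.
#' `missing_cost = "zero"` instead treats any missing allele as a free
#' match. The per-site ancestry label
#' is the panel of the copied template. Any template change -- within or
#' between panels -- pays the same switch penalty; only between-panel
#' changes alter the label. Ties are resolved deterministically: the
#' traceback prefers staying on the current template, then the
#' lowest-index template (panel 0 templates are listed first).
#'
#' @param query Numeric/integer vector of 0/1 alleles (`NA` = missing) on
#'   one chromosome.
#' @param panel0,panel1 Haplotype matrices (rows = templates, columns =
#'   the same sites as `query`), alleles 0/1/`NA`. Panel 0 is the
#'   first-listed source and wins ties.
#' @param lambda Positive switch penalty.
#' @param missing_cost `"expected"` (default) or `"zero"`; see Details.
#' @return List: `labels` (0/1 per site), `path` (template index per site),
#'   `cost` (optimal path cost), `n_switches`.
#' @export
paint_haplotype <- function(query, panel0, panel1, lambda,
                            missing_cost = c("expected", "zero")) {
  missing_cost <- match.arg(missing_cost)
  stopifnot(lambda > 0)
  if (is.null(dim(panel0)) || nrow(panel0) == 0 ||
      is.null(dim(panel1)) || nrow(panel1) == 0)
    stop("both panels need at least one haplotype")
  if (ncol(panel0) != length(query) || ncol(panel1) != length(query))
    stop("query and panels must share the site list")
  H <- rbind(panel0, panel1)
  K0 <- nrow(panel0)
  K <- nrow(H)
  T_ <- length(query)
  M <- mismatch_costs(query, H, K0, missing_cost)
  switched <- matrix(FALSE, T_, K)
  best_prev <- integer(T_)
  C <- M[, 1]
  for (t in seq_len(T_)[-1]) {
    b <- which.min(C)                      # lowest index on ties
    sw <- C[b] + lambda
    stay <- C
    switched[t, ] <- sw < stay             # strict: prefer no-switch on ties
    best_prev[t] <- b
    C <- M[, t] + pmin(stay, sw)
  }
  path <- integer(T_)
  path[T_] <- which.min(C)
  if (T_ > 1) for (t in T_:2) {
    path[t - 1] <- if (switched[t, path[t]]) best_prev[t] else path[t]
  }
  labels <- as.integer(path > K0)
  list(labels = labels, path = path, cost = min(C),
       n_switches = sum(diff(path) != 0))
}

# K x T matrix of per-site copying costs. Query-missing sites cost 0 for
# every template. Template-missing entries cost 0 ("zero") or the expected
# mismatch against the template's own panel frequency ("expected"); a
# panel column with no data at all scores 0.5.
mismatch_costs <- function(query, H, K0, missing_cost) {
  K <- nrow(H); T_ <- length(query)
  Q <- matrix(query, K, T_, byrow = TRUE)
  M <- H != Q
  M[is.na(M)] <- FALSE
  mode(M) <- "double"
  if (missing_cost == "expected") {
    f0 <- colMeans(H[seq_len(K0), , drop = FALSE], na.rm = TRUE)
    f1 <- colMeans(H[-seq_len(K0), , drop = FALSE], na.rm = TRUE)
    f0[is.nan(f0)] <- 0.5
    f1[is.nan(f1)] <- 0.5
    F_ <- rbind(matrix(f0, K0, T_, byrow = TRUE),
                matrix(f1, K - K0, T_, byrow = TRUE))
    fill <- is.na(H) & !is.na(Q)
    exp_m <- Q * (1 - F_) + (1 - Q) * F_
    M[fill] <- exp_m[fill]
  }
  M
}

#' Paint a haplotype with a vote over switch penalties
#'
#' The single-penalty painting is sensitive to the choice of `lambda`; the
#' vote aggregates paintings over a small penalty grid and takes the
#' per-site majority label. Vote ties are assigned to source 0 (the
#' first-listed panel) and counted.
#'
#' @inheritParams paint_haplotype
#' @param lambda_set Numeric vector of switch penalties.
#' @return List: `labels`, `n_ties` (sites with a split vote), `votes1`
#'   (per-site count of source-1 votes).
#' @export
paint_with_vote <- function(query, panel0, panel1,
                            lambda_set = c(1.5, 2.5, 3.5, 4.5, 5.5),
                            missing_cost = c("expected", "zero")) {
  missing_cost <- match.arg(missing_cost)
  stopifnot(length(lambda_set) >= 1)
  votes <- vapply(lambda_set, function(l)
    paint_haplotype(query, panel0, panel1, l, missing_cost)$labels,
    integer(length(query)))
  votes1 <- rowSums(as.matrix(votes))
  n <- length(lambda_set)
  labels <- as.integer(votes1 > n / 2)     # ties (votes1 == n/2) -> 0
  list(labels = labels, n_ties = sum(votes1 * 2 == n), votes1 = votes1)
}

#' Paint a set of phased haplotypes chromosome by chromosome
#'
#' Applies [paint_with_vote()] per query haplotype and chromosome; the
#' copying path restarts on each chromosome, so no switch penalty is paid
#' across chromosome boundaries.
#'
#' @param queries Haplotype matrix (rows named `<ind>_h1`/`_h2`).
#' @param panel0,panel1 Reference haplotype matrices on the same sites.
#' @param sites Site table with a `chrom` column, parallel to the columns.
#' @param lambda_set Switch penalty grid.
#' @return Object of class `ancestry_painting`: `labels` (0/1 matrix,
#'   haplotypes x sites), `sites`, `n_ties`, `lambda_set`.
#' @export
paint_haplotypes <- function(queries, panel0, panel1, sites,
                             lambda_set = c(1.5, 2.5, 3.5, 4.5, 5.5),
                             missing_cost = c("expected", "zero")) {
  missing_cost <- match.arg(missing_cost)
  stopifnot(ncol(queries) == nrow(sites))
  labels <- matrix(NA_integer_, nrow(queries), ncol(queries),
                   dimnames = list(rownames(queries), NULL))
  n_ties <- 0L
  for (ch in unique(sites$chrom)) {
    ix <- which(sites$chrom == ch)
    p0 <- panel0[, ix, drop = FALSE]
    p1 <- panel1[, ix, drop = FALSE]
    for (h in seq_len(nrow(queries))) {
      pv <- paint_with_vote(queries[h, ix], p0, p1, lambda_set,
                            missing_cost)
      labels[h, ix] <- pv$labels
      n_ties <- n_ties + pv$n_ties
    }
  }
  structure(list(labels = labels, sites = sites, n_ties = n_ties,
                 lambda_set = lambda_set),
            class = "ancestry_painting")
}

#' @export
print.ancestry_painting <- function(x, ...) {
  cat(sprintf(
    "ancestry_painting: %d haplotypes x %d sites, mean source-1 fraction %.3f\n",
    nrow(x$labels), ncol(x$labels), mean(x$labels)))
  invisible(x)
}

#' Genome-wide inferred ancestry fractions
#'
#' @param painting An `ancestry_painting`.
#' @param by `"haplotype"` or `"individual"` (mean over the `_h1`/`_h2`
#'   pair).
#' @return Data frame with the fraction of sites labelled source 1.
#' @export
painting_fractions <- function(painting,
                               by = c("individual", "haplotype")) {
  by <- match.arg(by)
  fr <- rowMeans(painting$labels)
  out <- data.frame(haplotype = rownames(painting$labels),
                    frac1 = unname(fr), stringsAsFactors = FALSE)
  if (by == "individual") {
    ind <- sub("_h[12]$", "", out$haplotype)
    fr2 <- tapply(out$frac1, ind, mean)
    out <- data.frame(individual = names(fr2), frac1 = as.numeric(fr2),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build in-silico recombinants of known 50/50 ancestry
#'
#' Pairs the i-th parent of each set and, per chromosome, splits at the
#' site-count midpoint, producing the two complementary products
#' (A-first-half/B-second-half and B-first-half/A-second-half). Each pair
#' therefore yields two recombinant haplotypes whose per-chromosome true
#' ancestry is exactly half A and half B (up to one site on odd counts).
#' Parents enter through their first haplotype.
#'
#' @param parents_a,parents_b Phased parent haplotype matrices (two
#'   consecutive rows per individual, `_h1` first); equal numbers of
#'   individuals, shared site list. Set A is source 0.
#' @param sites Site table with `chrom`.
#' @return List: `haps` (recombinant haplotype matrix, rows
#'   `REC<i>a`/`REC<i>b`), `truth_labels` (0/1 matrix of the same shape),
#'   `pairs` (which parents formed each recombinant).
#' @export
make_recombinants <- function(parents_a, parents_b, sites) {
  if (is.null(dim(parents_a)) || is.null(dim(parents_b)) ||
      nrow(parents_a) == 0 || nrow(parents_b) == 0)
    stop("parent sets must be non-empty haplotype matrices")
  ha <- parents_a[grepl("_h1$", rownames(parents_a)), , drop = FALSE]
  hb <- parents_b[grepl("_h1$", rownames(parents_b)), , drop = FALSE]
  if (nrow(ha) == 0) ha <- parents_a[seq(1, nrow(parents_a), 2), , drop = FALSE]
  if (nrow(hb) == 0) hb <- parents_b[seq(1, nrow(parents_b), 2), , drop = FALSE]
  if (nrow(ha) != nrow(hb)) stop("parent counts differ")
  stopifnot(ncol(ha) == nrow(sites), ncol(hb) == nrow(sites))
  n_pair <- nrow(ha)
  first_half <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    ix <- which(sites$chrom == ch)
    first_half[ix[seq_len(floor(length(ix) / 2))]] <- TRUE
  }
  haps <- matrix(NA_integer_, 2L * n_pair, nrow(sites))
  truth <- matrix(NA_integer_, 2L * n_pair, nrow(sites))
  nm <- character(2L * n_pair)
  for (i in seq_len(n_pair)) {
    r1 <- ifelse(first_half, ha[i, ], hb[i, ])
    r2 <- ifelse(first_half, hb[i, ], ha[i, ])
    haps[2 * i - 1, ] <- r1
    haps[2 * i, ] <- r2
    truth[2 * i - 1, ] <- as.integer(!first_half)
    truth[2 * i, ] <- as.integer(first_half)
    nm[2 * i - 1] <- sprintf("REC%da", i)
    nm[2 * i] <- sprintf("REC%db", i)
  }
  rownames(haps) <- nm
  rownames(truth) <- nm
  pairs <- data.frame(recombinant = nm,
                      parent_a = rep(rownames(ha), each = 2),
                      parent_b = rep(rownames(hb), each = 2),
                      stringsAsFactors = FALSE)
  list(haps = haps, truth_labels = truth, pairs = pairs)
}

#' Calibrate the ancestry estimator on recombinants of known truth
#'
#' Compares a painting of recombinant haplotypes with their known labels and
#' summarizes the systematic under- or over-estimation of source-1 ancestry
#' as a single multiplicative factor, `bias_factor = mean(true source-1
#' fraction) / mean(inferred source-1 fraction)`, the ratio of means across
#' recombinants. Corrected fractions are `min(1, inferred * bias_factor)`.
#'
#' @param truth_labels 0/1 matrix of true per-site labels (haplotypes x
#'   sites).
#' @param painting An `ancestry_painting` of the same haplotypes, or a 0/1
#'   label matrix.
#' @return List of class `calibration_result`: `bias_factor`, `per_hap`
#'   (true, inferred, corrected fractions), `site_accuracy`, `mean_abs_err`
#'   (mean absolute per-haplotype fraction error), `confusion` (2x2 site
#'   counts).
#' @export
calibrate_bias <- function(truth_labels, painting) {
  inf <- if (inherits(painting, "ancestry_painting")) painting$labels
  else painting
  stopifnot(all(dim(truth_labels) == dim(inf)))
  if (!is.null(rownames(inf)) && !is.null(rownames(truth_labels)))
    inf <- inf[rownames(truth_labels), , drop = FALSE]
  t_fr <- rowMeans(truth_labels)
  i_fr <- rowMeans(inf)
  mean_inf <- mean(i_fr)
  bias <- if (mean_inf > 0) mean(t_fr) / mean_inf else NA_real_
  if (is.na(bias)) warning("mean inferred source-1 fraction is 0; ",
                           "bias factor undefined")
  per_hap <- data.frame(
    haplotype = rownames(truth_labels), true_frac = t_fr,
    inferred_frac = i_fr,
    corrected_frac = if (is.na(bias)) NA_real_ else pmin(1, i_fr * bias),
    stringsAsFactors = FALSE)
  rownames(per_hap) <- NULL
  confusion <- table(factor(truth_labels, levels = 0:1),
                     factor(inf, levels = 0:1), dnn = c("true", "inferred"))
  structure(list(
    bias_factor = bias, per_hap = per_hap,
    site_accuracy = mean(truth_labels == inf),
    mean_abs_err = mean(abs(t_fr - i_fr)),
    confusion = confusion), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: bias factor %.3f, site accuracy %.3f (%d recombinants)\n",
    x$bias_factor, x$site_accuracy, nrow(x$per_hap)))
  invisible(x)
}

#' Per-individual ancestry report with bias correction
#'
#' @param painting An `ancestry_painting` of the admixed haplotypes.
#' @param bias_factor Multiplicative correction from [calibrate_bias()]
#'   (default 1 = no correction). Corrected fractions are capped at 1.
#' @return List: `individuals` (raw/corrected genome-wide fractions and
#'   per-chromosome raw fractions), `group` (mean, min, max of raw and
#'   corrected fractions).
#' @export
ancestry_report <- function(painting, bias_factor = 1) {
  fr <- painting_fractions(painting, by = "individual")
  fr$corrected_frac1 <- pmin(1, fr$frac1 * bias_factor)
  chroms <- unique(painting$sites$chrom)
  ind <- sub("_h[12]$", "", rownames(painting$labels))
  per_chrom <- sapply(chroms, function(ch) {
    ix <- painting$sites$chrom == ch
    tapply(rowMeans(painting$labels[, ix, drop = FALSE]), ind, mean)[fr$individual]
  })
  per_chrom <- matrix(per_chrom, nrow = nrow(fr),
                      dimnames = list(fr$individual, chroms))
  grp <- data.frame(
    statistic = c("mean", "min", "max"),
    raw = c(mean(fr$frac1), min(fr$frac1), max(fr$frac1)),
    corrected = c(mean(fr$corrected_frac1), min(fr$corrected_frac1),
                  max(fr$corrected_frac1)))
  list(individuals = cbind(fr, per_chrom), group = grp,
       bias_factor = bias_factor)
}

#' Ancestry calls at gene intervals
#'
#' For each individual and interval, the fraction of painted sites falling
#' in the interval (both haplotypes pooled) that carry the source-1 label;
#' the interval is called source 0 below `lo`, source 1 above `hi`, mixed
#' in between, and flagged undefined when it contains no painted site.
#'
#' @param painting An `ancestry_painting`.
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based,
#'   inclusive) and optionally `name`.
#' @param lo,hi Call thresholds (defaults 0.25 and 0.75).
#' @return Data frame: interval name, individual, n_sites, frac1, call
#'   (`"source0"`, `"source1"`, `"mixed"`, `NA` when no sites).
#' @export
locus_ancestry <- function(painting, intervals, lo = 0.25, hi = 0.75) {
  if (is.null(intervals$name))
    intervals$name <- sprintf("%s:%d-%d", intervals$chrom,
                              intervals$start, intervals$end)
  ind <- sub("_h[12]$", "", rownames(painting$labels))
  inds <- unique(ind)
  rows <- list()
  for (r in seq_len(nrow(intervals))) {
    ix <- which(painting$sites$chrom == intervals$chrom[r] &
                  painting$sites$pos >= intervals$start[r] &
                  painting$sites$pos <= intervals$end[r])
    for (id in inds) {
      hx <- which(ind == id)
      if (!length(ix)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = intervals$name[r], individual = id, n_sites = 0L,
          frac1 = NA_real_, call = NA_character_, stringsAsFactors = FALSE)
        next
      }
      f <- mean(painting$labels[hx, ix])
      call <- if (f < lo) "source0" else if (f > hi) "source1" else "mixed"
      rows[[length(rows) + 1L]] <- data.frame(
        name = intervals$name[r], individual = id,
        n_sites = length(ix), frac1 = f, call = call,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Impute missing haplotype alleles from the merged sample majority
#'
#' Fills each missing allele with the major allele at that site across a
#' pooled set of haplotype matrices, mimicking the crudest effect of
#' imputing a merged panel in which densely genotyped groups dominate:
#' sparsely genotyped haplotypes are pulled toward the majority of the
#' merged sample. Provided for emulating pipelines that impute the merged
#' matrix before painting. Note that the default painting pipeline does
#' not impute; it scores missing template alleles at their expected
#' mismatch instead (see [paint_haplotype()]), which keeps sparse panels
#' honestly priced without inventing consensus haplotypes.
#'
#' @param haps_list Named list of 0/1/`NA` haplotype matrices sharing a
#'   site list.
#' @return The list with every `NA` replaced by the pooled major allele
#'   (ties go to 0).
#' @export
impute_major <- function(haps_list) {
  pool <- do.call(rbind, haps_list)
  freq <- colMeans(pool, na.rm = TRUE)
  major <- as.integer(!is.na(freq) & freq > 0.5)
  lapply(haps_list, function(h) {
    idx <- which(is.na(h), arr.ind = TRUE)
    if (nrow(idx)) h[idx] <- major[idx[, 2]]
    h
  })
}
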