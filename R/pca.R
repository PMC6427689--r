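#' PCA of genotypes with projection of non-core samples
#'
#' Computes principal axes from a "core" sample set only (typically the
#' deeply sequenced panel) and projects the remaining samples onto those
#' axes. Per-site means and the optional Patterson scaling
#' `sqrt(p (1 - p))` are estimated from the core's non-missing calls;
#' missing calls (core and projected alike) are mean-imputed before
#' centering. Axis signs are fixed by forcing each axis' largest-magnitude
#' loading to be positive.
#'
#' @param m A [genotype_matrix()].
#' @param core Character vector of core sample names (non-empty).
#' @param k Number of axes to retain; must be `<= min(|core| - 1, n_sites)`.
#' @param scale `"patterson"` (default) or `"none"` (plain centering).
#' @return A list of class `pc_coords`: `scores` (all samples x k),
#'   `explained` (variance fractions, non-increasing), `core` (the fitting
#'   samples), `n_dropped` (sites unusable in the fit).
#' @export
pca_fit_project <- function(m, core, k = 10L,
                            scale = c("patterson", "none")) {
  scale <- match.arg(scale)
  if (length(core) == 0) stop("core sample set is empty")
  miss <- setdiff(core, sample_names(m))
  if (length(miss)) stop("core samples absent: ", paste(miss, collapse = ", "))
  if (k > min(length(core) - 1L, n_sites(m)))
    stop("k exceeds min(|core| - 1, number of sites)")
  X <- m$calls
  Xc <- X[core, , drop = FALSE]
  mu <- colMeans(Xc, na.rm = TRUE)
  usable <- !is.nan(mu)
  p_hat <- mu / 2
  sdv <- if (scale == "patterson") sqrt(p_hat * (1 - p_hat)) else
    rep(1, length(mu))
  usable <- usable & sdv > 0
  n_dropped <- sum(!usable)
  if (!any(usable)) stop("no usable sites for the PCA fit")
  X <- X[, usable, drop = FALSE]
  mu <- mu[usable]; sdv <- sdv[usable]
  if (k > ncol(X)) stop("k exceeds the number of usable sites")
  # mean-imputation, centering, scaling (core statistics for everyone)
  Z <- sweep(X, 2, mu, check.margin = FALSE)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sdv, "/", check.margin = FALSE)
  Zc <- Z[core, , drop = FALSE]
  sv <- svd(Zc, nu = 0, nv = k)
  d2 <- sv$d^2
  if (d2[1] < 1e-12) stop("core samples have zero variance; PCA undefined")
  V <- sv$v
  # deterministic axis orientation
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Z %*% V
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = scores,
    explained = d2[seq_len(k)] / sum(d2),
    core = core,
    n_dropped = n_dropped
  ), class = "pc_coords")
}

#' @export
print.pc_coords <- function(x, ...) {
  cat(sprintf("pc_coords: %d samples x %d axes (%.1f%% variance explained)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$explained)))
  invisible(x)
}

#' Select typical group representatives on PC coordinates
#'
#' For each group, a sample is kept iff on every one of the top `n_pcs` axes
#' its score lies within one standard deviation of the group median
#' (inclusive). This extracts "typical" members rather than maximizing
#' within-group diversity, trimming intermediate and misassigned accessions.
#'
#' @param coords A `pc_coords` object.
#' @param groups A `group_map` over (a subset of) the scored samples.
#' @param n_pcs Number of leading axes to test (default 10).
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n).
#' @return A list: `kept` (named list of sample vectors per group) and
#'   `summary` (per-group input/kept counts).
#' @export
select_representatives <- function(coords, groups, n_pcs = 10L,
                                   sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n_pcs <- min(n_pcs, ncol(coords$scores))
  sc <- coords$scores[, seq_len(n_pcs), drop = FALSE]
  missing <- setdiff(groups$sample, rownames(sc))
  if (length(missing))
    stop("group map labels unscored samples: ", paste(missing, collapse = ", "))
  kept <- list()
  summ <- list()
  for (g in sort(unique(groups$group))) {
    ss <- group_samples(groups, g)
    gs <- sc[ss, , drop = FALSE]
    if (length(ss) == 1L) {
      warning("group '", g, "' has a single member; kept trivially")
      kept[[g]] <- ss
      summ[[g]] <- data.frame(group = g, n_in = 1L, n_kept = 1L)
      next
    }
    med <- apply(gs, 2, stats::median)
    sdv <- apply(gs, 2, stats::sd)
    if (sd_type == "population")
      sdv <- sdv * sqrt((nrow(gs) - 1) / nrow(gs))
    ok <- rep(TRUE, nrow(gs))
    for (j in seq_len(ncol(gs)))
      ok <- ok & abs(gs[, j] - med[j]) <= sdv[j]
    kept[[g]] <- ss[ok]
    summ[[g]] <- data.frame(group = g, n_in = length(ss), n_kept = sum(ok))
  }
  list(kept = kept, summary = do.call(rbind, summ))
}
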