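# Independent oracles and small fixture builders shared across tests.

# quick genotype_matrix from a plain matrix; default sites on one chromosome
gm_fix <- function(calls, chrom = "chr1", pos = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 100L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites)
}

write_vcf_fix <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# brute-force copying-model optimum: enumerate every path through the
# template union and take the minimum cost; mismatch rules mirrored
# independently of the package internals
brute_paint <- function(query, panel0, panel1, lambda,
                        missing_cost = "expected") {
  H <- rbind(panel0, panel1)
  K <- nrow(H); T_ <- length(query)
  f <- c(rep(NA, K))
  f0 <- colMeans(panel0, na.rm = TRUE); f0[is.nan(f0)] <- 0.5
  f1 <- colMeans(panel1, na.rm = TRUE); f1[is.nan(f1)] <- 0.5
  cost_at <- function(t, k) {
    a <- H[k, t]; q <- query[t]
    if (is.na(q)) return(0)
    if (is.na(a)) {
      if (missing_cost == "zero") return(0)
      fr <- if (k <= nrow(panel0)) f0[t] else f1[t]
      return(if (q == 1) 1 - fr else fr)
    }
    as.numeric(a != q)
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  best <- Inf
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    cst <- sum(vapply(seq_len(T_), function(t) cost_at(t, pth[t]),
                      numeric(1))) +
      lambda * sum(diff(pth) != 0)
    if (cst < best) best <- cst
  }
  best
}

# scalar per-site Weir-Cockerham (1984) two-population theta components,
# written from the published formulas with explicit loops
wc_oracle_site <- function(geno_a, geno_b) {
  ga <- geno_a[!is.na(geno_a)]; gb <- geno_b[!is.na(geno_b)]
  n1 <- length(ga); n2 <- length(gb)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 2) return(c(a = 0, d = 0))
  p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
  h1 <- sum(ga == 1) / n1; h2 <- sum(gb == 1) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  if (nbar <= 1) return(c(a = 0, d = 0))
  nc <- (n1 + n2 - (n1 ^ 2 + n2 ^ 2) / (n1 + n2)) / (r - 1)
  if (nc <= 0) return(c(a = 0, d = 0))
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar) ^ 2 + n2 * (p2 - pbar) ^ 2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, d = a + b + cc)
}

# per-site nucleotide diversity by explicit pair counting over the allele
# pool
pi_oracle_site <- function(geno) {
  g <- geno[!is.na(geno)]
  alleles <- unlist(lapply(g, function(d) c(rep(1, d), rep(0, 2 - d))))
  n <- length(alleles)
  if (n < 2) return(0)
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diffs <- diffs + (alleles[i] != alleles[j])
  diffs / choose(n, 2)
}

# exhaustive largest-gap scan used to check detect_elevated
gap_oracle <- function(v, min_gap = 0.05, min_group = 2) {
  v <- sort(v)
  n <- length(v)
  best <- NULL
  for (i in seq_len(n - 1)) {
    gap <- v[i + 1] - v[i]
    if (gap < min_gap) next
    if (v[i + 1] < (min(v) + max(v)) / 2) next
    if (n - i < min_group) next
    if (is.null(best) || gap > best$gap)
      best <- list(gap = gap, thr = (v[i] + v[i + 1]) / 2)
  }
  best
}

# minimum-spanning-tree cost by Kruskal with an independent union-find
mst_oracle <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(0)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ed <- which(upper.tri(D), arr.ind = TRUE)
  ed <- ed[order(D[ed]), , drop = FALSE]
  cost <- 0
  for (r in seq_len(nrow(ed))) {
    a <- find(ed[r, 1]); b <- find(ed[r, 2])
    if (a != b) {
      parent[a] <- b
      cost <- cost + D[ed[r, 1], ed[r, 2]]
    }
  }
  cost
}

# small cached default-scenario study shared by acceptance tests
study_cache <- new.env()
default_study <- function() {
  if (is.null(study_cache$st))
    study_cache$st <- simulate_study(sim_params(seed = 1))
  study_cache$st
}

hamming_matrix_test <- function(h) {
  n <- nrow(h)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum(h[i, ] != h[j, ])
    D[i, j] <- d; D[j, i] <- d
  }
  D
}
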