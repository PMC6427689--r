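#' Extract variable columns from a haplotype alignment
#'
#' Recodes gaps and ambiguity characters as missing and keeps the columns
#' whose minor-state frequency among non-missing entries exceeds `min_freq`
#' (the minor-state frequency is one minus the most frequent state's
#' frequency). Column order is preserved.
#'
#' @param alignment Character matrix (samples x positions) or an `ape`
#'   `DNAbin` alignment; rows named by sample.
#' @param min_freq Minimum minor-state frequency (default 0.005).
#' @param missing_chars Characters treated as missing (gaps, Ns).
#' @return Character matrix of retained columns (uppercase bases, `NA` for
#'   missing) with attribute `positions` giving original column indices.
#' @export
extract_variants <- function(alignment, min_freq = 0.005,
                             missing_chars = c("-", "N", "?", ".")) {
  aln <- as_char_alignment(alignment)
  if (nrow(aln) == 0 || ncol(aln) == 0) stop("empty alignment")
  aln[aln %in% missing_chars] <- NA_character_
  minor <- apply(aln, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(0)
    1 - max(table(col)) / length(col)
  })
  keep <- which(minor > min_freq)
  out <- aln[, keep, drop = FALSE]
  attr(out, "positions") <- keep
  out
}

as_char_alignment <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- as.character(as.matrix(alignment))
  aln <- toupper(as.matrix(alignment))
  if (nrow(aln) == 0 || ncol(aln) == 0) stop("empty alignment")
  if (is.null(rownames(aln)))
    rownames(aln) <- paste0("S", seq_len(nrow(aln)))
  aln
}

#' Collapse aligned samples into distinct haplotypes
#'
#' Samples with identical complete profiles share a haplotype. A sample with
#' missing entries is assigned to the most frequent complete haplotype
#' compatible with its non-missing entries; samples with no compatible
#' complete haplotype get a new profile with missing entries filled by the
#' column majority state. Haplotypes are named `H01, H02, ...` by descending
#' final membership (ties broken lexicographically by profile).
#'
#' @param hm Character matrix from [extract_variants()] (`NA` = missing).
#' @return List: `haplotypes` (character matrix, one row per haplotype),
#'   `assignment` (data frame sample -> haplotype), `counts` (named member
#'   counts).
#' @export
collapse_haplotypes <- function(hm) {
  prof_str <- function(mat) apply(mat, 1, paste, collapse = "|")
  complete <- !apply(hm, 1, anyNA)
  profiles <- list(); members <- list()
  if (any(complete)) {
    keys <- prof_str(hm[complete, , drop = FALSE])
    for (u in unique(keys)) {
      profiles[[length(profiles) + 1L]] <-
        hm[complete, , drop = FALSE][match(u, keys), ]
      members[[length(members) + 1L]] <- rownames(hm)[complete][keys == u]
    }
  }
  counts0 <- lengths(members)
  maj_fill <- apply(hm, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]
  })
  for (s in rownames(hm)[!complete]) {
    v <- hm[s, ]
    obs <- !is.na(v)
    compat <- which(vapply(profiles, function(p)
      all(p[obs] == v[obs]), logical(1)))
    if (length(compat)) {
      # most frequent compatible; ties by lexicographic profile
      ord <- order(-counts0[compat],
                   vapply(profiles[compat], paste, collapse = "|", ""))
      pick <- compat[ord[1]]
      members[[pick]] <- c(members[[pick]], s)
    } else {
      filled <- ifelse(obs, v, maj_fill)
      key <- paste(filled, collapse = "|")
      existing <- match(key, vapply(profiles, paste, collapse = "|", ""))
      if (!is.na(existing)) {
        members[[existing]] <- c(members[[existing]], s)
      } else {
        profiles[[length(profiles) + 1L]] <- filled
        members[[length(members) + 1L]] <- s
        counts0 <- c(counts0, 0L)
      }
    }
  }
  n_mem <- lengths(members)
  keys <- vapply(profiles, paste, collapse = "|", "")
  ord <- order(-n_mem, keys)
  profiles <- profiles[ord]; members <- members[ord]
  hap_names <- sprintf("H%02d", seq_along(profiles))
  hap_mat <- do.call(rbind, profiles)
  rownames(hap_mat) <- hap_names
  assignment <- data.frame(
    sample = unlist(members),
    haplotype = rep(hap_names, lengths(members)),
    stringsAsFactors = FALSE)
  counts <- lengths(members)
  names(counts) <- hap_names
  list(haplotypes = hap_mat, assignment = assignment, counts = counts)
}

hamming_matrix <- function(h) {
  n <- nrow(h)
  D <- matrix(0L, n, n, dimnames = list(rownames(h), rownames(h)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum(h[i, ] != h[j, ])
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

# epsilon-relaxed minimum spanning network: an edge (i, j) belongs to the
# network iff d(i, j) <= (weight level at which i and j first become
# connected in the level-by-level Kruskal process) + epsilon.
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n == 1L) return(data.frame(from = integer(0), to = integer(0),
                                 weight = integer(0)))
  M <- matrix(Inf, n, n)
  comp <- seq_len(n)
  for (w in sort(unique(D[upper.tri(D)]))) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (D[i, j] == w && comp[i] != comp[j])
        comp[comp == comp[j]] <- comp[i]
    newly <- outer(comp, comp, "==") & !is.finite(M)
    M[newly] <- w
    if (length(unique(comp)) == 1L && all(is.finite(M[upper.tri(M)]))) break
  }
  sel <- which(upper.tri(D) & D <= M + epsilon, arr.ind = TRUE)
  data.frame(from = sel[, 1], to = sel[, 2],
             weight = D[sel], stringsAsFactors = FALSE)
}

mst_cost <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  # Prim
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  cost <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + unname(best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  cost
}

col_median_vector <- function(a, b, c) {
  out <- a
  disagree <- !(a == b & b == c)
  for (i in which(disagree)) {
    states <- c(a[i], b[i], c[i])
    tab <- table(states)
    if (max(tab) >= 2) out[i] <- names(tab)[which.max(tab)]
    else out[i] <- a[i]  # all three distinct: keep the first profile's state
  }
  out
}

#' Median-joining network of haplotypes
#'
#' Builds a median-joining network in the spirit of Bandelt, Forster and
#' Roehl: starting from the epsilon-relaxed minimum spanning network under
#' Hamming distance, candidate median (Steiner) vectors -- column-wise
#' majorities of triplets around network links -- are added greedily
#' whenever they strictly reduce the spanning cost of the node set, until no
#' candidate helps; median nodes of degree <= 2 whose removal leaves the
#' spanning cost unchanged are pruned. All columns are weighted equally and
#' ties are broken lexicographically on profile strings, so the result is
#' deterministic.
#'
#' @param haplotypes Character (or integer) matrix of complete haplotype
#'   profiles, one row per haplotype, rows named.
#' @param epsilon Relaxation of the minimum spanning network (default 0).
#' @return A list of class `mj_network`: `graph` (an `igraph` with vertex
#'   attributes `name` and `type` = observed/median and edge attribute
#'   `weight`), `nodes` (profile matrix incl. medians), `edges` (data
#'   frame), `cost` (spanning cost over all nodes), `mst_cost_observed`.
#' @export
median_joining <- function(haplotypes, epsilon = 0) {
  h <- as.matrix(haplotypes)
  mode(h) <- "character"
  if (is.null(rownames(h))) rownames(h) <- paste0("H", seq_len(nrow(h)))
  if (anyNA(h)) stop("median-joining needs complete haplotype profiles")
  n_obs <- nrow(h)
  mst_obs <- mst_cost(hamming_matrix(h))
  nodes <- h
  n_median <- 0L
  repeat {
    D <- hamming_matrix(nodes)
    ed <- msn_edges(D, epsilon)
    cur_cost <- mst_cost(D)
    # candidate triples: a linked pair (u, v) plus a neighbour of either
    adj <- lapply(seq_len(nrow(nodes)), function(i)
      unique(c(ed$to[ed$from == i], ed$from[ed$to == i])))
    cand <- list()
    for (e in seq_len(nrow(ed))) {
      u <- ed$from[e]; v <- ed$to[e]
      for (w in setdiff(unique(c(adj[[u]], adj[[v]])), c(u, v))) {
        med <- col_median_vector(nodes[u, ], nodes[v, ], nodes[w, ])
        key <- paste(med, collapse = "|")
        if (!key %in% vapply(cand, function(x) x$key, "") &&
            !key %in% apply(nodes, 1, paste, collapse = "|"))
          cand[[length(cand) + 1L]] <- list(key = key, vec = med)
      }
    }
    if (!length(cand)) break
    deltas <- vapply(cand, function(x) {
      dvec <- colSums(t(nodes) != x$vec)
      D2 <- rbind(cbind(D, dvec), c(dvec, 0))
      mst_cost(D2) - cur_cost
    }, numeric(1))
    ord <- order(deltas, vapply(cand, function(x) x$key, ""))
    if (deltas[ord[1]] >= 0) break
    n_median <- n_median + 1L
    new <- matrix(cand[[ord[1]]]$vec, nrow = 1,
                  dimnames = list(sprintf("MV%d", n_median), NULL))
    nodes <- rbind(nodes, new)
  }
  # prune useless medians of degree <= 2
  repeat {
    D <- hamming_matrix(nodes)
    ed <- msn_edges(D, epsilon)
    cost <- mst_cost(D)
    deg <- tabulate(c(ed$from, ed$to), nbins = nrow(nodes))
    drop <- NA_integer_
    for (i in seq_len(nrow(nodes))) {
      if (i <= n_obs || deg[i] > 2L) next
      if (nrow(nodes) > 1L &&
          mst_cost(D[-i, -i, drop = FALSE]) <= cost) { drop <- i; break }
    }
    if (is.na(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
  }
  D <- hamming_matrix(nodes)
  ed <- msn_edges(D, epsilon)
  edges <- data.frame(from = rownames(nodes)[ed$from],
                      to = rownames(nodes)[ed$to],
                      weight = ed$weight, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(
      name = rownames(nodes),
      type = ifelse(seq_len(nrow(nodes)) <= n_obs, "observed", "median")))
  structure(list(graph = g, nodes = nodes, edges = edges,
                 cost = mst_cost(D), mst_cost_observed = mst_obs),
            class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf(
    "mj_network: %d nodes (%d median), %d edges, spanning cost %g (MST over observed: %g)\n",
    nrow(x$nodes), sum(igraph::V(x$graph)$type == "median"),
    nrow(x$edges), x$cost, x$mst_cost_observed))
  invisible(x)
}

#' Per-group haplotype frequencies
#'
#' @param assignment Data frame sample -> haplotype from
#'   [collapse_haplotypes()].
#' @param groups A `group_map` covering the assigned samples.
#' @return Data frame: haplotype, group, count, group size, percent.
#' @export
group_haplotype_freqs <- function(assignment, groups) {
  miss <- setdiff(assignment$sample, groups$sample)
  if (length(miss))
    stop("unassigned group for samples: ", paste(utils::head(miss, 5), collapse = ", "))
  grp <- groups$group[match(assignment$sample, groups$sample)]
  gsize <- table(groups$group)
  tab <- table(assignment$haplotype, grp)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("haplotype", "group", "count")
  out$group_size <- as.integer(gsize[out$group])
  out$percent <- 100 * out$count / out$group_size
  out[order(out$haplotype, out$group), ]
}

#' Intersect nuclear donor candidates with organellar haplotype carriers
#'
#' @param candidates Sample names flagged by nuclear allele-sharing (e.g.
#'   [detect_elevated()]).
#' @param assignment Haplotype assignment data frame.
#' @param focal_haplotypes Haplotype names regarded as the focal (donor)
#'   maternal lineage.
#' @return Character vector of candidate samples carrying a focal
#'   haplotype; empty with a warning if the intersection is empty.
#' @export
integrate_donor_set <- function(candidates, assignment, focal_haplotypes) {
  carriers <- assignment$sample[assignment$haplotype %in% focal_haplotypes]
  out <- intersect(candidates, carriers)
  if (!length(out))
    warning("no candidate carries a focal haplotype; empty donor set")
  out
}
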