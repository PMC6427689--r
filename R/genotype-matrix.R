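#' Construct a genotype matrix
#'
#' The central container of the package: diploid alt-allele dosages for a set
#' of samples at a set of biallelic SNPs. Calls are coded 0/1/2 (count of the
#' alternative allele) with `NA` for missing. Sites are kept sorted by
#' chromosome and position.
#'
#' @param calls Integer matrix, samples in rows, sites in columns. Values in
#'   `{0, 1, 2, NA}`.
#' @param sites Data frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `ref` and `alt` (single nucleotides, `ref != alt`). One row per
#'   column of `calls`.
#' @return An object of class `genotype_matrix` with elements `calls` and
#'   `sites`. Row names of `calls` are the sample identifiers.
#' @export
genotype_matrix <- function(calls, sites) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(
    nrow(sites) == ncol(calls),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    !is.null(rownames(calls))
  )
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample identifiers in genotype matrix")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L) ||
      any(sites$ref == sites$alt))
    stop("sites must be biallelic SNPs with ref != alt")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(sites) <- NULL
  colnames(calls) <- site_key(sites)
  structure(list(calls = calls, sites = sites), class = "genotype_matrix")
}

site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites (%.1f%% missing)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname genotype_matrix
#' @export
n_sites <- function(x) ncol(x$calls)

#' @rdname genotype_matrix
#' @export
sample_names <- function(x) rownames(x$calls)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param samples Character vector of sample names to keep (default: all).
#' @param site_idx Integer/logical index into the site list (default: all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, site_idx = NULL) {
  calls <- x$calls
  sites <- x$sites
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(calls))
    if (length(miss))
      stop("samples not in matrix: ", paste(miss, collapse = ", "))
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(site_idx)) {
    calls <- calls[, site_idx, drop = FALSE]
    sites <- sites[site_idx, , drop = FALSE]
  }
  genotype_matrix(calls, sites)
}

#' Read a sample-to-group assignment table
#'
#' @param path Two-column TSV (sample, group), no header required; a header
#'   line `sample<TAB>group` is tolerated.
#' @return A `group_map`: data frame with columns `sample` and `group`.
#' @export
read_group_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, col.names = c("sample", "group"))
  if (nrow(tab) && identical(tolower(tab$sample[1]), "sample"))
    tab <- tab[-1, , drop = FALSE]
  group_map(tab$sample, tab$group)
}

#' Construct a sample-to-group map
#'
#' @param sample Character vector of sample identifiers (unique).
#' @param group Character vector of group labels, parallel to `sample`.
#' @return Data frame of class `group_map` with columns `sample`, `group`.
#' @export
group_map <- function(sample, group) {
  stopifnot(length(sample) == length(group))
  if (anyDuplicated(sample)) stop("duplicate samples in group map")
  structure(
    data.frame(sample = as.character(sample), group = as.character(group),
               stringsAsFactors = FALSE),
    class = c("group_map", "data.frame")
  )
}

#' Samples belonging to a group
#'
#' @param groups A `group_map`.
#' @param g Group label(s).
#' @return Character vector of sample names.
#' @export
group_samples <- function(groups, g) groups$sample[groups$group %in% g]

#' Check a group map against a genotype matrix
#'
#' Errors if any labelled sample is absent from the matrix.
#' @param groups A `group_map`.
#' @param m A `genotype_matrix`.
#' @return Invisibly, `groups`.
#' @export
validate_group_map <- function(groups, m) {
  miss <- setdiff(groups$sample, sample_names(m))
  if (length(miss))
    stop("group map labels samples absent from the matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  invisible(groups)
}
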