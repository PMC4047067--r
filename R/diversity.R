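#' Haplotype (gene) diversity
#'
#' Nei's unbiased gene diversity,
#' \deqn{H = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big),}
#' with its sampling standard deviation from Nei (1987, eq. 8.12):
#' \deqn{V(H) = \frac{2}{n(n-1)}\Big\{2(n-2)\big[\sum p_i^3 - (\sum p_i^2)^2\big]
#'   + \sum p_i^2 - (\sum p_i^2)^2\Big\}.}
#'
#' @param counts positive integer vector of haplotype counts.
#' @return list with `H` and `SD`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts <= 0) || any(counts != round(counts))) stop("counts must be positive integers")
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs at least 2 sequences")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(H = H, SD = sqrt(max(V, 0)))
}

#' Nucleotide diversity
#'
#' Per-site nucleotide diversity
#' \deqn{\pi = \frac{1}{L}\binom{n}{2}^{-1}\sum_{i<j} d_{ij},}
#' the mean number of pairwise differences (pairwise deletion of missing
#' bases, see [pairwise_diff_matrix()]) divided by the comparable length
#' `L`. The standard deviation is the square root of the no-recombination
#' sampling variance of Nei (1987, eq. 10.7), the estimator used by the
#' classic popgen packages:
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\,\pi + \frac{2(n^2+n+3)}{9n(n-1)}\,\pi^2.}
#'
#' @param aln an `mt_alignment` (at least two sequences).
#' @param L normalising length; defaults to the post-masking column count.
#' @return list with `pi`, `SD`, and `mean_pairwise_diff`.
#' @export
nucleotide_diversity <- function(aln, L = ncol(aln$bases)) {
  stopifnot(inherits(aln, "mt_alignment"))
  n <- nrow(aln$bases)
  if (n < 2) stop("nucleotide diversity needs at least 2 sequences")
  if (L <= 0) stop("L must be positive")
  d <- pairwise_diff_matrix(aln)$values
  k <- mean(d[upper.tri(d)])
  pi <- k / L
  V <- (n + 1) / (3 * (n - 1) * L) * pi + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(pi = pi, SD = sqrt(V), mean_pairwise_diff = k)
}

#' Number of segregating sites
#'
#' Columns with at least two distinct non-missing bases.
#'
#' @param aln an `mt_alignment`.
#' @return integer count.
#' @export
segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "mt_alignment"))
  sum(apply(aln$bases, 2, function(col) {
    length(unique(col[col != "N" & col != "-"])) >= 2
  }))
}

#' Per-population diversity table
#'
#' Computes, for every population, the sample size, haplotype count,
#' segregating sites, haplotype diversity (with SD) and nucleotide diversity
#' (with SD) -- the columns of a standard mtDNA survey table.
#'
#' @param aln an `mt_alignment` (masked; residual "N" handled by pairwise
#'   deletion).
#' @param meta metadata data.frame with `sample_id` and `population`.
#' @param L normalising length for nucleotide diversity.
#' @return data.frame, one row per population.
#' @export
diversity_table <- function(aln, meta, L = ncol(aln$bases)) {
  pops <- unique(meta$population[match(aln$sample_ids, meta$sample_id)])
  rows <- lapply(pops, function(p) {
    ids <- meta$sample_id[meta$population == p]
    idx <- which(aln$sample_ids %in% ids)
    sub <- mt_alignment(aln$bases[idx, , drop = FALSE], aln$sample_ids[idx], aln$coord_map)
    ht <- collapse_haplotypes(sub, meta[meta$sample_id %in% sub$sample_ids, ])
    hd <- haplotype_diversity(rowSums(ht$counts))
    nd <- nucleotide_diversity(sub, L)
    data.frame(population = p, N = nrow(sub$bases), n_hap = length(ht$haplotypes),
               S = segregating_sites(sub), seq_div = hd$H, seq_div_sd = hd$SD,
               pi = nd$pi, pi_sd = nd$SD, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Haplotype-sharing summary
#'
#' Classifies haplotypes by their incidence across population groups. In the
#' default `between_populations` mode a haplotype counts as shared within
#' group G when it occurs in at least two distinct populations of G, and as
#' shared between two groups when it occurs in at least one population of
#' each; group totals are haplotypes present in at least one population of
#' the group. The alternative `between_individuals` mode counts a haplotype
#' as shared within a group when at least two individuals of the group carry
#' it, irrespective of population.
#'
#' @param ht a `haplotype_table` from [collapse_haplotypes()].
#' @param grouping named character vector population -> group, covering every
#'   population in `ht`.
#' @param mode sharing definition (see above).
#' @return list with `groups`, per-group `total` and `shared_within`, and a
#'   `shared_between` matrix.
#' @export
sharing_summary <- function(ht, grouping,
                            mode = c("between_populations", "between_individuals")) {
  mode <- match.arg(mode)
  pops <- colnames(ht$counts)
  unknown <- setdiff(pops, names(grouping))
  if (length(unknown)) stop("populations not in grouping: ", paste(unknown, collapse = ", "))
  groups <- unique(grouping[pops])
  inc <- ht$counts > 0                       # haplotype x population incidence
  total <- shared_within <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    cols <- pops[grouping[pops] == g]
    total[g] <- sum(rowSums(inc[, cols, drop = FALSE]) >= 1)
    shared_within[g] <- if (mode == "between_populations")
      sum(rowSums(inc[, cols, drop = FALSE]) >= 2)
    else
      sum(rowSums(ht$counts[, cols, drop = FALSE]) >= 2)
  }
  between <- matrix(0L, length(groups), length(groups), dimnames = list(groups, groups))
  for (a in groups) for (b in groups) if (a != b) {
    ca <- pops[grouping[pops] == a]; cb <- pops[grouping[pops] == b]
    between[a, b] <- sum(rowSums(inc[, ca, drop = FALSE]) >= 1 &
                           rowSums(inc[, cb, drop = FALSE]) >= 1)
  }
  list(groups = groups, total = total, shared_within = shared_within,
       shared_between = between, mode = mode)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from beta quantiles: for `k` successes in `n` trials at
#' level `1 - alpha`, lower = `qbeta(alpha/2, k, n-k+1)` (0 when k = 0) and
#' upper = `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n). This is the interval
#' `binom.test()` reports.
#'
#' @param k successes (vectorised).
#' @param n trials.
#' @param level confidence level, default 0.95.
#' @return data.frame with columns k, n, level, estimate, lower, upper.
#' @export
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n)) stop("need 0 <= k <= n, n >= 1")
  a <- 1 - level
  lower <- ifelse(k == 0, 0, stats::qbeta(a / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, stats::qbeta(1 - a / 2, k + 1, n - k))
  data.frame(k = k, n = n, level = level, estimate = k / n,
             lower = lower, upper = upper)
}
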