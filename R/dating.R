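#' Rho-statistic founder age estimation
#'
#' Under the star-genealogy reading of the rho statistic, rho is the mean
#' number of mutational differences between the sampled sequences and a
#' designated founder haplotype, and its standard error is
#' `sqrt(rho / n)` (lineages accumulate mutations independently, so the
#' total mutation count is treated as Poisson). Multiplying by a linear
#' molecular clock (years per mutation; the canonical full-genome mtDNA
#' clock is 3533 years per mutation) converts rho to an age in years BP,
#' with a 95\% range from `rho +/- 1.96 * sigma`, clipped at zero.
#' Differences are counted with pairwise deletion of missing bases.
#'
#' The founder must be supplied (e.g. the modal haplotype of a starlike
#' cluster); no root inference is attempted. Rate-correction calculators and
#' tree-based rho variants are out of scope.
#'
#' @param aln an `mt_alignment` of the cluster to date (masked).
#' @param founder character vector of bases, same length as the alignment
#'   columns (or a 1-row `mt_alignment`).
#' @param clock_years_per_mutation linear clock, default 3533.
#' @return a `rho_result`: rho, sigma, n, clock, age_bp, age_range_bp.
#' @export
rho_estimate <- function(aln, founder, clock_years_per_mutation = 3533) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (inherits(founder, "mt_alignment")) founder <- founder$bases[1, ]
  founder <- toupper(as.character(founder))
  if (length(founder) != ncol(aln$bases))
    stop("founder length (", length(founder), ") does not match alignment columns (",
         ncol(aln$bases), ")")
  cmp <- aln$bases != matrix(founder, nrow(aln$bases), ncol(aln$bases), byrow = TRUE)
  cmp[aln$bases == "N" | matrix(founder == "N", nrow(aln$bases), ncol(aln$bases),
                                byrow = TRUE)] <- FALSE
  dists <- rowSums(cmp)
  n <- length(dists)
  rho <- mean(dists)
  sigma <- sqrt(rho / n)
  age <- rho * clock_years_per_mutation
  rng <- pmax(0, (rho + c(-1.96, 1.96) * sigma)) * clock_years_per_mutation
  structure(list(rho = rho, sigma = sigma, n = n,
                 clock_years_per_mutation = clock_years_per_mutation,
                 age_bp = age, age_range_bp = rng, distances = dists),
            class = "rho_result")
}

#' @export
print.rho_result <- function(x, ...) {
  cat(sprintf("rho = %.3f +/- %.3f (n = %d); clock %s y/mutation -> %.0f y BP (95%% %.0f-%.0f)\n",
              x$rho, x$sigma, x$n, format(x$clock_years_per_mutation),
              x$age_bp, x$age_range_bp[1], x$age_range_bp[2]))
  invisible(x)
}

#' Per-site clock converted to years per mutation
#'
#' Alternative to the fixed full-genome clock: `1 / (site_rate * L)` years
#' per mutation for an alignment of comparable length `L`.
#'
#' @param L alignment length in bases.
#' @param site_rate substitutions per site per year, default 1.665e-8.
#' @return years per mutation.
#' @export
clock_from_site_rate <- function(L, site_rate = 1.665e-8) {
  if (L <= 0 || site_rate <= 0) stop("L and site_rate must be positive")
  1 / (site_rate * L)
}
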