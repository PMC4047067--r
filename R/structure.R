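# Excoffier-style distance AMOVA: variance components from the nested ANOVA
# of squared inter-individual distances, with unequal-sample-size
# coefficients. Written here because no installed package provides the
# hierarchical decomposition with its three permutation schemes.

# sum of squared deviations within each level of f: sum_l (1/n_l) sum_{i<j in l} d2_ij
.ssd_within <- function(D2, f) {
  tot <- 0
  for (l in levels(f)) {
    idx <- which(f == l)
    tot <- tot + sum(D2[idx, idx]) / (2 * length(idx))
  }
  tot
}

.amova_one_level <- function(D2, pop) {
  pop <- droplevels(as.factor(pop))
  N <- length(pop); P <- nlevels(pop)
  np <- as.numeric(table(pop))
  ssd_t <- sum(D2) / (2 * N)
  ssd_wp <- .ssd_within(D2, pop)
  ssd_ap <- ssd_t - ssd_wp
  sigma_c <- ssd_wp / (N - P)
  n0 <- (N - sum(np^2) / N) / (P - 1)
  sigma_a <- (ssd_ap / (P - 1) - sigma_c) / n0
  list(sigma = c(among_pops = sigma_a, within_pops = sigma_c),
       phi_st = sigma_a / (sigma_a + sigma_c),
       ssd = c(among_pops = ssd_ap, within_pops = ssd_wp, total = ssd_t),
       df = c(P - 1, N - P))
}

.amova_two_level <- function(D2, pop, grp) {
  pop <- droplevels(as.factor(pop)); grp <- droplevels(as.factor(grp))
  N <- length(pop); P <- nlevels(pop); G <- nlevels(grp)
  np <- table(pop)
  pop_grp <- tapply(as.character(grp), pop, function(x) x[1])[levels(pop)]
  ng <- table(grp)
  ssd_t <- sum(D2) / (2 * N)
  ssd_wp <- .ssd_within(D2, pop)
  ssd_wg <- .ssd_within(D2, grp)
  ssd_ap_wg <- ssd_wg - ssd_wp
  ssd_ag <- ssd_t - ssd_wg
  sigma_c <- ssd_wp / (N - P)
  # Excoffier (1992) coefficients for unequal sizes
  sum_np2_by_g <- tapply(as.numeric(np)^2, pop_grp, sum) /
    as.numeric(ng[names(tapply(as.numeric(np)^2, pop_grp, sum))])
  A <- sum(sum_np2_by_g)                       # sum_g (sum_{p in g} n_p^2)/n_g
  n1 <- (N - A) / (P - G)
  n2 <- (A - sum(as.numeric(np)^2) / N) / (G - 1)
  n3 <- (N - sum(as.numeric(ng)^2) / N) / (G - 1)
  sigma_b <- (ssd_ap_wg / (P - G) - sigma_c) / n1
  sigma_a <- (ssd_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c
  list(sigma = c(among_groups = sigma_a, among_pops_within_groups = sigma_b,
                 within_pops = sigma_c),
       phi = c(phi_ct = sigma_a / tot,
               phi_sc = sigma_b / (sigma_b + sigma_c),
               phi_st = (sigma_a + sigma_b) / tot),
       ssd = c(among_groups = ssd_ag, among_pops_within_groups = ssd_ap_wg,
               within_pops = ssd_wp, total = ssd_t),
       df = c(G - 1, P - G, N - P))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical decomposition of squared inter-individual distances into
#' among-group, among-population-within-group, and within-population
#' variance components, with the Phi statistics and their permutation
#' p-values. With `groups = NULL` a one-level design (among/within
#' populations, Phi-ST only) is fitted.
#'
#' Permutation schemes follow the conventional ones: Phi-ST permutes
#' individuals among populations (across the whole dataset), Phi-SC permutes
#' individuals among populations within their group, and Phi-CT permutes
#' whole populations among groups. p-values use the (b + 1)/(m + 1)
#' estimator.
#'
#' @param d a `dist_matrix` of pairwise sequence differences (individuals).
#' @param pops named character vector or factor assigning each sample (in
#'   `d$labels` order, or by name) to a population.
#' @param groups optional named character vector population -> group.
#' @param n_perm number of permutations (0 skips the tests).
#' @return an `amova_result`: variance components, percentages of total,
#'   Phi statistics, permutation p-values and the design description.
#' @export
amova <- function(d, pops, groups = NULL, n_perm = 1000) {
  stopifnot(inherits(d, "dist_matrix"))
  if (!is.null(names(pops))) pops <- pops[d$labels]
  pops <- droplevels(as.factor(as.character(pops)))
  if (length(pops) != length(d$labels)) stop("pops must cover every sample")
  small <- names(which(table(pops) < 2))
  if (length(small)) stop("population(s) with fewer than 2 samples: ",
                          paste(small, collapse = ", "))
  D2 <- d$values^2
  if (is.null(groups)) {
    obs <- .amova_one_level(D2, pops)
    pval <- NA_real_
    if (n_perm > 0) {
      b <- 0L
      for (r in seq_len(n_perm)) {
        perm <- sample(seq_along(pops))
        st <- .amova_one_level(D2[perm, perm], pops)$phi_st
        if (st >= obs$phi_st) b <- b + 1L
      }
      pval <- (b + 1) / (n_perm + 1)
    }
    pct <- 100 * obs$sigma / sum(obs$sigma)
    return(structure(list(design = "one-level (among/within populations)",
                          sigma = obs$sigma, percent = pct,
                          phi = c(phi_st = obs$phi_st),
                          p = c(phi_st = pval), ssd = obs$ssd, df = obs$df,
                          n_perm = n_perm), class = "amova_result"))
  }
  grp_of_pop <- groups[levels(pops)]
  if (any(is.na(grp_of_pop))) stop("groups must map every population")
  if (any(table(grp_of_pop) < 2))
    stop("each group needs at least 2 populations in a two-level design")
  grp <- factor(grp_of_pop[as.character(pops)])
  obs <- .amova_two_level(D2, pops, grp)
  p <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (n_perm > 0) {
    b <- c(phi_ct = 0L, phi_sc = 0L, phi_st = 0L)
    idx_by_grp <- split(seq_along(pops), grp)
    for (r in seq_len(n_perm)) {
      # phi_st: individuals among populations, whole dataset
      perm <- sample(seq_along(pops))
      st <- .amova_two_level(D2, pops[perm], grp[perm])$phi
      if (st["phi_st"] >= obs$phi["phi_st"]) b["phi_st"] <- b["phi_st"] + 1L
      # phi_sc: individuals among populations within groups
      pop_sc <- pops
      for (ix in idx_by_grp) pop_sc[ix] <- pops[ix][sample(length(ix))]
      sc <- .amova_two_level(D2, pop_sc, grp)$phi
      if (sc["phi_sc"] >= obs$phi["phi_sc"]) b["phi_sc"] <- b["phi_sc"] + 1L
      # phi_ct: whole populations among groups
      g_perm <- stats::setNames(sample(grp_of_pop), levels(pops))
      ct <- .amova_two_level(D2, pops, factor(g_perm[as.character(pops)]))$phi
      if (ct["phi_ct"] >= obs$phi["phi_ct"]) b["phi_ct"] <- b["phi_ct"] + 1L
    }
    p <- (b + 1) / (n_perm + 1)
  }
  pct <- 100 * obs$sigma / sum(obs$sigma)
  structure(list(design = "two-level (groups / populations / individuals)",
                 sigma = obs$sigma, percent = pct, phi = obs$phi, p = p,
                 ssd = obs$ssd, df = obs$df, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA,", x$design, "\n")
  tab <- data.frame(component = names(x$sigma), sigma2 = round(x$sigma, 5),
                    percent = round(x$percent, 2))
  print(tab, row.names = FALSE)
  cat("Phi:", paste(sprintf("%s = %.4f", names(x$phi), x$phi), collapse = ", "), "\n")
  if (!all(is.na(x$p)))
    cat("p  :", paste(sprintf("%s = %.4g", names(x$p), x$p), collapse = ", "),
        sprintf(" (%d permutations)\n", x$n_perm))
  invisible(x)
}

#' Pairwise Phi-ST between populations
#'
#' For every pair of populations, Phi-ST from the one-level AMOVA variance
#' decomposition restricted to the pair, with a permutation p-value
#' (individuals shuffled between the two populations, (b + 1)/(m + 1)
#' estimator).
#'
#' @inheritParams amova
#' @return list with `phi_st` (a `dist_matrix` of unit phi_st) and `p`
#'   (matrix of p-values, NA diagonal).
#' @export
phi_st_pairwise <- function(d, pops, n_perm = 1000) {
  stopifnot(inherits(d, "dist_matrix"))
  if (!is.null(names(pops))) pops <- pops[d$labels]
  pops <- droplevels(as.factor(as.character(pops)))
  small <- names(which(table(pops) < 2))
  if (length(small)) stop("population(s) with fewer than 2 samples: ",
                          paste(small, collapse = ", "))
  lv <- levels(pops)
  D2 <- d$values^2
  phi <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b) {
    idx <- which(pops %in% lv[c(a, b)])
    f <- droplevels(pops[idx])
    sub <- D2[idx, idx]
    obs <- .amova_one_level(sub, f)$phi_st
    phi[a, b] <- phi[b, a] <- obs
    if (n_perm > 0) {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        perm <- sample(length(idx))
        if (.amova_one_level(sub[perm, perm], f)$phi_st >= obs) cnt <- cnt + 1L
      }
      pmat[a, b] <- pmat[b, a] <- (cnt + 1) / (n_perm + 1)
    }
  }
  list(phi_st = dist_matrix(phi, lv, units = "phi_st"), p = pmat, n_perm = n_perm)
}

#' Mean great-circle distances between populations
#'
#' Entry (A, B) is the mean haversine distance (Earth radius 6371 km) over
#' all sample pairs a in A, b in B with GPS coordinates; the diagonal is set
#' to zero. Populations without any GPS-bearing sample are excluded with a
#' warning; samples lacking GPS are dropped from the averaging only.
#'
#' @param meta metadata data.frame with `population`, `lat`, `lon`.
#' @return a `dist_matrix` in km.
#' @export
geo_distance_matrix <- function(meta) {
  ok <- !is.na(meta$lat) & !is.na(meta$lon)
  have <- unique(meta$population[ok])
  none <- setdiff(unique(meta$population), have)
  if (length(none))
    warning("populations without GPS excluded: ", paste(none, collapse = ", "))
  m <- meta[ok, ]
  k <- length(have)
  out <- matrix(0, k, k, dimnames = list(have, have))
  coords <- split(m[, c("lon", "lat")], m$population)
  for (a in seq_len(k)) for (b in seq_len(k)) if (a < b) {
    pa <- as.matrix(coords[[have[a]]]); pb <- as.matrix(coords[[have[b]]])
    dd <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j)
      geosphere::distHaversine(pa[i, , drop = FALSE], pb[j, , drop = FALSE], r = 6371000))
    out[a, b] <- out[b, a] <- mean(dd) / 1000
  }
  dist_matrix(out, have, units = "km")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a one-tailed
#' (greater) permutation test, permuting rows and columns of one matrix
#' jointly; p-value with the (b + 1)/(m + 1) estimator. Backed by
#' [vegan::mantel()].
#'
#' @param x,y `dist_matrix` objects with identical labels in the same order.
#' @param n_perm number of permutations (default 999).
#' @return list with `r`, `p`, `n_perm`, `tail`.
#' @export
mantel_test <- function(x, y, n_perm = 999) {
  stopifnot(inherits(x, "dist_matrix"), inherits(y, "dist_matrix"))
  if (!identical(x$labels, y$labels)) stop("label mismatch between matrices")
  res <- vegan::mantel(stats::as.dist(x$values), stats::as.dist(y$values),
                       method = "pearson", permutations = n_perm)
  list(r = unname(res$statistic), p = unname(res$signif),
       n_perm = n_perm, tail = "greater")
}
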