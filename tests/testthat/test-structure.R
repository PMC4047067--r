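toy_distance_set <- function(seed = 5, n = 8, L = 30) {
  set.seed(seed)
  B <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  pairwise_diff_matrix(mt_alignment(B, paste0("S", 1:n)))
}

test_that("pairwise Phi-ST equals the brute-force sums-of-squares oracle", {
  d <- toy_distance_set()
  pop <- rep(c("P1", "P2"), each = 4)
  got <- phi_st_pairwise(d, pop, n_perm = 0)
  want <- brute_one_level(d$values, pop)
  expect_equal(got$phi_st$values["P1", "P2"], want$phi_st, tolerance = 1e-9)

  # 2x3-sample toy with hand-listed distances
  dm <- matrix(0, 6, 6)
  dd <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 1, 2, 3, 1, 2, 1)
  dm[upper.tri(dm)] <- dd; dm <- dm + t(dm)
  d2 <- dist_matrix(dm, paste0("S", 1:6), units = "diff_count")
  pop2 <- rep(c("A", "B"), each = 3)
  expect_equal(phi_st_pairwise(d2, pop2, n_perm = 0)$phi_st$values["A", "B"],
               brute_one_level(dm, pop2)$phi_st, tolerance = 1e-9)
})

test_that("Phi-ST is ~0 without structure and 1 for fixed divergent haplotypes", {
  set.seed(21)
  # two populations drawn identically from one haplotype pool
  pool <- matrix(sample(c("A", "C", "G", "T"), 12 * 50, replace = TRUE), 12, 50)
  draw <- pool[sample(12, 60, replace = TRUE), ]
  aln <- mt_alignment(draw, paste0("S", 1:60))
  d <- pairwise_diff_matrix(aln)
  got <- phi_st_pairwise(d, rep(c("P1", "P2"), each = 30), n_perm = 0)
  expect_lt(abs(got$phi_st$values["P1", "P2"]), 0.05)

  # fixed haplotypes 3 differences apart
  h1 <- rep("A", 10); h2 <- c(rep("A", 7), rep("T", 3))
  B <- rbind(h1, h1, h1, h2, h2, h2)
  alnf <- mt_alignment(B, paste0("S", 1:6))
  df <- pairwise_diff_matrix(alnf)
  expect_equal(phi_st_pairwise(df, rep(c("P1", "P2"), each = 3),
                               n_perm = 0)$phi_st$values["P1", "P2"], 1)

  expect_error(phi_st_pairwise(df, c("P1", rep("P2", 5)), n_perm = 0),
               "fewer than 2")
})

test_that("one-level AMOVA matches the oracle, vegan's SS, and pairwise Phi-ST", {
  d <- toy_distance_set(seed = 8)
  pop <- c("A", "A", "A", "B", "B", "C", "C", "C")
  a <- amova(d, pop, n_perm = 0)
  expect_equal(sum(a$percent), 100, tolerance = 1e-9)

  # independent SS cross-check via vegan::adonis2 on the same d^2 partition
  ad <- vegan::adonis2(stats::as.dist(d$values) ~ g,
                       data = data.frame(g = pop), permutations = 0)
  expect_equal(unname(a$ssd["among_pops"]), ad$SumOfSqs[1], tolerance = 1e-9)
  expect_equal(unname(a$ssd["within_pops"]), ad$SumOfSqs[2], tolerance = 1e-9)

  # restriction to two populations equals pairwise Phi-ST
  idx <- pop %in% c("A", "B")
  d_ab <- dist_matrix(d$values[idx, idx], d$labels[idx], units = "diff_count")
  expect_equal(amova(d_ab, pop[idx], n_perm = 0)$phi[["phi_st"]],
               phi_st_pairwise(d, pop, n_perm = 0)$phi_st$values["A", "B"],
               tolerance = 1e-12)
})

test_that("two-level AMOVA components equal exhaustive sums of squares", {
  d <- toy_distance_set(seed = 13, n = 8)
  pop <- c("A", "A", "B", "B", "C", "C", "D", "D")
  groups <- c(A = "G1", B = "G1", C = "G2", D = "G2")
  a <- amova(d, pop, groups = groups, n_perm = 0)
  expect_equal(sum(a$percent), 100, tolerance = 1e-9)

  # brute force, written as explicit loops
  D2 <- d$values^2; n <- 8
  ss <- function(idx) {
    s <- 0
    if (length(idx) > 1)
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        s <- s + D2[idx[i], idx[j]]
    s / length(idx)
  }
  ssd_t <- ss(1:8)
  ssd_wp <- ss(1:2) + ss(3:4) + ss(5:6) + ss(7:8)
  ssd_wg <- ss(1:4) + ss(5:8)
  sigma_c <- ssd_wp / (n - 4)
  # equal sizes: n1 = 2, n2 = 2, n3 = 4
  sigma_b <- ((ssd_wg - ssd_wp) / (4 - 2) - sigma_c) / 2
  sigma_a <- ((ssd_t - ssd_wg) / (2 - 1) - sigma_c - 2 * sigma_b) / 4
  expect_equal(unname(a$sigma), c(sigma_a, sigma_b, sigma_c), tolerance = 1e-9)
  expect_equal(a$phi[["phi_ct"]], sigma_a / (sigma_a + sigma_b + sigma_c),
               tolerance = 1e-9)
  expect_equal(a$phi[["phi_sc"]], sigma_b / (sigma_b + sigma_c), tolerance = 1e-9)

  expect_error(amova(d, pop, groups = c(A = "G1", B = "G2", C = "G2", D = "G2")),
               "at least 2 populations")
})

test_that("null-model AMOVA puts ~all variance within populations and p is calibrated", {
  set.seed(77)
  pool <- matrix(sample(c("A", "C", "G", "T"), 10 * 60, replace = TRUE), 10, 60)
  draw <- pool[sample(10, 40, replace = TRUE), ]
  d <- pairwise_diff_matrix(mt_alignment(draw, paste0("S", 1:40)))
  pop <- rep(c("A", "B", "C", "D"), each = 10)
  a <- amova(d, pop, n_perm = 199)
  expect_lt(abs(a$percent[["among_pops"]]), 5)
  expect_gt(a$percent[["within_pops"]], 95)
  expect_true(a$p[["phi_st"]] > 0 && a$p[["phi_st"]] <= 1)

  # permutation p-values approximately uniform under a permuted-labels null
  ps <- replicate(120, {
    perm_pop <- sample(pop)
    amova(d, perm_pop, n_perm = 49)$p[["phi_st"]]
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("great-circle population distances use haversine averaging (R = 6371 km)", {
  meta <- data.frame(sample_id = paste0("S", 1:4),
                     population = c("A", "A", "B", "B"),
                     lat = c(0, 0, 0, 0), lon = c(0, 0, 1, 1))
  g <- geo_distance_matrix(meta)
  expect_equal(g$values["A", "B"], 2 * pi * 6371 / 360, tolerance = 1e-4)

  # all samples at one point -> zero matrix
  meta0 <- meta; meta0$lon <- 0
  expect_true(all(geo_distance_matrix(meta0)$values == 0))

  # averaging over all 4 cross pairs
  meta2 <- data.frame(sample_id = paste0("S", 1:4),
                      population = c("A", "A", "B", "B"),
                      lat = 0, lon = c(0, 1, 2, 4))
  hv <- function(l1, l2) geosphere::distHaversine(c(l1, 0), c(l2, 0), r = 6371000) / 1000
  expect_equal(geo_distance_matrix(meta2)$values["A", "B"],
               mean(c(hv(0, 2), hv(0, 4), hv(1, 2), hv(1, 4))))

  # population without GPS dropped with a warning
  meta3 <- rbind(meta, data.frame(sample_id = "S5", population = "C",
                                  lat = NA, lon = NA))
  expect_warning(g3 <- geo_distance_matrix(meta3), "without GPS")
  expect_false("C" %in% g3$labels)
})

test_that("Mantel test recovers perfect monotone association and a flat null", {
  set.seed(15)
  m <- matrix(runif(49), 7, 7); m <- m + t(m); diag(m) <- 0
  x <- dist_matrix(m, paste0("P", 1:7), units = "km")
  y <- dist_matrix(2 * m + 3 - diag(3, 7), paste0("P", 1:7), units = "km")
  r1 <- mantel_test(x, y, n_perm = 99)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lte(r1$p, 0.05)

  # affine with negative slope on off-diagonals
  vals <- max(m) * 1.5 - m; diag(vals) <- 0
  neg <- dist_matrix(vals, paste0("P", 1:7), units = "km")
  expect_equal(mantel_test(x, neg, n_perm = 99)$r, -1, tolerance = 1e-12)

  bad <- dist_matrix(m, paste0("Q", 1:7), units = "km")
  expect_error(mantel_test(x, bad), "label mismatch")

  # independent matrices: |r| small and false-positive rate compatible with
  # the nominal 5% level (binomial 3-sigma band around 0.95 at 100 runs)
  set.seed(99)
  runs <- replicate(100, {
    a <- matrix(runif(100), 10, 10); a <- a + t(a); diag(a) <- 0
    b <- matrix(runif(100), 10, 10); b <- b + t(b); diag(b) <- 0
    res <- mantel_test(dist_matrix(a, paste0("P", 1:10), units = "km"),
                       dist_matrix(b, paste0("P", 1:10), units = "km"),
                       n_perm = 199)
    c(res$p > 0.05, abs(res$r))
  })
  expect_gte(mean(runs[1, ]), 0.95 - 3 * sqrt(0.05 * 0.95 / 100))
  expect_lt(mean(runs[2, ]), 0.25)
})

test_that("Phi-ST rises monotonically with generator divergence", {
  set.seed(31)
  phis <- sapply(1:10, function(div) {
    d <- generate_dataset(two_pop_config(f1 = c(1, 0), f2 = c(0, 1),
                                         n1 = 12, n2 = 12, lambda = 1,
                                         divergence = div, length = 600))
    dm <- pairwise_diff_matrix(d$alignment)
    pops <- setNames(d$metadata$population, d$metadata$sample_id)
    phi_st_pairwise(dm, pops, n_perm = 0)$phi_st$values["P1", "P2"]
  })
  expect_gt(cor(phis, 1:10, method = "spearman"), 0.9)
})
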