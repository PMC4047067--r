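# fixtures shared across test files; everything is built in code

aln_from <- function(seqs, ids = names(seqs), coord_map = NULL) {
  if (is.null(ids)) ids <- paste0("S", seq_along(seqs))
  mt_alignment(do.call(rbind, strsplit(unname(seqs), "")), ids, coord_map)
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  if (is.null(ids)) ids <- paste0("S", seq_along(seqs))
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

meta_for <- function(aln, population, lat = NA_real_, lon = NA_real_) {
  data.frame(sample_id = aln$sample_ids,
             population = population,
             country = "x", language_branch = "WestBantu",
             subsistence = "agriculturalist", haplogroup = "L3",
             lat = lat, lon = lon, stringsAsFactors = FALSE)
}

# Brute-force oracle for the one-level AMOVA decomposition: explicit loops
# over the squared-distance sums, independent of the package's code path.
brute_one_level <- function(d, pop) {
  n <- length(pop); P <- length(unique(pop))
  ssd_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ssd_t <- ssd_t + d[i, j]^2
  ssd_t <- ssd_t / n
  ssd_wp <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p); s <- 0
    if (length(idx) > 1)
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx))
        s <- s + d[idx[a], idx[b]]^2
    ssd_wp <- ssd_wp + s / length(idx)
  }
  sigma_c <- ssd_wp / (n - P)
  np <- table(pop)
  n0 <- (n - sum(np^2) / n) / (P - 1)
  sigma_a <- ((ssd_t - ssd_wp) / (P - 1) - sigma_c) / n0
  list(sigma_a = sigma_a, sigma_c = sigma_c,
       phi_st = sigma_a / (sigma_a + sigma_c))
}

# two-population config used by several generator tests
two_pop_config <- function(f1 = c(0.5, 0.5), f2 = c(0.5, 0.5),
                           n1 = 20, n2 = 20, lambda = 1, divergence = 5,
                           length = 1000, missing_rate = 0, shared = NULL) {
  pops <- data.frame(name = c("P1", "P2"), size = c(n1, n2),
                     language_branch = "WestBantu", subsistence = "agriculturalist",
                     lat = c(-18, -20), lon = c(14, 16),
                     HgA = c(f1[1], f2[1]), HgB = c(f1[2], f2[2]),
                     stringsAsFactors = FALSE)
  hg <- data.frame(label = c("HgA", "HgB"), divergence = divergence,
                   lambda = lambda, stringsAsFactors = FALSE)
  sim_config(pops, hg, shared_haplotypes = shared,
             length = length, missing_rate = missing_rate)
}
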