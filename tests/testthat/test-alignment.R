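test_that("FASTA reading normalises symbols and enforces alignment invariants", {
  p <- write_tmp_fasta(c(A = "acgtacgtna", B = "ACGT?CGT-N"))
  aln <- read_alignment(p)
  expect_equal(dim(aln), c(2L, 10L))
  expect_equal(unname(aln$bases["A", 9]), "N")      # lowercase n -> N
  expect_equal(unname(aln$bases["B", 5]), "N")      # ? -> N
  expect_equal(unname(aln$bases["B", 9]), "-")

  expect_error(read_alignment(write_tmp_fasta(c(A = "ACGT", B = "ACGTT"))),
               "not aligned")
  expect_error(read_alignment(write_tmp_fasta(c(A = "ACGT", A = "ACGT"))),
               "duplicate")
  expect_error(read_alignment(write_tmp_fasta(c(A = "ACRT"))), "invalid")
})

test_that("round-trip through write_alignment preserves the matrix", {
  aln <- aln_from(c(A = "ACGTN-AC", B = "ACGTAAAC"))
  p <- tempfile(fileext = ".fasta")
  write_alignment(aln, p)
  back <- read_alignment(p)
  expect_identical(back$bases, aln$bases)
})

test_that("masking drops reference ranges and indel columns", {
  # full-length-style map: the two poly-C ranges cover 13 + 12 = 25 columns
  L <- 16465
  seq1 <- paste(rep("A", L), collapse = "")
  aln <- aln_from(c(A = seq1, B = seq1), coord_map = 1:L)
  masked <- apply_mask(aln, mask_spec(list(c(303, 315), c(16183, 16194))))
  expect_equal(ncol(aln$bases) - ncol(masked$bases), 25L)
  expect_false(any(masked$coord_map %in% c(303:315, 16183:16194)))

  # empty mask is the identity
  expect_identical(apply_mask(aln, mask_spec())$bases, aln$bases)

  # indel-column dropping
  toy <- aln_from(c(A = "A-C", B = "AAC"))
  m <- apply_mask(toy, mask_spec(drop_indel_columns = TRUE))
  expect_equal(ncol(m$bases), 2L)
  expect_equal(m$coord_map, c(1L, 3L))

  # idempotence
  expect_identical(apply_mask(m, mask_spec(drop_indel_columns = TRUE))$bases, m$bases)
  pc <- apply_mask(aln, polyc_mask())
  expect_identical(apply_mask(pc, polyc_mask())$bases, pc$bases)
})

test_that("imputation fills sites with >=2 unanimous otherwise-identical donors", {
  aln <- aln_from(c(S = "ACN", D1 = "ACT", D2 = "ACT", D3 = "AGG"))
  r <- impute_missing(aln)
  expect_equal(unname(r$alignment$bases["S", 3]), "T")
  expect_equal(r$report$sites_imputed, 1L)
  expect_equal(r$report$log$n_support, 2L)

  # a single donor is not enough
  one <- impute_missing(aln_from(c(S = "ACN", D1 = "ACT", D2 = "AGG")))
  expect_equal(unname(one$alignment$bases["S", 3]), "N")
  expect_equal(one$report$sites_imputed, 0L)

  # disagreeing donors leave the site missing (unanimity required)
  dis <- impute_missing(aln_from(c(S = "ACN", D1 = "ACT", D2 = "ACG", D3 = "ACG")))
  expect_equal(unname(dis$alignment$bases["S", 3]), "N")

  # no missing data: identity and zero count
  clean <- aln_from(c(A = "ACGT", B = "ACGA"))
  rc <- impute_missing(clean)
  expect_identical(rc$alignment$bases, clean$bases)
  expect_equal(rc$report$sites_imputed, 0L)
})

test_that("imputation is a single pass and never edits known bases", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:10, 1); L <- sample(5:12, 1)
    B <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    # duplicate some rows so donors exist, then punch holes
    B[2, ] <- B[1, ]; B[3, ] <- B[1, ]
    holes <- matrix(runif(n * L) < 0.1, n, L)
    B2 <- B; B2[holes] <- "N"
    aln <- mt_alignment(B2, paste0("S", 1:n))
    r <- impute_missing(aln)
    known <- B2 != "N"
    expect_identical(r$alignment$bases[known], B2[known])
    n_before <- sum(B2 == "N")
    expect_equal(r$report$sites_imputed + sum(r$alignment$bases == "N"), n_before)
    expect_lte(r$report$samples_with_missing_after,
               r$report$samples_with_missing_before)
  }
})

test_that("masking and imputing commute when no masked column carries N", {
  # N placed outside the masked range by construction
  aln <- aln_from(c(A = "NACGT", B = "TACGT", C = "TACGT", D = "TACCT"),
                  coord_map = 1:5)
  mask <- mask_spec(list(c(4, 4)))
  a <- impute_missing(apply_mask(aln, mask))$alignment
  b <- apply_mask(impute_missing(aln)$alignment, mask)
  expect_identical(a$bases, b$bases)
})

test_that("haplotype collapsing groups identical sequences by population", {
  aln <- aln_from(c(A1 = "AAA", A2 = "AAA", B1 = "AAA", B2 = "AAA"))
  meta <- meta_for(aln, c("P1", "P1", "P2", "P2"))
  ht <- collapse_haplotypes(aln, meta)
  expect_equal(length(ht$haplotypes), 1L)
  expect_equal(as.vector(ht$counts), c(2L, 2L))

  aln2 <- aln_from(c(A = "AAA", B = "AAT", C = "AAT"))
  ht2 <- collapse_haplotypes(aln2, meta_for(aln2, "P1"))
  expect_equal(sort(as.vector(ht2$counts)), c(1L, 2L))

  # column sums equal population sizes on a 6-sample toy
  aln3 <- aln_from(c(a = "ACG", b = "ACG", c = "ACT", d = "GCT", e = "GGG", f = "ACT"))
  meta3 <- meta_for(aln3, c("P1", "P1", "P1", "P2", "P2", "P2"))
  ht3 <- collapse_haplotypes(aln3, meta3)
  expect_equal(length(ht3$haplotypes), 4L)
  expect_equal(colSums(ht3$counts), c(P1 = 3L, P2 = 3L))
  expect_equal(sum(lengths(ht3$members)), 6L)

  expect_error(collapse_haplotypes(aln3, meta3[-1, ]), "without metadata")

  # drop_missing_samples excludes and reports
  aln4 <- aln_from(c(A = "AAN", B = "AAT"))
  ht4 <- collapse_haplotypes(aln4, meta_for(aln4, "P1"), drop_missing_samples = TRUE)
  expect_equal(ht4$dropped, "A")
  expect_equal(sum(ht4$counts), 1L)
})

test_that("pairwise differences use pairwise deletion and obey the triangle inequality", {
  expect_true(all(pairwise_diff_matrix(aln_from(c(A = "ACGT", B = "ACGT")))$values == 0))
  expect_equal(pairwise_diff_matrix(aln_from(c(A = "AAAA", B = "AATT")))$values["A", "B"], 2)
  expect_equal(pairwise_diff_matrix(aln_from(c(A = "AANA", B = "AATT")))$values["A", "B"], 1)
  expect_error(pairwise_diff_matrix(aln_from(c(A = "A-GT", B = "ACGT"))), "indel")

  set.seed(7)
  for (rep in 1:10) {
    B <- matrix(sample(c("A", "C", "G", "T"), 6 * 20, replace = TRUE), 6, 20)
    d <- pairwise_diff_matrix(mt_alignment(B, paste0("S", 1:6)))$values
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})
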