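#' Alignment container
#'
#' An `mt_alignment` is a plain list holding a rectangular character matrix of
#' aligned bases over the alphabet \{A, C, G, T, -, N\} ("-" = indel,
#' "N" = missing), the unique sample identifiers (also the rownames of the
#' matrix), and `coord_map`, an integer vector giving the 1-based reference
#' position (rCRS convention for real mtDNA data) of every column, with `NA`
#' for unmapped columns such as insertion columns.
#'
#' @param bases character matrix, one row per sample.
#' @param sample_ids character vector of unique ids; defaults to rownames.
#' @param coord_map integer vector of reference positions (or NA), one per
#'   column; defaults to `1:ncol(bases)`.
#' @return an object of class `mt_alignment`.
#' @export
mt_alignment <- function(bases, sample_ids = rownames(bases), coord_map = NULL) {
  stopifnot(is.matrix(bases), is.character(bases))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(bases)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in alignment")
  if (length(sample_ids) != nrow(bases)) stop("sample_ids/bases mismatch")
  if (is.null(coord_map)) coord_map <- seq_len(ncol(bases))
  if (length(coord_map) != ncol(bases)) stop("coord_map length must equal number of columns")
  cm <- coord_map[!is.na(coord_map)]
  if (length(cm) > 1 && any(diff(cm) <= 0)) stop("coord_map must be strictly increasing where mapped")
  bad <- setdiff(unique(as.vector(bases)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad)) stop("invalid alignment characters: ", paste(bad, collapse = ", "))
  rownames(bases) <- sample_ids
  structure(list(bases = bases, sample_ids = sample_ids, coord_map = as.integer(coord_map)),
            class = "mt_alignment")
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mt_alignment:", nrow(x$bases), "sequences x", ncol(x$bases), "columns;",
      sum(x$bases == "N"), "missing bases,", sum(x$bases == "-"), "gap characters\n")
  invisible(x)
}

#' @export
dim.mt_alignment <- function(x) dim(x$bases)

#' Read an aligned FASTA file
#'
#' Sequences must all have the same length (it is an alignment, not a read
#' set). Bases are uppercased; "?" and lowercase "n" are normalised to "N".
#' IUPAC ambiguity codes are rejected rather than silently treated as
#' missing, so that a miscalled base cannot masquerade as absent data.
#'
#' @param path path to an aligned FASTA file.
#' @param coord_map optional reference-position map (see [mt_alignment()]).
#' @return an `mt_alignment`.
#' @export
read_alignment <- function(path, coord_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                             forceDNAtolower = FALSE, set.attributes = FALSE)
  if (!length(seqs)) stop("empty FASTA: ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate sample ids in FASTA")
  bases <- toupper(do.call(rbind, seqs))
  bases[bases == "?"] <- "N"
  mt_alignment(bases, ids, coord_map)
}

#' Write an alignment to FASTA
#'
#' @param aln an `mt_alignment`.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(aln$bases)), function(i) aln$bases[i, ]),
                      names = aln$sample_ids, file.out = path, nbchar = 70)
  invisible(path)
}

#' Masking specification
#'
#' Reference-coordinate ranges to drop (e.g. the unstable poly-C stretches of
#' the mtDNA control region, rCRS 303--315 and 16183--16194) and whether to
#' drop every column containing an indel character in any sample.
#'
#' @param ranges list of length-2 integer vectors `(start, end)`, 1-based
#'   inclusive reference positions. Overlapping ranges are merged.
#' @param drop_indel_columns drop any column carrying "-" in at least one row.
#' @return a `mask_spec` object.
#' @export
mask_spec <- function(ranges = list(), drop_indel_columns = FALSE) {
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || r[1] > r[2]) stop("each range must be (start, end) with start <= end")
    r
  })
  if (length(ranges) > 1) {
    o <- order(vapply(ranges, `[`, integer(1), 1))
    ranges <- ranges[o]
    merged <- list(ranges[[1]])
    for (r in ranges[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] <= last[2] + 1L) merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
      else merged <- c(merged, list(r))
    }
    ranges <- merged
  }
  structure(list(ranges = ranges, drop_indel_columns = drop_indel_columns), class = "mask_spec")
}

#' The control-region poly-C mask
#'
#' Convenience constructor for the standard rCRS mask: poly-C regions
#' 303--315 and 16183--16194, with indel columns dropped.
#' @export
polyc_mask <- function() {
  mask_spec(list(c(303L, 315L), c(16183L, 16194L)), drop_indel_columns = TRUE)
}

#' Apply a mask to an alignment
#'
#' Drops columns whose reference position falls in any masked range and,
#' optionally, all columns containing an indel character. Idempotent.
#'
#' @param aln an `mt_alignment`.
#' @param mask a `mask_spec`.
#' @return the masked `mt_alignment`.
#' @export
apply_mask <- function(aln, mask) {
  stopifnot(inherits(aln, "mt_alignment"), inherits(mask, "mask_spec"))
  keep <- rep(TRUE, ncol(aln$bases))
  for (r in mask$ranges)
    keep <- keep & !(!is.na(aln$coord_map) & aln$coord_map >= r[1] & aln$coord_map <= r[2])
  if (isTRUE(mask$drop_indel_columns))
    keep <- keep & colSums(aln$bases == "-") == 0
  mt_alignment(aln$bases[, keep, drop = FALSE], aln$sample_ids, aln$coord_map[keep])
}

#' Impute missing bases from otherwise-identical haplotypes
#'
#' For each sample `s` and each missing position `c`, the donors are the
#' samples that are non-missing at `c` and identical to `s` at every column
#' where `s` itself is non-missing. If at least `min_support` donors exist
#' and they all carry the same base at `c`, that base is filled in; if donors
#' disagree, or fewer exist, the site stays "N". Support is counted in
#' individuals, not distinct haplotype classes. The whole pass is computed
#' from the pre-imputation alignment, so the result does not depend on sample
#' order and freshly imputed bases never act as donors.
#'
#' @param aln an `mt_alignment` with missing data encoded as "N".
#' @param min_support minimum number of unanimous donors (default 2).
#' @return list with elements `alignment` (imputed) and `report`, a list with
#'   `sites_imputed`, `samples_with_missing_before`/`_after`, and `log`, a
#'   data.frame of (sample_id, column, position, base, n_support).
#' @export
impute_missing <- function(aln, min_support = 2L) {
  stopifnot(inherits(aln, "mt_alignment"))
  B <- aln$bases
  miss <- B == "N"
  before <- sum(rowSums(miss) > 0)
  log <- list()
  out <- B
  for (i in which(rowSums(miss) > 0)) {
    known <- !miss[i, ]
    # donors: rows matching sample i at all its known columns
    cand <- which(seq_len(nrow(B)) != i &
                    colSums(t(B[, known, drop = FALSE]) != B[i, known]) == 0)
    if (!length(cand)) next
    for (cc in which(miss[i, ])) {
      donors <- cand[B[cand, cc] != "N"]
      if (length(donors) >= min_support) {
        bb <- unique(B[donors, cc])
        if (length(bb) == 1L) {
          out[i, cc] <- bb
          log[[length(log) + 1L]] <- data.frame(
            sample_id = aln$sample_ids[i], column = cc,
            position = aln$coord_map[cc], base = bb,
            n_support = length(donors), stringsAsFactors = FALSE)
        }
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(sample_id = character(), column = integer(), position = integer(),
               base = character(), n_support = integer(), stringsAsFactors = FALSE)
  res <- mt_alignment(out, aln$sample_ids, aln$coord_map)
  report <- list(sites_imputed = nrow(log),
                 samples_with_missing_before = before,
                 samples_with_missing_after = sum(rowSums(res$bases == "N") > 0),
                 log = log)
  list(alignment = res, report = report)
}

#' Collapse identical sequences into haplotypes
#'
#' Identical post-masking sequences are grouped into haplotypes and
#' cross-tabulated against populations.
#'
#' @param aln an `mt_alignment`.
#' @param meta metadata data.frame with columns `sample_id` and `population`
#'   covering every sample in `aln`.
#' @param drop_missing_samples exclude samples still containing "N".
#' @return a `haplotype_table`: list with `haplotypes` (character vector of
#'   base strings), `counts` (haplotype x population integer matrix),
#'   `members` (list of sample-id vectors) and `dropped` (excluded ids).
#' @export
collapse_haplotypes <- function(aln, meta, drop_missing_samples = FALSE) {
  stopifnot(inherits(aln, "mt_alignment"))
  missing_meta <- setdiff(aln$sample_ids, meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  keep <- rep(TRUE, nrow(aln$bases))
  if (drop_missing_samples) keep <- rowSums(aln$bases == "N") == 0
  dropped <- aln$sample_ids[!keep]
  ids <- aln$sample_ids[keep]
  seqs <- apply(aln$bases[keep, , drop = FALSE], 1, paste, collapse = "")
  pop <- meta$population[match(ids, meta$sample_id)]
  hap <- factor(seqs, levels = unique(seqs))
  counts <- table(hap, factor(pop, levels = unique(meta$population[meta$sample_id %in% ids])))
  counts <- matrix(as.integer(counts), nrow = nlevels(hap),
                   dimnames = list(paste0("H", seq_len(nlevels(hap))), colnames(counts)))
  members <- split(ids, hap)
  names(members) <- rownames(counts)
  structure(list(haplotypes = levels(hap), counts = counts,
                 members = members, dropped = dropped),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes,",
      sum(x$counts), "samples,", ncol(x$counts), "populations\n")
  invisible(x)
}

#' Pairwise sequence difference matrix
#'
#' Entry (i, j) is the number of columns at which samples i and j carry
#' different bases, counting only columns where both bases are in
#' \{A, C, G, T\} (pairwise deletion of residual missing data). Indel
#' columns must already have been masked.
#'
#' @param aln an `mt_alignment` with no "-" characters remaining.
#' @return a `dist_matrix` of unit `diff_count` (see [dist_matrix()]).
#' @export
pairwise_diff_matrix <- function(aln) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (any(aln$bases == "-")) stop("indel columns present; apply a mask with drop_indel_columns first")
  B <- aln$bases
  valid <- (B != "N") * 1
  npairs <- valid %*% t(valid)                 # comparable columns per pair
  matches <- matrix(0, nrow(B), nrow(B))
  for (b in c("A", "C", "G", "T")) {
    M <- (B == b) * 1
    matches <- matches + M %*% t(M)
  }
  d <- npairs - matches
  diag(d) <- 0
  dist_matrix(d, labels = aln$sample_ids, units = "diff_count")
}
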