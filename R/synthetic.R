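#' Configuration for the synthetic mtDNA survey generator
#'
#' Describes a multi-population mtDNA survey with the statistical structure
#' the analysis modules assume: populations with haplogroup-frequency
#' vectors, starlike haplotype radiation within haplogroups (each sample =
#' haplogroup founder + Poisson-distributed private mutations under an
#' infinite-sites model), optional haplotypes forced to be shared across
#' populations, and uniformly injected missing bases.
#'
#' @param populations data.frame with columns `name`, `size`,
#'   `language_branch`, `subsistence`, `lat`, `lon`, and one frequency
#'   column per haplogroup label (rows must sum to 1 within 0.01).
#' @param haplogroups data.frame with columns `label`, `divergence` (founder
#'   mutations from the reference) and `lambda` (Poisson mean of private
#'   mutations per lineage).
#' @param shared_haplotypes optional data.frame with columns `haplogroup`,
#'   `populations` (comma-separated names) and `freq`: in each named
#'   population, `round(freq * size)` samples carry one identical haplotype.
#' @param length alignment length in bases.
#' @param missing_rate fraction of bases replaced by "N", in [0, 1).
#' @return a `sim_config` object.
#' @export
sim_config <- function(populations, haplogroups, shared_haplotypes = NULL,
                       length = 1000, missing_rate = 0) {
  labs <- haplogroups$label
  if (!all(labs %in% names(populations)))
    stop("populations table lacks frequency columns for: ",
         paste(setdiff(labs, names(populations)), collapse = ", "))
  fr <- as.matrix(populations[, labs, drop = FALSE])
  if (any(abs(rowSums(fr) - 1) > 0.01))
    stop("haplogroup frequency rows must sum to 1 (+/- 0.01)")
  if (any(populations$size < 2)) stop("population sizes must be >= 2")
  if (any(haplogroups$lambda < 0)) stop("lambda must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(populations = populations, haplogroups = haplogroups,
                 shared_haplotypes = shared_haplotypes,
                 length = as.integer(length), missing_rate = missing_rate),
            class = "sim_config")
}

#' Generate a synthetic alignment, metadata and truth record
#'
#' Draws a uniform random reference sequence, builds each haplogroup founder
#' as the reference plus `divergence` substitutions at globally distinct
#' positions (infinite sites), assigns samples to haplogroups by multinomial
#' draws on the population frequency vectors, adds Poisson(`lambda`) private
#' mutations per sample at further distinct positions, overwrites the
#' designated shared-haplotype carriers with one common sequence per spec,
#' and finally injects "N" uniformly at the missing rate. Deterministic for
#' a fixed seed set beforehand with `set.seed()`.
#'
#' @param cfg a `sim_config`.
#' @return list with `alignment` (an `mt_alignment`), `metadata`
#'   (data.frame in the dialect [read_sample_metadata()] consumes) and
#'   `truth` (per-sample haplogroup, shared-haplotype flag, mutated
#'   positions; per-population expected frequencies).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$length
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  avail <- sample(L)                           # global infinite-sites position pool
  take <- function(k) {
    if (k == 0) return(integer(0))
    if (k > length(avail)) stop("requested mutations exceed available positions")
    out <- avail[seq_len(k)]
    avail <<- avail[-seq_len(k)]
    out
  }
  mutate <- function(seq, pos) {
    for (p in pos) seq[p] <- sample(setdiff(bases, seq[p]), 1)
    seq
  }
  hg <- cfg$haplogroups
  founders <- list()
  for (i in seq_len(nrow(hg)))
    founders[[hg$label[i]]] <- mutate(ref, take(hg$divergence[i]))
  # pre-build shared haplotypes (founder + lambda-mean shared private mutations)
  shared_seq <- list()
  if (!is.null(cfg$shared_haplotypes)) {
    for (i in seq_len(nrow(cfg$shared_haplotypes))) {
      lab <- cfg$shared_haplotypes$haplogroup[i]
      lam <- hg$lambda[hg$label == lab]
      shared_seq[[i]] <- mutate(founders[[lab]], take(stats::rpois(1, lam)))
    }
  }
  rows <- list(); meta <- list(); truth <- list()
  for (p in seq_len(nrow(cfg$populations))) {
    pop <- cfg$populations[p, ]
    freqs <- as.numeric(pop[, hg$label])
    ns <- as.vector(stats::rmultinom(1, pop$size, freqs))
    assign <- rep(hg$label, ns)[sample(pop$size)]
    is_shared <- rep(NA_integer_, pop$size)
    if (!is.null(cfg$shared_haplotypes)) {
      for (i in seq_len(nrow(cfg$shared_haplotypes))) {
        sh <- cfg$shared_haplotypes[i, ]
        if (!pop$name %in% trimws(strsplit(sh$populations, ",")[[1]])) next
        k <- round(sh$freq * pop$size)
        slots <- which(is.na(is_shared))[seq_len(min(k, sum(is.na(is_shared))))]
        is_shared[slots] <- i
        assign[slots] <- sh$haplogroup
      }
    }
    for (s in seq_len(pop$size)) {
      id <- sprintf("%s_%03d", pop$name, s)
      if (!is.na(is_shared[s])) {
        seq <- shared_seq[[is_shared[s]]]
        pos <- integer(0)
      } else {
        lam <- hg$lambda[hg$label == assign[s]]
        pos <- take(stats::rpois(1, lam))
        seq <- mutate(founders[[assign[s]]], pos)
      }
      rows[[id]] <- seq
      meta[[id]] <- data.frame(sample_id = id, population = pop$name,
                               country = "synthetic",
                               language_branch = pop$language_branch,
                               subsistence = pop$subsistence,
                               haplogroup = assign[s],
                               lat = pop$lat, lon = pop$lon,
                               stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(sample_id = id, haplogroup = assign[s],
                                shared_haplotype = is_shared[s],
                                n_private = length(pos),
                                positions = paste(sort(pos), collapse = ","),
                                stringsAsFactors = FALSE)
    }
  }
  B <- do.call(rbind, rows)
  if (cfg$missing_rate > 0) {
    hit <- stats::runif(length(B)) < cfg$missing_rate
    B[hit] <- "N"
  }
  expected <- cfg$populations[, c("name", hg$label)]
  list(alignment = mt_alignment(B, names(rows)),
       metadata = do.call(rbind, meta),
       truth = list(samples = do.call(rbind, truth),
                    expected_frequencies = expected,
                    reference = paste(ref, collapse = "")))
}

#' Build a sim_config from a haplogroup-frequency table
#'
#' Takes a table whose rows are populations and whose columns are haplogroup
#' labels (plus `name` and `size`), in the layout of a published basic
#' haplogroup frequency table, and turns it into a `sim_config` whose
#' expected haplogroup frequencies match the table.
#'
#' @param table data.frame with `name`, `size` and one column per
#'   haplogroup; frequency rows must sum to 1 within 0.01.
#' @param divergence founder divergence applied to every haplogroup.
#' @param lambda within-haplogroup Poisson mean applied to every haplogroup.
#' @param ... passed to [sim_config()] (length, missing_rate, ...).
#' @return a `sim_config`.
#' @export
emulate_study_frequencies <- function(table, divergence = 5, lambda = 1, ...) {
  labs <- setdiff(names(table), c("name", "size", "language_branch",
                                  "subsistence", "lat", "lon"))
  if (!length(labs)) stop("no haplogroup columns found")
  pops <- table
  for (col in c("language_branch", "subsistence"))
    if (!col %in% names(pops)) pops[[col]] <- "synthetic"
  for (col in c("lat", "lon")) if (!col %in% names(pops)) pops[[col]] <- NA_real_
  hg <- data.frame(label = labs, divergence = divergence, lambda = lambda,
                   stringsAsFactors = FALSE)
  sim_config(pops, hg, ...)
}
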