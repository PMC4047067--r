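#' Run the analysis pipeline from a single configuration
#'
#' Chains curation (masking + imputation), per-population diversity,
#' population structure (pairwise Phi-ST, AMOVA under optional groupings,
#' Mantel test against geography) and the drift-resampling grids, writing
#' TSV/JSON outputs and a manifest (seed, per-stage status, file checksums)
#' into `out_dir`. Reruns with the same config and seed reproduce every
#' stochastic output bit-identically.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{alignment, metadata}{input FASTA / TSV paths.}
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{integer seed for all stochastic stages.}
#'     \item{stages}{character subset of c("curate", "diversity",
#'       "structure", "driftsim"); defaults to all.}
#'     \item{mask}{list(ranges = list(c(start, end), ...),
#'       drop_indel_columns); defaults to the poly-C mask.}
#'     \item{impute}{logical, default TRUE.}
#'     \item{groupings}{named list of population->group TSV paths (or named
#'       vectors) for two-level AMOVAs.}
#'     \item{n_perm}{permutations for Phi-ST/AMOVA (default 1000) ;
#'       `n_perm_mantel` for the Mantel test (default 999).}
#'     \item{driftsim}{list(presets, initial_freqs, split_years, n_outer,
#'       n_inner).}
#'   }
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("alignment", "metadata", "out_dir", "seed"))
    if (is.null(config[[f]])) stop("config lacks required field: ", f)
  for (f in c("alignment", "metadata"))
    if (!file.exists(config[[f]])) stop("input file missing: ", config[[f]])
  stages <- config$stages %||% c("curate", "diversity", "structure", "driftsim")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  emit <- function(path) manifest$files[[basename(path)]] <<-
    unname(tools::md5sum(path))
  log_line <- function(stage, msg)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", msg)

  aln <- read_alignment(config$alignment)
  meta <- read_sample_metadata(config$metadata)
  no_meta <- setdiff(aln$sample_ids, meta$sample_id)
  if (length(no_meta))
    stop("curate: aligned samples without metadata: ", paste(no_meta, collapse = ", "))

  if ("curate" %in% stages) {
    log_line("curate", sprintf("%d sequences x %d columns", nrow(aln$bases), ncol(aln$bases)))
    mk <- config$mask
    mask <- if (is.null(mk)) polyc_mask() else
      mask_spec(mk$ranges %||% list(), isTRUE(mk$drop_indel_columns))
    aln <- apply_mask(aln, mask)
    if (!identical(config$impute, FALSE)) {
      imp <- impute_missing(aln)
      aln <- imp$alignment
      utils::write.table(imp$report$log, file.path(out, "imputation_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(file.path(out, "imputation_report.tsv"))
      log_line("curate", sprintf("imputed %d sites", imp$report$sites_imputed))
    }
    write_alignment(aln, file.path(out, "curated.fasta"))
    emit(file.path(out, "curated.fasta"))
    manifest$stages$curate <- "ok"
  }

  ht <- collapse_haplotypes(aln, meta)
  d <- pairwise_diff_matrix(aln)
  pops <- stats::setNames(meta$population[match(aln$sample_ids, meta$sample_id)],
                          aln$sample_ids)

  if ("diversity" %in% stages) {
    log_line("diversity", "per-population diversity table")
    tab <- diversity_table(aln, meta)
    utils::write.table(tab, file.path(out, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(file.path(out, "diversity.tsv"))
    ht_long <- do.call(rbind, lapply(seq_along(ht$members), function(i)
      data.frame(haplotype = names(ht$members)[i],
                 sample_id = ht$members[[i]], stringsAsFactors = FALSE)))
    utils::write.table(ht_long, file.path(out, "haplotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(file.path(out, "haplotypes.tsv"))
    manifest$stages$diversity <- "ok"
  }

  if ("structure" %in% stages) {
    n_perm <- config$n_perm %||% 1000
    log_line("structure", sprintf("pairwise Phi-ST (%d permutations)", n_perm))
    ph <- phi_st_pairwise(d, pops, n_perm = n_perm)
    write_dist_matrix(ph$phi_st, file.path(out, "phi_st.tsv"))
    emit(file.path(out, "phi_st.tsv"))
    amovas <- list(overall = amova(d, pops, n_perm = n_perm))
    for (gname in names(config$groupings %||% list())) {
      g <- config$groupings[[gname]]
      if (is.character(g) && length(g) == 1 && file.exists(g)) g <- read_grouping(g)
      amovas[[gname]] <- amova(d, pops, groups = g, n_perm = n_perm)
    }
    jsonlite::write_json(
      lapply(amovas, function(a) a[c("design", "sigma", "percent", "phi", "p", "n_perm")]),
      file.path(out, "amova.json"), auto_unbox = TRUE, digits = NA)
    emit(file.path(out, "amova.json"))
    mantel_out <- NULL
    if (all(c("lat", "lon") %in% names(meta)) && any(!is.na(meta$lat))) {
      geo <- suppressWarnings(geo_distance_matrix(meta))
      common <- intersect(ph$phi_st$labels, geo$labels)
      if (length(common) >= 3) {
        gsub_ <- dist_matrix(geo$values[common, common], common, units = "km")
        psub <- dist_matrix(ph$phi_st$values[common, common], common, units = "phi_st")
        mantel_out <- mantel_test(psub, gsub_, n_perm = config$n_perm_mantel %||% 999)
        jsonlite::write_json(mantel_out, file.path(out, "mantel.json"),
                             auto_unbox = TRUE, digits = NA)
        emit(file.path(out, "mantel.json"))
      }
    }
    manifest$stages$structure <- "ok"
  }

  if ("driftsim" %in% stages && !is.null(config$driftsim)) {
    ds <- config$driftsim
    for (pr in (ds$presets %||% "a")) {
      log_line("driftsim", paste("preset", pr))
      grid <- run_drift_grid(
        ds$initial_freqs %||% seq(0.09, 0.57, by = 0.04),
        ds$split_years %||% c(500, 1000, 2000),
        function(sy) drift_preset(pr, split_years = sy,
                                  n_outer = ds$n_outer %||% 10000,
                                  n_inner = ds$n_inner %||% 100),
        seed = config$seed + match(pr, letters))
      f <- file.path(out, paste0("drift_grid_", pr, ".tsv"))
      write_drift_grid(grid, f)
      emit(f); emit(sub("\\.tsv$", ".json", f))
    }
    manifest$stages$driftsim <- "ok"
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
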