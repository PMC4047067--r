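#' Labelled symmetric distance matrix
#'
#' Thin wrapper around a square numeric matrix carrying its labels and units:
#' `diff_count` (pairwise sequence differences), `phi_st`, or `km`.
#' Phi-ST entries may be slightly negative (estimator property); all other
#' units must be non-negative.
#'
#' @param values square numeric matrix.
#' @param labels row/column labels.
#' @param units one of "diff_count", "phi_st", "km".
#' @return a `dist_matrix` object.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        units = c("diff_count", "phi_st", "km")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(values)))
  if (length(labels) != nrow(values)) stop("labels/size mismatch")
  if (max(abs(values - t(values))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (units != "phi_st" && any(values < 0)) stop("negative distances")
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, units = units),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", x$units, "), ", length(x$labels), " labels\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Write a dist_matrix as a labelled square TSV
#' @param d a `dist_matrix`.
#' @param path output path.
#' @export
write_dist_matrix <- function(d, path) {
  utils::write.table(data.frame(label = d$labels, d$values, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
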