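#' Read per-sample metadata
#'
#' Reads a tab-separated table with header columns `sample_id`, `population`,
#' `country`, `language_branch`, `subsistence`, `haplogroup`, `lat`, `lon`
#' (latitude/longitude in decimal degrees; empty values allowed). Validates
#' id uniqueness and coordinate ranges.
#'
#' @param path path to the TSV file.
#' @return a data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("sample_id", "population", "country", "language_branch",
                "subsistence", "haplogroup", "lat", "lon")
  missing <- setdiff(required, names(m))
  if (length(missing)) stop("metadata lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in metadata")
  m$lat <- as.numeric(m$lat); m$lon <- as.numeric(m$lon)
  if (any(!is.na(m$lat) & abs(m$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(!is.na(m$lon) & abs(m$lon) > 180)) stop("longitude outside [-180, 180]")
  m
}

#' Write per-sample metadata
#' @param meta metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column population grouping table
#'
#' TSV with header `population`, `group`; used to define AMOVA groupings
#' (e.g. language branch, subsistence, geography).
#'
#' @param path path to the TSV file.
#' @return named character vector mapping population to group.
#' @export
read_grouping <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("population", "group") %in% names(g)))
    stop("grouping file needs columns population, group")
  stats::setNames(as.character(g$group), g$population)
}
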