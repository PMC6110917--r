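# Plain-text I/O for the pipeline's tabular objects. Metadata and distance
# matrices travel as TSV; community tables as a dense counts TSV plus a
# two-column taxonomy TSV, or as BIOM (via the biomformat package when
# available). Round trips are lossless.

metadata_columns <- c("sample_id", "basin", "polygon", "dist_from_trough",
                      "easting", "northing", "ph", "ec")

#' Write per-sample metadata as TSV
#'
#' @param frame A `sample_frame`.
#' @param path Output file.
#' @export
write_metadata <- function(frame, path) {
  out <- as.data.frame(frame)[, metadata_columns]
  names(out) <- c("sample_id", "basin", "polygon", "dist_from_trough_m",
                  "easting_m", "northing_m", "ph", "ec_uS_cm")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata TSV
#'
#' @param path File written by [write_metadata()].
#' @return A `sample_frame` data frame.
#' @export
read_metadata <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(d) <- sub("_m$", "", sub("_uS_cm$", "", names(d)))
  missing <- setdiff(metadata_columns, names(d))
  if (length(missing)) stop("metadata lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in metadata")
  rownames(d) <- d$sample_id
  class(d) <- c("sample_frame", class(d))
  d
}

#' Write a community matrix
#'
#' TSV format: a dense samples-x-OTUs counts table (first column
#' `sample_id`) plus a two-column taxonomy TSV next to it. BIOM format uses
#' the biomformat package.
#'
#' @param community A `community_matrix` or `rarefied_community`.
#' @param path Counts file (TSV) or BIOM file.
#' @param format `"tsv"` or `"biom"`.
#' @param taxonomy_path Taxonomy TSV path (default `path` with a
#'   `.taxonomy.tsv` suffix); TSV format only.
#' @export
write_community <- function(community, path, format = c("tsv", "biom"),
                            taxonomy_path = NULL) {
  format <- match.arg(format)
  counts <- community$counts
  tax <- community$taxonomy
  if (format == "tsv") {
    out <- data.frame(sample_id = rownames(counts), counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    taxonomy_path <- taxonomy_path %||% paste0(path, ".taxonomy.tsv")
    utils::write.table(
      data.frame(otu_id = names(tax), phylum = unname(tax)),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM support requires the biomformat package")
    }
    b <- biomformat::make_biom(
      data = t(counts),
      observation_metadata = data.frame(taxonomy = unname(tax[colnames(counts)]),
                                        row.names = colnames(counts)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read a community matrix
#'
#' @param path Counts TSV or BIOM file.
#' @param format `"tsv"` or `"biom"`.
#' @param taxonomy_path Taxonomy TSV (TSV format only; default derived from
#'   `path`).
#' @return A validated `community_matrix`.
#' @export
read_community <- function(path, format = c("tsv", "biom"),
                           taxonomy_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    if (names(d)[1] != "sample_id") {
      stop("community TSV must start with a sample_id column (",
           path, ", field 1)")
    }
    counts <- as.matrix(d[, -1, drop = FALSE])
    rownames(counts) <- d$sample_id
    if (any(counts < 0)) {
      bad <- which(counts < 0, arr.ind = TRUE)[1, ]
      stop("negative count at sample ", rownames(counts)[bad[1]],
           ", OTU ", colnames(counts)[bad[2]])
    }
    if (any(counts != round(counts))) stop("counts must be integers")
    taxonomy_path <- taxonomy_path %||% paste0(path, ".taxonomy.tsv")
    tx <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    taxonomy <- stats::setNames(tx$phylum, tx$otu_id)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM support requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(b)))
    om <- biomformat::observation_metadata(b)
    if (is.null(om)) stop("BIOM file lacks taxonomy metadata")
    om <- as.data.frame(om)
    taxonomy <- stats::setNames(as.character(om[[1]]), rownames(om))
  }
  community_matrix(counts, taxonomy)
}

#' Write / read a distance matrix as square TSV
#'
#' Square layout with sample ids as both header row and first column.
#'
#' @param d A `dist_matrix` (or square labelled matrix).
#' @param path File path.
#' @export
write_distance <- function(d, path) {
  m <- as_square_distance(d)
  out <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance
#' @param metric Metric name to attach on read.
#' @export
read_distance <- function(path, metric = "unknown") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  as_distance_matrix(m, metric = metric)
}
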