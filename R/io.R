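#' Read and write tab-delimited interchange files
#'
#' The on-disk interchange format is plain TSV: the feature table has
#' samples as rows and ASV ids as columns (first column `sample_id`);
#' metadata has one row per sample; taxonomy has `asv_id` plus a
#' semicolon-delimited rank string; distance matrices are labelled square
#' TSV.
#'
#' @param path file path.
#' @name wildgut-io
NULL

#' @rdname wildgut-io
#' @param mode abundance mode of the file contents.
#' @return `readFeatureTable()`: counts- or relative-mode matrix wrapped
#'   in an [AsvExperiment-class] without metadata (attach via
#'   [attachMetadata()]).
#' @export
readFeatureTable <- function(path, mode = "counts") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  AsvExperiment(m, mode = mode, samplesAsRows = TRUE)
}

#' @rdname wildgut-io
#' @param x object to write.
#' @export
writeFeatureTable <- function(x, path) {
  m <- abundances(x, samplesAsRows = TRUE)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wildgut-io
#' @export
readSampleMetadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("metadata needs a sample_id column")
  if ("date" %in% names(meta)) {
    meta$date <- as.Date(meta$date)        # ISO-8601
    if (!"day_of_year" %in% names(meta))
      meta$day_of_year <- dayOfYear365(meta$date)
  }
  rownames(meta) <- meta$sample_id
  meta
}

#' @rdname wildgut-io
#' @param meta data.frame of metadata.
#' @export
writeSampleMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wildgut-io
#' @return `readTaxonomyTable()`: data.frame with `asv_id`, the split
#'   ranks `Kingdom` ... `Genus`, the original `taxonomy` string and
#'   `is_organelle`.
#' @export
readTaxonomyTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("asv_id", "taxonomy") %in% names(df)))
  ranks <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus")
  parts <- strsplit(df$taxonomy, ";", fixed = TRUE)
  for (k in seq_along(ranks))
    df[[ranks[k]]] <- vapply(parts, function(p)
      if (length(p) >= k) p[k] else NA_character_, "")
  df$is_organelle <- grepl("chloroplast|mitochondria", df$taxonomy,
                           ignore.case = TRUE)
  rownames(df) <- df$asv_id
  df
}

#' @rdname wildgut-io
#' @param tax taxonomy data.frame (with `asv_id` and either a `taxonomy`
#'   string or rank columns).
#' @export
writeTaxonomyTable <- function(tax, path) {
  if (!"taxonomy" %in% names(tax)) {
    ranks <- intersect(c("Kingdom", "Phylum", "Class", "Order", "Family",
                         "Genus"), names(tax))
    tax$taxonomy <- apply(tax[ranks], 1L, function(r)
      paste(ifelse(is.na(r), "unassigned", r), collapse = ";"))
  }
  utils::write.table(tax[c("asv_id", "taxonomy")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wildgut-io
#' @param d distance object.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- asDistanceMatrix(d)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname wildgut-io
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}

#' Attach metadata and taxonomy to a bare feature table
#'
#' @param x an [AsvExperiment-class].
#' @param meta per-sample metadata data.frame.
#' @param tax per-ASV taxonomy data.frame (optional).
#' @return an [AsvExperiment-class] with populated colData/rowData.
#' @export
attachMetadata <- function(x, meta, tax = NULL) {
  AsvExperiment(abundances(x), sampleData = meta, taxonomy = tax,
                mode = abundanceMode(x), samplesAsRows = FALSE)
}

#' Day-of-year on a fixed 365-day cycle
#'
#' Maps calendar dates to 1..365 with Feb 29 folded onto day 59 (the
#' same index as Mar 1 shifted), keeping the seasonal cycle a constant
#' length across leap years.
#'
#' @param date a `Date` vector.
#' @return integer day-of-year in 1..365.
#' @export
dayOfYear365 <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  leap <- as.integer(strftime(date, "%Y")) %% 4 == 0 &
    (as.integer(strftime(date, "%Y")) %% 100 != 0 |
       as.integer(strftime(date, "%Y")) %% 400 == 0)
  adj <- doy
  fix <- leap & doy >= 60          # Mar 1 of a leap year is day 61
  adj[fix] <- doy[fix] - 1L
  feb29 <- leap & doy == 60
  adj[feb29] <- 59L
  adj
}

#' Import a BIOM-format JSON feature table
#'
#' Thin wrapper around the biomformat package for the common
#' interchange format.
#'
#' @param path path to a BIOM (JSON) file.
#' @param mode abundance mode of the stored values.
#' @return an [AsvExperiment-class].
#' @export
readBiomTable <- function(path, mode = "counts") {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  AsvExperiment(m, mode = mode, samplesAsRows = FALSE)
}
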