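#' Remove organelle-assigned ASVs
#'
#' Drops ASVs whose taxonomy contains "chloroplast" or "mitochondria"
#' (case-insensitive, matched as a substring at any rank): 16S primers
#' amplify plant chloroplast and host mitochondrial rRNA, which are not
#' gut bacteria. Matching is deliberately loose because reference
#' taxonomies place these labels at different ranks across versions.
#' Applied before any other filter.
#'
#' @param x counts-mode [AsvExperiment-class] whose `rowData` carries
#'   taxonomic ranks (and/or a semicolon-delimited `taxonomy` column).
#' @return The table without organelle ASVs, ASV order preserved.
#' @export
removeOrganelles <- function(x) {
  .assertMode(x, "counts")
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  if (nrow(rd) == 0L || ncol(rd) == 0L)
    stop("taxonomy (rowData) is required to remove organelle ASVs")
  rankCols <- intersect(c("Kingdom", "Phylum", "Class", "Order", "Family",
                          "Genus", "taxonomy"), names(rd))
  if (!length(rankCols))
    stop("no taxonomic rank columns found in rowData")
  txt <- do.call(paste, c(lapply(rd[rankCols], as.character), sep = ";"))
  hit <- grepl("chloroplast|mitochondria", txt, ignore.case = TRUE)
  x[!hit, ]
}

#' Drop samples below a sequencing-depth threshold
#'
#' Samples whose total read count falls below `min_reads` are removed;
#' samples at exactly `min_reads` are kept. The default of 8000 reads
#' reflects the depth at which sample completeness typically plateaus in
#' rodent gut 16S data.
#'
#' @param x counts-mode [AsvExperiment-class].
#' @param min_reads minimum per-sample read count to keep.
#' @return Filtered table; the number of dropped samples is attached as
#'   attribute `n_dropped` and reported via `message()`.
#' @export
filterLowDepth <- function(x, min_reads = 8000) {
  .assertMode(x, "counts")
  keep <- sampleDepths(x) >= min_reads
  nd <- sum(!keep)
  out <- x[, keep]
  if (ncol(out) == 0L)
    warning("all samples fall below ", min_reads, " reads")
  if (nd > 0L)
    message(nd, " sample(s) below ", min_reads, " reads removed")
  attr(out, "n_dropped") <- nd
  out
}

#' Prevalence filter for rare ASVs
#'
#' Keeps ASV j iff it has at least `min_copies` reads (default 2, i.e.
#' "more than one copy") in at least `ceiling(min_sample_fraction * n)`
#' samples (default 1% of samples). Guards against PCR/sequencing
#' artefacts and cross-talk.
#'
#' @param x counts-mode [AsvExperiment-class].
#' @param min_copies minimum per-sample copy number that counts as a
#'   qualifying detection.
#' @param min_sample_fraction minimum fraction of samples with a
#'   qualifying detection (ceiling applied).
#' @return Filtered table, ASV order preserved.
#' @export
prevalenceFilter <- function(x, min_copies = 2, min_sample_fraction = 0.01) {
  .assertMode(x, "counts")
  m <- abundances(x)
  need <- max(1, ceiling(min_sample_fraction * ncol(m)))
  keep <- rowSums(m >= min_copies) >= need
  x[keep, ]
}

#' Convert counts to per-sample relative abundance
#'
#' Divides each sample's counts by its total. Refuses already-relative
#' input (double normalisation) and all-zero samples.
#'
#' @param x counts-mode [AsvExperiment-class].
#' @return Relative-mode [AsvExperiment-class].
#' @export
toRelative <- function(x) {
  if (abundanceMode(x) == "relative")
    stop("table is already in relative mode")
  m <- abundances(x)
  tot <- colSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  rel <- sweep(m, 2L, tot, "/")
  out <- x
  SummarizedExperiment::assay(out, 1L, withDimnames = FALSE) <- rel
  out@abundanceMode <- "relative"
  methods::validObject(out)
  out
}

.assertMode <- function(x, mode) {
  stopifnot(methods::is(x, "AsvExperiment"))
  if (abundanceMode(x) != mode)
    stop("expected a ", mode, "-mode AsvExperiment, got ",
         abundanceMode(x), " mode")
  invisible(x)
}

#' Apply the standard filtering cascade
#'
#' Organelle removal, then the depth filter, then the prevalence filter —
#' the order used for amplicon beta-diversity datasets.
#'
#' @inheritParams removeOrganelles
#' @inheritParams filterLowDepth
#' @inheritParams prevalenceFilter
#' @return counts-mode filtered table; per-stage sample/ASV counts in
#'   attribute `filter_log` (data.frame stage, n_samples, n_asvs).
#' @export
standardFilter <- function(x, min_reads = 8000, min_copies = 2,
                           min_sample_fraction = 0.01) {
  log <- data.frame(stage = "input", n_samples = ncol(x), n_asvs = nrow(x))
  x <- removeOrganelles(x)
  log <- rbind(log, data.frame(stage = "organelles_removed",
                               n_samples = ncol(x), n_asvs = nrow(x)))
  x <- suppressMessages(filterLowDepth(x, min_reads))
  log <- rbind(log, data.frame(stage = "depth_filtered",
                               n_samples = ncol(x), n_asvs = nrow(x)))
  x <- prevalenceFilter(x, min_copies, min_sample_fraction)
  log <- rbind(log, data.frame(stage = "prevalence_filtered",
                               n_samples = ncol(x), n_asvs = nrow(x)))
  attr(x, "filter_log") <- log
  x
}
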