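#' AsvExperiment: a container for longitudinal ASV abundance data
#'
#' `AsvExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold a single
#' abundance assay (ASVs as rows, samples as columns) together with
#' per-sample host metadata in `colData` and per-ASV taxonomy in `rowData`.
#' The `abundanceMode` slot records whether the assay holds raw read
#' counts (`"counts"`) or per-sample relative abundances (`"relative"`);
#' analysis functions check this flag so that, for example, Bray-Curtis
#' dissimilarity is never computed on unnormalised counts by accident.
#'
#' Expected `colData` columns (created by [simulateDataset()] and
#' [readSampleMetadata()]): `individual_id`, `population`, `date`,
#' `day_of_year`, `session_id`, plus optional host covariates (`sex`,
#' `age_class`, `reproductive_status`, `body_mass`, `body_condition`,
#' `batch`). Expected `rowData` columns: the taxonomic ranks
#' `Kingdom` ... `Genus` and the derived logical `is_organelle`.
#'
#' @slot abundanceMode character; `"counts"` (non-negative integers) or
#'   `"relative"` (columns sum to 1 within 1e-9).
#'
#' @importFrom methods new validObject is callNextMethod setValidity
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("AsvExperiment",
  contains = "SummarizedExperiment",
  slots = c(abundanceMode = "character"),
  prototype = prototype(abundanceMode = "counts")
)

.validAsvExperiment <- function(object) {
  msgs <- character()
  mode <- object@abundanceMode
  if (length(mode) != 1L || !mode %in% c("counts", "relative"))
    msgs <- c(msgs, "abundanceMode must be 'counts' or 'relative'")
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    return(c(msgs, "an 'abundance' assay is required"))
  m <- SummarizedExperiment::assay(object, 1L)
  if (any(m < 0)) msgs <- c(msgs, "abundances must be non-negative")
  if (identical(mode, "counts")) {
    if (any(abs(m - round(m)) > 1e-8))
      msgs <- c(msgs, "counts mode requires integer-valued abundances")
  } else if (identical(mode, "relative") && ncol(m) > 0L) {
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-9))
      msgs <- c(msgs, "relative mode requires per-sample sums of 1 (within 1e-9)")
  }
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample identifiers must be unique")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "ASV identifiers must be unique")
  if (length(msgs)) msgs else TRUE
}

setValidity("AsvExperiment", .validAsvExperiment)

#' Construct an AsvExperiment
#'
#' @param abundance numeric matrix of abundances. Orientation is declared
#'   by `samplesAsRows`: the on-disk interchange format stores samples as
#'   rows and ASVs as columns; internally ASVs are rows (the
#'   SummarizedExperiment convention).
#' @param sampleData data.frame (or DataFrame) of per-sample metadata with
#'   a `sample_id` column or row names matching the sample identifiers.
#' @param taxonomy data.frame of per-ASV taxonomy with an `asv_id` column
#'   or row names matching ASV identifiers; may be `NULL`.
#' @param mode `"counts"` or `"relative"`.
#' @param samplesAsRows logical; if `TRUE` (default) `abundance` has
#'   samples as rows and is transposed internally.
#'
#' @return An [AsvExperiment-class] object.
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("S", 1:3), paste0("ASV", 1:4)))
#' ae <- AsvExperiment(m, data.frame(sample_id = rownames(m),
#'                                   individual_id = c("M1", "M1", "M2")))
#' @export
AsvExperiment <- function(abundance, sampleData = NULL, taxonomy = NULL,
                          mode = c("counts", "relative"),
                          samplesAsRows = TRUE) {
  mode <- match.arg(mode)
  abundance <- as.matrix(abundance)
  if (samplesAsRows) abundance <- t(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("ASV_%04d", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("S%04d", seq_len(ncol(abundance)))

  cd <- .alignMetaFrame(sampleData, colnames(abundance), "sample_id",
                        "sample metadata")
  rd <- .alignMetaFrame(taxonomy, rownames(abundance), "asv_id",
                        "taxonomy", allowNull = TRUE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = cd, rowData = rd
  )
  new("AsvExperiment", se, abundanceMode = mode)
}

## match a metadata frame to identifiers, erroring on gaps or duplicates
.alignMetaFrame <- function(df, ids, keyCol, what, allowNull = FALSE) {
  if (is.null(df)) {
    if (!allowNull && length(ids))
      return(S4Vectors::DataFrame(row.names = ids))
    return(S4Vectors::DataFrame(row.names = ids))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (keyCol %in% names(df)) {
    keys <- as.character(df[[keyCol]])
  } else {
    keys <- rownames(df)
  }
  if (anyDuplicated(keys))
    stop("duplicate identifiers in ", what)
  missing <- setdiff(ids, keys)
  if (length(missing))
    stop("missing ", what, " for: ", paste(utils::head(missing, 5), collapse = ", "))
  df <- df[match(ids, keys), , drop = FALSE]
  rownames(df) <- ids
  S4Vectors::DataFrame(df)
}

#' Accessors for AsvExperiment
#'
#' `abundances()` returns the assay matrix (optionally samples-as-rows),
#' `abundanceMode()` the `"counts"`/`"relative"` flag, `sampleData()` the
#' per-sample metadata as a base data.frame, `taxonomy()` the per-ASV
#' taxonomy, `sampleIds()`/`asvIds()` the identifier vectors, and
#' `sampleDepths()` per-sample totals.
#'
#' @param x an [AsvExperiment-class].
#' @param samplesAsRows return the matrix with samples as rows?
#' @return See individual descriptions.
#' @name AsvExperiment-accessors
NULL

#' @rdname AsvExperiment-accessors
#' @export
abundances <- function(x, samplesAsRows = FALSE) {
  m <- SummarizedExperiment::assay(x, 1L)
  if (samplesAsRows) t(m) else m
}

#' @rdname AsvExperiment-accessors
#' @export
abundanceMode <- function(x) x@abundanceMode

#' @rdname AsvExperiment-accessors
#' @export
sampleData <- function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  df$sample_id <- colnames(x)
  df
}

#' @rdname AsvExperiment-accessors
#' @export
taxonomy <- function(x) {
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  df$asv_id <- rownames(x)
  df
}

#' @rdname AsvExperiment-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname AsvExperiment-accessors
#' @export
asvIds <- function(x) rownames(x)

#' @rdname AsvExperiment-accessors
#' @export
sampleDepths <- function(x) colSums(abundances(x))

#' @describeIn AsvExperiment-class compact display
#' @param object an AsvExperiment
#' @export
setMethod("show", "AsvExperiment", function(object) {
  cat("AsvExperiment (", object@abundanceMode, " mode): ",
      nrow(object), " ASVs x ", ncol(object), " samples\n", sep = "")
  sd <- SummarizedExperiment::colData(object)
  if ("individual_id" %in% colnames(sd))
    cat("  individuals: ", length(unique(sd$individual_id)), "\n", sep = "")
  if ("population" %in% colnames(sd))
    cat("  populations: ",
        paste(unique(as.character(sd$population)), collapse = ", "),
        "\n", sep = "")
  callNextMethod()
})
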