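#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum_j |x_j - y_j| / sum_j (x_j + y_j). On relative-abundance
#' rows the denominator is 2, so d = sum|x - y| / 2. Requires relative
#' mode: normalisation is a documented prerequisite, and accepting raw
#' counts here silently conflates depth differences with composition.
#'
#' @param x relative-mode [AsvExperiment-class].
#' @return A [stats::dist] object with `attr(, "metric") = "bray_curtis"`.
#' @export
brayCurtis <- function(x) {
  .assertMode(x, "relative")
  m <- abundances(x, samplesAsRows = TRUE)
  manh <- as.matrix(stats::dist(m, method = "manhattan"))
  tot <- rowSums(m)
  denom <- outer(tot, tot, "+")
  d <- manh / denom
  d[denom == 0] <- 0
  .asDist(d, "bray_curtis")
}

#' Jaccard dissimilarity between samples
#'
#' d(A, B) = 1 - |A n B| / |A u B| over presence sets (presence = any
#' nonzero abundance). Two all-absent samples have d = 0 by convention.
#'
#' @param x an [AsvExperiment-class] (counts or relative mode).
#' @return A [stats::dist] object with `attr(, "metric") = "jaccard"`.
#' @export
jaccardDissimilarity <- function(x) {
  stopifnot(methods::is(x, "AsvExperiment"))
  p <- abundances(x, samplesAsRows = TRUE) > 0
  storage.mode(p) <- "numeric"
  inter <- p %*% t(p)
  sz <- rowSums(p)
  union <- outer(sz, sz, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  .asDist(d, "jaccard")
}

.asDist <- function(m, metric) {
  diag(m) <- 0
  d <- stats::as.dist(m)
  attr(d, "metric") <- metric
  d
}

#' Coerce a dissimilarity object to a labelled matrix
#'
#' @param d a `dist` or square symmetric matrix.
#' @return symmetric numeric matrix with sample labels.
#' @export
asDistanceMatrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12)
    stop("distance input must be symmetric")
  m
}

#' Mean pairwise Jaccard index within and between groups
#'
#' For every pair of groups (including each group with itself) reports
#' the mean, over sample pairs, of the Jaccard *index* |A n B| / |A u B|
#' — the expected fraction of ASVs shared by two samples, as used to
#' summarise ASV sharing between host populations. Within-group means
#' exclude self-pairs.
#'
#' @param x an [AsvExperiment-class]; presence = abundance > 0.
#' @param groups factor/character of length `ncol(x)` (e.g. population).
#' @return data.frame with `group_a`, `group_b`, `mean_jaccard_index`,
#'   `n_pairs`; within-group rows for singleton groups carry `NA` and are
#'   flagged in column `degenerate`.
#' @export
meanPairwiseJaccardIndex <- function(x, groups) {
  stopifnot(length(groups) == ncol(x))
  groups <- as.character(groups)
  sim <- 1 - asDistanceMatrix(jaccardDissimilarity(x))
  gl <- unique(groups)
  out <- list()
  for (i in seq_along(gl)) for (j in seq(i, length(gl))) {
    ia <- which(groups == gl[i]); ib <- which(groups == gl[j])
    if (i == j) {
      if (length(ia) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          group_a = gl[i], group_b = gl[j],
          mean_jaccard_index = NA_real_, n_pairs = 0L, degenerate = TRUE)
        next
      }
      vals <- sim[ia, ia][upper.tri(matrix(0, length(ia), length(ia)))]
    } else {
      vals <- as.vector(sim[ia, ib])
    }
    out[[length(out) + 1L]] <- data.frame(
      group_a = gl[i], group_b = gl[j],
      mean_jaccard_index = mean(vals), n_pairs = length(vals),
      degenerate = FALSE)
  }
  do.call(rbind, out)
}
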