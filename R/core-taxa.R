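#' Subsampled population-wide prevalence
#'
#' Estimates each ASV's prevalence as the fraction of individuals in
#' whose (single, randomly selected) sample it is detected, averaged over
#' `n_iter` random selections. Selecting one sample per individual per
#' iteration removes the bias from unequal capture numbers in
#' capture-mark-recapture sampling.
#'
#' @param x an [AsvExperiment-class]; detection is any nonzero abundance.
#' @param n_iter number of subsampling iterations.
#' @param seed integer seed; results are reproducible given it.
#' @return named numeric vector of per-ASV prevalence in [0, 1].
#' @export
subsampledPrevalence <- function(x, n_iter = 100, seed = 1) {
  meta <- sampleData(x)
  if (!"individual_id" %in% names(meta))
    stop("sample metadata must contain individual_id")
  inds <- split(seq_len(ncol(x)), meta$individual_id)
  if (length(inds) < 2L)
    stop("subsampled prevalence needs >= 2 individuals")
  present <- abundances(x) > 0
  acc <- numeric(nrow(x))
  .withSubSeed(seed, "prevalence", {
    for (it in seq_len(n_iter)) {
      sel <- vapply(inds, function(ix)
        if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)], 0L)
      acc <- acc + rowMeans(present[, sel, drop = FALSE])
    }
  })
  stats::setNames(acc / n_iter, rownames(x))
}

#' Within-individual persistence
#'
#' For each individual with at least `min_captures` samples, the fraction
#' of that individual's samples in which an ASV is detected; persistence
#' is the mean of these fractions over eligible individuals. High
#' persistence marks taxa stably carried by their hosts rather than
#' transient passengers.
#'
#' @param x an [AsvExperiment-class].
#' @param min_captures minimum samples per individual for eligibility.
#' @return named numeric vector of per-ASV persistence in [0, 1], with
#'   attribute `n_individuals` (number eligible).
#' @export
persistence <- function(x, min_captures = 3) {
  meta <- sampleData(x)
  inds <- split(seq_len(ncol(x)), meta$individual_id)
  inds <- inds[lengths(inds) >= min_captures]
  if (!length(inds))
    stop("no individual has >= ", min_captures, " samples")
  present <- abundances(x) > 0
  fr <- vapply(inds, function(ix) rowMeans(present[, ix, drop = FALSE]),
               numeric(nrow(x)))
  out <- stats::setNames(rowMeans(fr), rownames(x))
  attr(out, "n_individuals") <- length(inds)
  out
}

#' Spearman correlation between prevalence and persistence
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks (ties
#' receive average ranks); the p-value uses the large-sample t
#' approximation with n - 2 degrees of freedom.
#'
#' @param prevalence,persistence numeric vectors, matched by position (or
#'   by names if both are named).
#' @return list with `rho`, `p_value`, `n`.
#' @export
prevalencePersistenceCorrelation <- function(prevalence, persistence) {
  if (!is.null(names(prevalence)) && !is.null(names(persistence)))
    persistence <- persistence[names(prevalence)]
  ok <- stats::complete.cases(prevalence, persistence)
  p <- prevalence[ok]; q <- persistence[ok]
  n <- length(p)
  if (n < 3L) stop("need >= 3 ASVs")
  if (stats::sd(p) == 0 || stats::sd(q) == 0) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(p), rank(q))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  if (abs(rho) == 1) pv <- 0
  list(rho = rho, p_value = pv, n = n)
}

#' Delimit the core ASV set by joint prevalence-abundance thresholds
#'
#' An ASV is core when the fraction of samples in which it reaches at
#' least `abundance_threshold` relative abundance is at least
#' `prevalence_threshold` (defaults: present in >= 60% of samples at
#' >= 0.1% relative abundance). By default a sample counts toward
#' prevalence only when the ASV clears the abundance threshold *in that
#' sample* (joint reading); `joint = FALSE` instead applies two marginal
#' conditions — detection prevalence >= `prevalence_threshold` and
#' abundance >= `abundance_threshold` in at least one sample.
#' Both comparisons are inclusive.
#'
#' @param x relative-mode [AsvExperiment-class].
#' @param prevalence_threshold minimum qualifying-sample fraction, in [0,1].
#' @param abundance_threshold minimum within-sample relative abundance,
#'   in [0,1].
#' @param joint use the joint per-sample reading (default TRUE).
#' @return character vector of core ASV ids, with the per-ASV qualifying
#'   fraction as attribute `qualifying_fraction`.
#' @export
coreSet <- function(x, prevalence_threshold = 0.60,
                    abundance_threshold = 0.001, joint = TRUE) {
  .assertMode(x, "relative")
  if (prevalence_threshold < 0 || prevalence_threshold > 1 ||
      abundance_threshold < 0 || abundance_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  m <- abundances(x)
  if (joint) {
    qual <- rowMeans(m >= abundance_threshold)
    core <- qual >= prevalence_threshold
  } else {
    qual <- rowMeans(m > 0)
    core <- qual >= prevalence_threshold & rowSums(m >= abundance_threshold) > 0
  }
  out <- rownames(m)[core]
  attr(out, "qualifying_fraction") <- stats::setNames(qual, rownames(m))
  out
}

#' Per-ASV core-taxa report
#'
#' Combines subsampled prevalence, persistence and core membership into
#' one table, recording the thresholds and seed used.
#'
#' @param counts counts-mode table (for detection-based prevalence and
#'   persistence).
#' @param rel relative-mode table (for the abundance-based core
#'   criterion); defaults to `toRelative(counts)`.
#' @inheritParams subsampledPrevalence
#' @inheritParams persistence
#' @inheritParams coreSet
#' @return data.frame, one row per ASV: `asv_id`, `prevalence`,
#'   `persistence`, `core`; thresholds and seed in attributes.
#' @export
coreTaxaReport <- function(counts, rel = NULL, n_iter = 100,
                           min_captures = 3, prevalence_threshold = 0.60,
                           abundance_threshold = 0.001, seed = 1) {
  if (is.null(rel)) rel <- toRelative(counts)
  P <- subsampledPrevalence(counts, n_iter = n_iter, seed = seed)
  psi <- persistence(counts, min_captures = min_captures)
  core <- coreSet(rel, prevalence_threshold, abundance_threshold)
  out <- data.frame(asv_id = rownames(counts),
                    prevalence = as.numeric(P[rownames(counts)]),
                    persistence = as.numeric(psi[rownames(counts)]),
                    core = rownames(counts) %in% core,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(
    prevalence_threshold = prevalence_threshold,
    abundance_threshold = abundance_threshold,
    min_captures = min_captures, n_iterations = n_iter, seed = seed)
  out
}
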