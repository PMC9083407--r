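#' OrdinationResult: principal-coordinates output
#'
#' Holds sample scores, the full eigenvalue spectrum (descending), the
#' proportion of variance explained per retained axis (computed over
#' positive eigenvalues only), and the relative mass of negative
#' eigenvalues (nonzero for non-Euclidean metrics such as Bray-Curtis).
#'
#' @slot sampleIds character sample identifiers.
#' @slot coordinates numeric matrix, samples x axes; column c has squared
#'   norm equal to eigenvalue c.
#' @slot eigenvalues full spectrum, descending.
#' @slot proportionExplained per retained axis; sums to <= 1.
#' @slot negativeEigenvalueMass sum(|negative|) / sum(|all|).
#' @export
setClass("OrdinationResult",
  slots = c(sampleIds = "character", coordinates = "matrix",
            eigenvalues = "numeric", proportionExplained = "numeric",
            negativeEigenvalueMass = "numeric"))

setValidity("OrdinationResult", function(object) {
  msgs <- character()
  if (nrow(object@coordinates) != length(object@sampleIds))
    msgs <- c(msgs, "coordinate rows must match sampleIds")
  if (length(object@proportionExplained) &&
      sum(object@proportionExplained) > 1 + 1e-8)
    msgs <- c(msgs, "proportionExplained must sum to <= 1")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OrdinationResult-class compact display
#' @param object an OrdinationResult
#' @export
setMethod("show", "OrdinationResult", function(object) {
  k <- ncol(object@coordinates)
  cat("OrdinationResult: ", length(object@sampleIds), " samples, ",
      k, " axes\n", sep = "")
  if (k > 0)
    cat("  PC1 explains ",
        sprintf("%.1f%%", 100 * object@proportionExplained[1]),
        " of positive-eigenvalue variance\n", sep = "")
  cat("  negative eigenvalue mass: ",
      sprintf("%.3f", object@negativeEigenvalueMass), "\n", sep = "")
})

#' @rdname OrdinationResult-class
#' @param x an OrdinationResult
#' @param axes which axes to return.
#' @export
scores <- function(x, axes = NULL) {
  if (is.null(axes)) x@coordinates
  else x@coordinates[, axes, drop = FALSE]
}

#' @rdname OrdinationResult-class
#' @export
eigenvalues <- function(x) x@eigenvalues

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower-centres -0.5 * D^2 with the centring projector J = I - 11'/n,
#' eigendecomposes the resulting symmetric matrix, and scales the
#' eigenvectors of positive eigenvalues by sqrt(lambda). Axes are ordered
#' by descending eigenvalue; each axis's sign is fixed deterministically
#' so that its largest-magnitude loading is positive, making PC1
#' trajectories reproducible across runs. Negative eigenvalues (expected
#' for Bray-Curtis) are retained in the spectrum but excluded from
#' coordinates and from `proportionExplained`. The optional Lingoes
#' correction adds a constant to squared off-diagonal distances to make
#' the matrix Euclidean-embeddable.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities.
#' @param axes number of axes to retain (default: all positive).
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return An [OrdinationResult-class].
#' @examples
#' D <- as.dist(matrix(c(0, 3, 4, 3, 0, 1, 4, 1, 0), 3))
#' pcoa(D)  # one positive eigenvalue, 78/9
#' @export
pcoa <- function(d, axes = NULL, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  D <- asDistanceMatrix(d)
  n <- nrow(D)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  A <- -0.5 * D^2
  G <- .gowerCentre(A)
  e <- eigen(G, symmetric = TRUE)
  if (correction == "lingoes" && min(e$values) < -1e-12) {
    c1 <- -min(e$values)
    D2 <- D^2 + 2 * c1
    diag(D2) <- 0
    G <- .gowerCentre(-0.5 * D2)
    e <- eigen(G, symmetric = TRUE)
  }
  ev <- e$values
  tol <- max(abs(ev)) * 1e-10
  pos <- which(ev > tol)
  if (!is.null(axes)) pos <- pos[seq_len(min(axes, length(pos)))]
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), nrow = length(pos))
  ## deterministic sign: largest-|loading| element positive
  for (c in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, c]))
    if (coords[i, c] < 0) coords[, c] <- -coords[, c]
  }
  rownames(coords) <- ids
  colnames(coords) <- if (ncol(coords)) paste0("PC", seq_len(ncol(coords)))
  negMass <- if (any(ev < 0)) sum(abs(ev[ev < 0])) / sum(abs(ev)) else 0
  methods::new("OrdinationResult",
    sampleIds = ids, coordinates = coords, eigenvalues = ev,
    proportionExplained = if (length(pos)) ev[pos] / sum(ev[ev > tol]) else numeric(),
    negativeEigenvalueMass = negMass)
}

.gowerCentre <- function(A) {
  n <- nrow(A)
  rm <- rowMeans(A); cm <- colMeans(A); gm <- mean(A)
  G <- A - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + gm
  (G + t(G)) / 2
}
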