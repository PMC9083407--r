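#' Harmonic (cyclic) regression of a per-sample response on day-of-year
#'
#' Least-squares fit of `response ~ sum_k a_k cos(2 pi k doy/365) +
#' b_k sin(2 pi k doy/365) + covariates`. The first harmonic yields a
#' derived seasonal amplitude `sqrt(a1^2 + b1^2)` and peak day-of-year
#' `(365/2pi) atan2(b1, a1)`. Repeated measures on individuals can be
#' absorbed by within-individual centring of the response and all
#' regressors (`random_intercept_individual = TRUE`), a fixed-effects
#' approximation to an individual random intercept. The seasonal R^2 is
#' the drop in residual sum of squares attributable to the harmonic
#' terms over the total sum of squares (of the possibly-centred
#' response). With multiple calendar years in `meta$date`, the harmonic
#' terms are interacted with year so each year gets its own seasonal
#' curve (`year_interaction = TRUE` by default; ignored for single-year
#' data).
#'
#' @param response numeric per-sample response (e.g. PC1 scores).
#' @param meta per-sample metadata with `day_of_year` (and
#'   `individual_id` if centring, `date` if year interactions).
#' @param K harmonic order (>= 0; 0 = covariates-only model).
#' @param covariates character vector of metadata columns to adjust for.
#' @param random_intercept_individual centre within individuals?
#' @param year_interaction interact harmonics with sampling year?
#' @return list of class `wg_seasonalfit`: `K`, `coefficients`,
#'   `amplitude`, `peak_day`, `seasonal_r_squared`, `n`, `fit`.
#' @examples
#' doy <- seq(1, 365, by = 10)
#' y <- cos(2 * pi * (doy - 280) / 365)
#' f <- harmonicSeasonalFit(y, data.frame(day_of_year = doy), K = 1)
#' round(f$peak_day)  # 280
#' @export
harmonicSeasonalFit <- function(response, meta, K = 2, covariates = NULL,
                                random_intercept_individual = FALSE,
                                year_interaction = TRUE) {
  if (K < 0) stop("K must be >= 0")
  n <- length(response)
  stopifnot(nrow(meta) == n, "day_of_year" %in% names(meta))
  if (n < 2 * K + length(covariates) + 2)
    stop("too few samples for K = ", K)
  doy <- meta$day_of_year
  H <- NULL
  if (K > 0) {
    H <- do.call(cbind, lapply(seq_len(K), function(k)
      cbind(cos(2 * pi * k * doy / 365), sin(2 * pi * k * doy / 365))))
    colnames(H) <- as.vector(t(outer(seq_len(K), c("cos", "sin"),
                                     function(k, f) paste0(f, k))))
    if (year_interaction && "date" %in% names(meta)) {
      yr <- factor(format(as.Date(meta$date), "%Y"))
      if (nlevels(yr) > 1L) {
        Z <- stats::model.matrix(~ yr)          # year main effects
        Hy <- do.call(cbind, lapply(levels(yr), function(l) {
          Hk <- H * (yr == l)
          colnames(Hk) <- paste0(colnames(H), "_", l)
          Hk
        }))
        H <- cbind(Hy, Z[, -1, drop = FALSE])
      }
    }
  }
  X <- NULL
  if (length(covariates)) {
    X <- stats::model.matrix(
      stats::reformulate(covariates),
      data = as.data.frame(meta))[, -1, drop = FALSE]
    if (qr(cbind(1, X))$rank < ncol(X) + 1)
      warning("collinear covariates in seasonal model")
  }
  y <- response
  if (random_intercept_individual) {
    stopifnot("individual_id" %in% names(meta))
    ctr <- function(v) stats::ave(v, meta$individual_id) # individual means
    y <- y - ctr(y)
    if (!is.null(H)) H <- apply(H, 2L, function(cl) cl - ctr(cl))
    if (!is.null(X)) X <- apply(X, 2L, function(cl) cl - ctr(cl))
  }
  full <- cbind(H, X)
  fit <- if (is.null(full)) stats::lm(y ~ 1) else stats::lm(y ~ full)
  rss_full <- sum(stats::residuals(fit)^2)
  fit0 <- if (is.null(X)) stats::lm(y ~ 1) else stats::lm(y ~ X)
  tss <- sum((y - mean(y))^2)
  seas_r2 <- if (K > 0 && tss > 0)
    max(0, (sum(stats::residuals(fit0)^2) - rss_full) / tss) else 0
  cf <- stats::coef(fit)
  names(cf) <- sub("^full", "", names(cf))
  amplitude <- 0; peak <- NA_real_
  if (K > 0) {
    ## pooled first-harmonic coefficients (averaged over year curves)
    a1 <- mean(cf[grep("^cos1", names(cf))], na.rm = TRUE)
    b1 <- mean(cf[grep("^sin1", names(cf))], na.rm = TRUE)
    amplitude <- sqrt(a1^2 + b1^2)
    peak <- (365 / (2 * pi)) * atan2(b1, a1)
    peak <- ((peak - 1) %% 365) + 1
  }
  structure(list(K = K, coefficients = cf, amplitude = amplitude,
                 peak_day = peak, seasonal_r_squared = seas_r2,
                 n = n, fit = fit),
            class = "wg_seasonalfit")
}

#' @export
print.wg_seasonalfit <- function(x, ...) {
  cat("Harmonic seasonal fit (K = ", x$K, ", n = ", x$n, ")\n", sep = "")
  cat("  amplitude = ", format(x$amplitude, digits = 4),
      ", peak day = ", round(x$peak_day, 1),
      ", seasonal R^2 = ", format(x$seasonal_r_squared, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Paired within-individual seasonal contrast
#'
#' Averages the response per individual within each of two month
#' windows, keeps individuals observed in both, and applies a paired
#' two-sided t test — does each animal's microbiota shift between
#' seasons in a consistent direction?
#'
#' @param response numeric per-sample response.
#' @param meta metadata with `individual_id` and `date` (or
#'   `month_of_year`).
#' @param window_a,window_b integer month-of-year sets, e.g. `6:8` vs
#'   `9:11`.
#' @return list of class `wg_pairedtest`: `t`, `df`, `n`, `p_value`,
#'   `mean_difference` (b - a), `window_a`, `window_b`.
#' @export
pairedSeasonContrast <- function(response, meta, window_a, window_b) {
  stopifnot(length(response) == nrow(meta))
  mo <- if ("month_of_year" %in% names(meta)) meta$month_of_year
        else as.integer(format(as.Date(meta$date), "%m"))
  ia <- mo %in% window_a; ib <- mo %in% window_b
  ma <- tapply(response[ia], meta$individual_id[ia], mean)
  mb <- tapply(response[ib], meta$individual_id[ib], mean)
  common <- intersect(names(ma), names(mb))
  if (length(common) < 2L)
    stop("need >= 2 individuals sampled in both windows")
  dif <- mb[common] - ma[common]
  if (stats::sd(dif) == 0) {
    ## degenerate: identical shifts give an undefined t; report the limit
    tt <- list(statistic = if (mean(dif) == 0) 0 else Inf * sign(mean(dif)),
               parameter = length(dif) - 1,
               p.value = if (mean(dif) == 0) 1 else 0,
               estimate = mean(dif))
  } else {
    tt <- stats::t.test(mb[common], ma[common], paired = TRUE)
  }
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 n = length(common), p_value = tt$p.value,
                 mean_difference = unname(tt$estimate),
                 window_a = window_a, window_b = window_b),
            class = "wg_pairedtest")
}

#' @export
print.wg_pairedtest <- function(x, ...) {
  cat("Paired seasonal contrast (months ",
      paste(x$window_a, collapse = ","), " vs ",
      paste(x$window_b, collapse = ","), ")\n", sep = "")
  cat("  t = ", format(x$t, digits = 4), ", df = ", x$df,
      ", n = ", x$n, ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Permutational multivariate ANOVA on a dissimilarity matrix
#'
#' Distance-based linear modelling: with G the Gower-centred -0.5 D^2
#' matrix, the sum of squares explained by a model matrix X is
#' tr(H G H) with H the hat matrix of X. In `marginal` mode each term's
#' SS is SS(full) - SS(without that term); in `sequential` mode terms are
#' added in formula order. pseudo-F_T = (SS_T / df_T) / (SS_res /
#' df_res) with residual df = n - rank(full). Significance comes from
#' permuting the sample rows of D (raw permutation) `n_perm` times;
#' partial R^2 = SS_T / SS_total.
#'
#' @param d `dist`/matrix of dissimilarities.
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ month + sex + body_mass`.
#' @param data per-sample design data.frame, rows matching `d`'s samples
#'   (matched by `sample_id` column or row names when present).
#' @param n_perm permutations.
#' @param mode `"marginal"` (default) or `"sequential"`.
#' @param seed integer seed.
#' @return data.frame of class `wg_permanova`: one row per term plus
#'   Residual and Total: `term`, `df`, `SS`, `pseudo_F`, `p_value`,
#'   `partial_r2`; attributes `n_perm`, `mode`, `seed`.
#' @export
permanova <- function(d, formula, data, n_perm = 999,
                      mode = c("marginal", "sequential"), seed = 1) {
  mode <- match.arg(mode)
  D <- asDistanceMatrix(d)
  n <- nrow(D)
  data <- as.data.frame(data)
  if (!is.null(rownames(D))) {
    key <- if ("sample_id" %in% names(data)) data$sample_id else rownames(data)
    if (all(rownames(D) %in% key)) data <- data[match(rownames(D), key), ]
  }
  stopifnot(nrow(data) == n)
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  if (!length(labels)) stop("formula has no terms")
  Xfull <- stats::model.matrix(tt, data = data)
  asg <- attr(Xfull, "assign")
  qrF <- qr(Xfull)
  if (qrF$rank < ncol(Xfull)) {
    keep <- qrF$pivot[seq_len(qrF$rank)]
    aliased <- unique(labels[asg[setdiff(seq_len(ncol(Xfull)), keep)]])
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  G <- .gowerCentre(-0.5 * D^2)
  SStot <- sum(diag(G))
  hat <- function(X) { q <- qr(X); tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE]) }
  ssModel <- function(H, Gm) sum(H * Gm)  # tr(H G) for symmetric H, G
  Hfull <- hat(Xfull)
  SSfull <- ssModel(Hfull, G)
  dfRes <- n - qr(Xfull)$rank
  ssTol <- 1e-10 * max(abs(SStot), 1)
  clampRes <- function(ss) if (abs(ss) < ssTol) 0 else ss
  SSres <- clampRes(SStot - SSfull)

  termCols <- lapply(seq_along(labels), function(k) which(asg == k))
  Hred <- vector("list", length(labels))
  df <- SS <- numeric(length(labels))
  for (k in seq_along(labels)) {
    if (mode == "marginal") {
      Xr <- Xfull[, asg != k, drop = FALSE]
    } else {
      Xr <- Xfull[, asg < k, drop = FALSE]
    }
    Hr <- hat(Xr)
    Hred[[k]] <- Hr
    if (mode == "marginal") {
      SS[k] <- SSfull - ssModel(Hr, G)
      df[k] <- qr(Xfull)$rank - qr(Xr)$rank
    } else {
      Hk <- hat(Xfull[, asg <= k, drop = FALSE])
      SS[k] <- ssModel(Hk, G) - ssModel(Hr, G)
      df[k] <- qr(Xfull[, asg <= k, drop = FALSE])$rank - qr(Xr)$rank
      Hred[[k]] <- list(Hr, Hk)
    }
  }
  Fobs <- if (SSres == 0) rep(Inf, length(SS)) else
    (SS / df) / (SSres / dfRes)

  exceed <- rep(0L, length(labels))
  .withSubSeed(seed, "permanova", {
    for (p in seq_len(n_perm)) {
      pm <- sample.int(n)
      Gp <- G[pm, pm]
      SSfp <- ssModel(Hfull, Gp)
      SSrp <- clampRes(SStot - SSfp)
      for (k in seq_along(labels)) {
        if (mode == "marginal") {
          SSk <- SSfp - ssModel(Hred[[k]], Gp)
        } else {
          SSk <- ssModel(Hred[[k]][[2]], Gp) - ssModel(Hred[[k]][[1]], Gp)
        }
        Fp <- if (SSrp == 0) Inf else (SSk / df[k]) / (SSrp / dfRes)
        if (is.nan(Fobs[k]) || Fp >= Fobs[k])
          exceed[k] <- exceed[k] + 1L
      }
    }
  })
  pvals <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(df, dfRes, n - 1),
    SS = c(SS, SSres, SStot),
    pseudo_F = c(Fobs, NA, NA),
    p_value = c(pvals, NA, NA),
    partial_r2 = c(SS / SStot, SSres / SStot, 1),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  class(out) <- c("wg_permanova", "data.frame")
  out
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the samples by PCoA on the positive-eigenvalue axes (optionally
#' after a Lingoes correction), computes each sample's Euclidean distance
#' to its group's spatial median in that space, and tests equality of
#' mean distance-to-median across groups with a one-way F statistic whose
#' null distribution is built by permuting group labels. A significant
#' PERMANOVA term with heterogeneous dispersion may reflect spread rather
#' than location differences.
#'
#' @param d `dist`/matrix of dissimilarities.
#' @param grouping factor/character of group labels per sample.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @param correction passed to [pcoa()].
#' @param centroid `"spatial_median"` (default) or `"mean"`.
#' @return list of class `wg_dispersion`: `F`, `df1`, `df2`, `p_value`,
#'   `group_means` (mean distance-to-centroid per group), `n_perm`,
#'   `dropped_singletons`.
#' @export
dispersionTest <- function(d, grouping, n_perm = 999, seed = 1,
                           correction = "none",
                           centroid = c("spatial_median", "mean")) {
  centroid <- match.arg(centroid)
  grouping <- as.character(grouping)
  D <- asDistanceMatrix(d)
  stopifnot(length(grouping) == nrow(D))
  tab <- table(grouping)
  dropped <- names(tab)[tab < 2L]
  if (length(dropped)) {
    message("dropping singleton group(s): ", paste(dropped, collapse = ", "))
    keep <- !grouping %in% dropped
    D <- D[keep, keep]; grouping <- grouping[keep]
  }
  if (length(unique(grouping)) < 2L)
    stop("dispersion test needs >= 2 groups of >= 2 samples")
  ord <- pcoa(D, correction = correction)
  Y <- scores(ord)
  z <- numeric(nrow(Y))
  for (g in unique(grouping)) {
    ix <- which(grouping == g)
    ctr <- if (centroid == "mean") colMeans(Y[ix, , drop = FALSE])
           else .spatialMedian(Y[ix, , drop = FALSE])
    z[ix] <- sqrt(rowSums(sweep(Y[ix, , drop = FALSE], 2L, ctr)^2))
  }
  Fstat <- function(z, g) {
    fit <- stats::anova(stats::lm(z ~ factor(g)))
    fit$`F value`[1L]
  }
  Fobs <- Fstat(z, grouping)
  nullF <- .withSubSeed(seed, "dispersion", {
    vapply(seq_len(n_perm), function(p) Fstat(z, sample(grouping)), 0)
  })
  k <- length(unique(grouping))
  structure(list(
    F = Fobs, df1 = k - 1, df2 = length(z) - k,
    p_value = (1 + sum(nullF >= Fobs)) / (n_perm + 1),
    group_means = tapply(z, grouping, mean),
    n_perm = n_perm, dropped_singletons = dropped),
    class = "wg_dispersion")
}

#' @export
print.wg_dispersion <- function(x, ...) {
  cat("Multivariate dispersion test\n")
  cat("  F(", x$df1, ",", x$df2, ") = ", format(x$F, digits = 4),
      ", permutation p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

## Weiszfeld algorithm for the geometric (spatial) median
.spatialMedian <- function(Y, tol = 1e-8, maxit = 200) {
  m <- colMeans(Y)
  for (it in seq_len(maxit)) {
    dist <- sqrt(rowSums(sweep(Y, 2L, m)^2))
    if (any(dist < 1e-12)) return(m)
    w <- 1 / dist
    m2 <- colSums(Y * w) / sum(w)
    if (sqrt(sum((m2 - m)^2)) < tol) return(m2)
    m <- m2
  }
  m
}

#' Subset to one randomly chosen sample per individual
#'
#' Avoids pseudoreplication in tests that assume independent samples
#' (e.g. PERMANOVA). Uniform random choice per individual,
#' seed-reproducible.
#'
#' @param x an [AsvExperiment-class], `dist`, or distance matrix.
#' @param meta metadata (required for `dist`/matrix input; for an
#'   `AsvExperiment` the internal metadata is used).
#' @param seed integer seed.
#' @return object of the same kind restricted to the chosen samples; the
#'   chosen sample ids are attached as attribute `chosen`.
#' @export
oneSamplePerIndividual <- function(x, meta = NULL, seed = 1) {
  if (methods::is(x, "AsvExperiment")) {
    meta <- sampleData(x)
    ids <- colnames(x)
  } else {
    x <- asDistanceMatrix(x)
    ids <- rownames(x)
    stopifnot(!is.null(meta))
    meta <- meta[match(ids, meta$sample_id), ]
  }
  chosen <- .withSubSeed(seed, "one_per_individual", {
    unlist(lapply(split(ids, meta$individual_id), function(s)
      if (length(s) == 1L) s else s[sample.int(length(s), 1L)]),
      use.names = FALSE)
  })
  chosen <- ids[ids %in% chosen]  # preserve original order
  out <- if (methods::is(x, "AsvExperiment")) x[, chosen]
         else x[chosen, chosen]
  attr(out, "chosen") <- chosen
  out
}

#' Per-ASV association with an ordination axis
#'
#' Spearman correlation of each ASV's relative abundance with a
#' per-sample score (e.g. PC1). This is a deliberately simple screen for
#' taxa tracking an axis; it is *not* a variable-importance measure and
#' makes no claim about predictive contribution.
#'
#' @param x relative-mode [AsvExperiment-class].
#' @param axis_scores numeric per-sample scores matching `ncol(x)`.
#' @return data.frame: `asv_id`, `rho`, `abs_rho`, sorted by `abs_rho`
#'   descending.
#' @export
axisAssociation <- function(x, axis_scores) {
  .assertMode(x, "relative")
  stopifnot(length(axis_scores) == ncol(x))
  m <- abundances(x)
  rho <- apply(m, 1L, function(v)
    suppressWarnings(stats::cor(v, axis_scores, method = "spearman")))
  out <- data.frame(asv_id = rownames(m), rho = rho,
                    abs_rho = abs(rho), stringsAsFactors = FALSE)
  out[order(-out$abs_rho), ]
}
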