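#' Enumerate and type all sample pairs
#'
#' Every unordered sample pair is classified as `same_mouse` (same
#' individual, different timepoints), `same_date` (different individuals,
#' same trapping session), `same_month_diff_mouse` (different
#' individuals, same calendar month and year, different sessions) or
#' `other`, and annotated with its dissimilarity, interval in days, and
#' the calendar month of the earlier sample. Duplicate
#' (individual, session) samples are flagged and only the first is kept.
#'
#' @param d `dist`/matrix of dissimilarities among the samples.
#' @param meta per-sample metadata (data.frame with `sample_id`,
#'   `individual_id`, `session_id`, `date`) covering every sample in `d`.
#' @return data.frame: `sample_a`, `sample_b`, `pair_type`, `d`,
#'   `interval_days`, `month` (earlier sample, "YYYY-MM"),
#'   `month_of_year` (1-12), `individual_a`, `individual_b`.
#' @export
enumeratePairs <- function(d, meta) {
  D <- asDistanceMatrix(d)
  ids <- rownames(D)
  if (is.null(ids)) stop("distance matrix must carry sample labels")
  miss <- setdiff(ids, meta$sample_id)
  if (length(miss)) stop("metadata missing for: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), ]
  dup <- duplicated(paste(meta$individual_id, meta$session_id))
  if (any(dup)) {
    warning(sum(dup), " duplicate (individual, session) sample(s); ",
            "keeping the first of each")
    keep <- !dup
    D <- D[keep, keep]; meta <- meta[keep, ]; ids <- ids[keep]
  }
  n <- length(ids)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  dates <- as.Date(meta$date)
  sameInd <- meta$individual_id[i] == meta$individual_id[j]
  sameSes <- meta$session_id[i] == meta$session_id[j]
  ym <- format(dates, "%Y-%m")
  sameMonth <- ym[i] == ym[j]
  type <- rep("other", length(i))
  type[sameInd & !sameSes] <- "same_mouse"
  type[!sameInd & sameSes] <- "same_date"
  type[!sameInd & !sameSes & sameMonth] <- "same_month_diff_mouse"
  earlier <- ifelse(dates[i] <= dates[j], i, j)
  data.frame(
    sample_a = ids[i], sample_b = ids[j], pair_type = type,
    d = D[cbind(i, j)],
    interval_days = abs(as.numeric(dates[i] - dates[j])),
    month = ym[earlier],
    month_of_year = as.integer(format(dates[earlier], "%m")),
    individual_a = meta$individual_id[i],
    individual_b = meta$individual_id[j],
    stringsAsFactors = FALSE
  )
}

#' Permutational rank-sum (Mann-Whitney) test
#'
#' The observed statistic is the Mann-Whitney U of group A: the rank-sum
#' of A over pooled mid-ranks minus its minimum n_a(n_a+1)/2. The null
#' distribution is built by randomly reassigning the group labels over
#' the pooled values `n_perm` times; the p-value is
#' (1 + #{null as or more extreme}) / (n_perm + 1), so it can never be 0.
#' When the number of distinct label assignments, choose(n, n_a), does
#' not exceed `n_perm`, all assignments are enumerated instead and the
#' p-value is exact (the observed assignment belongs to the null set).
#'
#' @param values_a,values_b numeric vectors (e.g. dissimilarities of two
#'   pair types).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param sides `"less"` (A stochastically smaller), `"greater"`, or
#'   `"two_sided"` (distance of U from its null expectation n_a n_b / 2).
#' @return list of class `wg_permtest`: `U`, `n_a`, `n_b`, `n_perm`,
#'   `p_value`, `sides`, `direction` (sign of U - E[U]), `seed`.
#' @export
rankPermutationTest <- function(values_a, values_b, n_perm = 1000,
                                seed = 1,
                                sides = c("less", "greater", "two_sided")) {
  sides <- match.arg(sides)
  if (!length(values_a) || !length(values_b))
    stop("both groups must be nonempty")
  if (n_perm < 1) stop("n_perm must be >= 1")
  pooled <- c(values_a, values_b)
  n_a <- length(values_a); n <- length(pooled)
  r <- rank(pooled)              # mid-ranks; invariant under relabelling
  minU <- n_a * (n_a + 1) / 2
  obsU <- sum(r[seq_len(n_a)]) - minU
  expU <- n_a * (n - n_a) / 2
  exact <- choose(n, n_a) <= n_perm
  if (exact) {
    nullU <- apply(utils::combn(n, n_a), 2L,
                   function(ix) sum(r[ix])) - minU
    denom <- length(nullU)               # includes the observed assignment
    count <- function(hits) sum(hits)
  } else {
    nullU <- .withSubSeed(seed, "rank_perm", {
      vapply(seq_len(n_perm),
             function(p) sum(r[sample.int(n, n_a)]) - minU, 0)
    })
    denom <- n_perm + 1
    count <- function(hits) 1 + sum(hits)
  }
  p <- switch(sides,
    less = count(nullU <= obsU) / denom,
    greater = count(nullU >= obsU) / denom,
    two_sided = count(abs(nullU - expU) >= abs(obsU - expU)) / denom)
  structure(list(U = obsU, n_a = n_a, n_b = n - n_a, n_perm = n_perm,
                 p_value = p, sides = sides, exact = exact,
                 direction = sign(obsU - expU), seed = seed),
            class = "wg_permtest")
}

#' @export
print.wg_permtest <- function(x, ...) {
  cat("Permutational rank-sum test (", x$sides, ")\n", sep = "")
  cat("  U = ", format(x$U), ", n = ", x$n_a, " vs ", x$n_b,
      ", permutations = ", x$n_perm, "\n", sep = "")
  cat("  p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Test for host individuality of the microbiota
#'
#' Compares dissimilarities of samples from the same individual at
#' different timepoints ("same mouse") against dissimilarities of samples
#' from different individuals in the same trapping session ("same
#' date"), one-sided in the direction same_mouse < same_date. A
#' significant result means hosts are more similar to themselves over
#' time than to contemporaneous conspecifics. The permutation unit is the
#' pair label; pairs sharing a sample are not independent, which this
#' pooled-pair scheme ignores (see the package vignette).
#'
#' @param pairs pair table from [enumeratePairs()].
#' @param n_perm,seed passed to [rankPermutationTest()].
#' @return A `wg_permtest` with extra elements `mean_same_mouse`,
#'   `mean_same_date`.
#' @export
individualityTest <- function(pairs, n_perm = 1000, seed = 1) {
  a <- pairs$d[pairs$pair_type == "same_mouse"]
  b <- pairs$d[pairs$pair_type == "same_date"]
  if (!length(a)) stop("no same_mouse pairs")
  if (!length(b)) stop("no same_date pairs")
  out <- rankPermutationTest(a, b, n_perm = n_perm, seed = seed,
                             sides = "less")
  out$mean_same_mouse <- mean(a)
  out$mean_same_date <- mean(b)
  out
}

#' Time-decay of within-individual community similarity
#'
#' Ordinary least squares of log community similarity, log(1 - d), on
#' the interval in days between same-individual samples, restricted to
#' individuals with at least `min_captures` samples. A negative slope
#' means the individuality signal decays with time. Pairs with
#' similarity <= 0 (completely disjoint communities) are dropped with a
#' count, since their log is undefined.
#'
#' @param pairs pair table from [enumeratePairs()].
#' @param min_captures minimum samples per individual.
#' @param meta optional metadata to recount captures; if omitted,
#'   captures are counted from the pair table's sample ids.
#' @return list of class `wg_timedecay`: `slope` (per day), `intercept`,
#'   `F`, `df1`, `df2`, `p_value`, `adj_r_squared`, `n_pairs`,
#'   `n_dropped_zero_similarity`, `slope_se`, `fit` (the `lm`).
#' @export
timeDecay <- function(pairs, min_captures = 3, meta = NULL) {
  sm <- pairs[pairs$pair_type == "same_mouse", ]
  if (!is.null(meta)) {
    caps <- table(meta$individual_id)
  } else {
    samp <- rbind(data.frame(s = sm$sample_a, i = sm$individual_a),
                  data.frame(s = sm$sample_b, i = sm$individual_b))
    samp <- unique(samp)
    caps <- table(samp$i)
  }
  eligible <- names(caps)[caps >= min_captures]
  sm <- sm[sm$individual_a %in% eligible, ]
  sim <- 1 - sm$d
  drop <- sim <= 0
  ndrop <- sum(drop)
  sm <- sm[!drop, ]; sim <- sim[!drop]
  if (nrow(sm) < 3L || length(unique(sm$interval_days)) < 2L)
    stop("time-decay needs >= 3 same-individual pairs with distinct intervals")
  fit <- stats::lm(log(sim) ~ interval_days, data = sm)
  s <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    F = unname(s$fstatistic[1L]),
    df1 = unname(s$fstatistic[2L]), df2 = unname(s$fstatistic[3L]),
    p_value = stats::pf(s$fstatistic[1L], s$fstatistic[2L],
                        s$fstatistic[3L], lower.tail = FALSE),
    adj_r_squared = s$adj.r.squared,
    n_pairs = nrow(sm), n_dropped_zero_similarity = ndrop,
    slope_se = s$coefficients[2L, 2L], fit = fit),
    class = "wg_timedecay")
}

#' @export
print.wg_timedecay <- function(x, ...) {
  cat("Time-decay of log community similarity\n")
  cat("  slope = ", format(x$slope, digits = 4), " per day (s.e. ",
      format(x$slope_se, digits = 3), ")\n", sep = "")
  cat("  F(", x$df1, ",", x$df2, ") = ", format(x$F, digits = 4),
      ", p = ", format.pval(x$p_value),
      ", adj. R^2 = ", format(x$adj_r_squared, digits = 3),
      ", n = ", x$n_pairs, " pairs\n", sep = "")
  invisible(x)
}

#' Rate of community change by time lag
#'
#' Each same-individual pair contributes d / interval to the lag bin its
#' interval falls in; bin means and standard errors are reported. Under a
#' stationary individual process the rate declines with lag because
#' dissimilarity saturates while the interval keeps growing.
#'
#' @param pairs pair table from [enumeratePairs()].
#' @param lag_bins numeric vector of bin edges in days (left-closed).
#' @return data.frame: `bin`, `lag_min`, `lag_max`, `n`, `mean_rate`,
#'   `se_rate` (`NA` and flagged when n < 2), `flag`.
#' @export
rateOfChange <- function(pairs, lag_bins = c(0, 14, 28, 56, 112, 365)) {
  sm <- pairs[pairs$pair_type == "same_mouse" & pairs$interval_days > 0, ]
  rate <- sm$d / sm$interval_days
  bin <- cut(sm$interval_days, breaks = lag_bins, right = FALSE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    v <- rate[!is.na(bin) & bin == b]
    data.frame(bin = b, n = length(v),
               mean_rate = if (length(v)) mean(v) else NA_real_,
               se_rate = if (length(v) > 1L)
                 stats::sd(v) / sqrt(length(v)) else NA_real_,
               flag = if (!length(v)) "empty"
                      else if (length(v) == 1L) "single_pair" else "")
  }))
  edges <- cbind(lag_bins[-length(lag_bins)], lag_bins[-1])
  out$lag_min <- edges[, 1]; out$lag_max <- edges[, 2]
  out[c("bin", "lag_min", "lag_max", "n", "mean_rate", "se_rate", "flag")]
}

#' Monthly inter-individual convergence
#'
#' For each calendar month (pooled across years): (i) the mean
#' dissimilarity among same-session pairs of different individuals in
#' that month, and (ii) a one-sided permutational rank test asking
#' whether those inter-individual dissimilarities are *smaller* than the
#' same-individual (cross-study) dissimilarities of the mice involved —
#' i.e. whether seasonal convergence overrides individuality that month.
#' The study-wide mean same-individual dissimilarity is returned as a
#' reference.
#'
#' @param pairs pair table from [enumeratePairs()].
#' @param n_perm,seed passed to [rankPermutationTest()].
#' @return list: `summary` (data.frame month_of_year, n_pairs,
#'   mean_inter, U, p_value), `reference_mean_same_mouse`, `tests`
#'   (per-month `wg_permtest`s). Months with no qualifying pairs are
#'   skipped with a message.
#' @export
monthlyConvergence <- function(pairs, n_perm = 1000, seed = 1) {
  sm <- pairs[pairs$pair_type == "same_mouse", ]
  sd_ <- pairs[pairs$pair_type == "same_date", ]
  if (!nrow(sm)) stop("no same_mouse pairs")
  rows <- list(); tests <- list()
  for (m in sort(unique(sd_$month_of_year))) {
    inter <- sd_[sd_$month_of_year == m, ]
    if (nrow(inter) < 1L) next
    mice <- unique(c(inter$individual_a, inter$individual_b))
    intra <- sm$d[sm$individual_a %in% mice]
    if (!length(intra)) {
      message("month ", m, ": no same-individual pairs for its mice; skipped")
      next
    }
    tst <- rankPermutationTest(inter$d, intra, n_perm = n_perm,
                               seed = .subSeed(seed, paste0("month", m)),
                               sides = "less")
    rows[[length(rows) + 1L]] <- data.frame(
      month_of_year = m, n_pairs = nrow(inter),
      mean_inter = mean(inter$d), U = tst$U, p_value = tst$p_value)
    tests[[as.character(m)]] <- tst
  }
  list(summary = do.call(rbind, rows),
       reference_mean_same_mouse = mean(sm$d), tests = tests)
}
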