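## Small fixtures built in code.

## A counts-mode AsvExperiment from a samples x ASVs matrix.
toyExperiment <- function(m, meta = NULL, tax = NULL, mode = "counts") {
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("A", seq_len(ncol(m)))
  if (is.null(meta))
    meta <- data.frame(sample_id = rownames(m),
                       individual_id = rownames(m))
  AsvExperiment(m, sampleData = meta, taxonomy = tax, mode = mode)
}

## Random counts table with given dims.
randomCounts <- function(n_samples, n_asvs, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda), nrow = n_samples)
  rownames(m) <- paste0("S", seq_len(n_samples))
  colnames(m) <- paste0("A", seq_len(n_asvs))
  m
}

## Naive double-loop Bray-Curtis / Jaccard oracles.
oracleBray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- den <- 0
    for (k in seq_len(ncol(m))) {
      num <- num + abs(m[i, k] - m[j, k])
      den <- den + m[i, k] + m[j, k]
    }
    d[i, j] <- if (den > 0) num / den else 0
  }
  d
}
oracleJaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- m[i, ] > 0; b <- m[j, ] > 0
    u <- sum(a | b)
    d[i, j] <- if (u > 0) 1 - sum(a & b) / u else 0
  }
  d
}

## Exhaustive permutation oracle for the rank-sum test.
oracleRankPerm <- function(a, b, sides = "less") {
  pooled <- c(a, b); n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  minU <- na * (na + 1) / 2
  expU <- na * (n - na) / 2
  obs <- sum(r[seq_len(na)]) - minU
  combos <- utils::combn(n, na)
  Us <- apply(combos, 2L, function(ix) sum(r[ix]) - minU)
  switch(sides,
    less = mean(Us <= obs),
    greater = mean(Us >= obs),
    two_sided = mean(abs(Us - expU) >= abs(obs - expU)))
}

## Small longitudinal simulation for analysis tests.
quickSim <- function(seed = 1, sigma_individual = 1, seasonal_amplitude = 1,
                     n_ind = 10, n_asv = 40, days = 200, capture = 0.6,
                     n_pop = 1, ...) {
  simulateDataset(simulationConfig(
    n_populations = n_pop, asvs_per_population = n_asv, n_families = 6,
    n_individuals_per_population = n_ind, study_length_days = days,
    capture_probability = capture, sigma_individual = sigma_individual,
    seasonal_amplitude = seasonal_amplitude,
    depth_log_mean = log(4000), depth_log_sd = 0.3,
    n_contaminant_asvs = 0, seed = seed, ...))
}
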