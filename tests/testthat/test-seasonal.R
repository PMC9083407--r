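test_that("harmonic fit recovers a pure cosine exactly", {
  doy <- seq(1, 365, by = 5)
  y <- cos(2 * pi * (doy - 280) / 365)
  f <- harmonicSeasonalFit(y, data.frame(day_of_year = doy), K = 1)
  expect_equal(f$peak_day, 280, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-8)
  expect_equal(f$seasonal_r_squared, 1, tolerance = 1e-8)
  ## constant response: amplitude 0
  f0 <- harmonicSeasonalFit(rep(2, length(doy)),
                            data.frame(day_of_year = doy), K = 1)
  expect_equal(f0$amplitude, 0, tolerance = 1e-8)
  expect_error(harmonicSeasonalFit(y, data.frame(day_of_year = doy), K = -1),
               "K")
})

test_that("harmonic fit is equivariant to day-of-year rotation", {
  set.seed(4)
  doy <- sample(1:365, 120, replace = TRUE)
  y <- 0.7 * cos(2 * pi * (doy - 100) / 365) + rnorm(120, 0, 0.2)
  f1 <- harmonicSeasonalFit(y, data.frame(day_of_year = doy), K = 1)
  shift <- 90
  doy2 <- ((doy + shift - 1) %% 365) + 1
  f2 <- harmonicSeasonalFit(y, data.frame(day_of_year = doy2), K = 1)
  delta <- (f2$peak_day - f1$peak_day) %% 365
  expect_equal(delta, shift, tolerance = 0.1)
})

test_that("within-individual centring absorbs individual offsets", {
  set.seed(9)
  ind <- rep(paste0("M", 1:10), each = 12)
  doy <- rep(seq(15, 345, by = 30), 10)
  off <- rep(rnorm(10, 0, 5), each = 12)
  y <- off + cos(2 * pi * (doy - 50) / 365) + rnorm(120, 0, 0.1)
  meta <- data.frame(day_of_year = doy, individual_id = ind)
  fc <- harmonicSeasonalFit(y, meta, K = 1,
                            random_intercept_individual = TRUE)
  expect_equal(fc$peak_day, 50, tolerance = 5)
  expect_gt(fc$seasonal_r_squared, 0.9)
  ## without centring the offsets dominate the total SS
  f <- harmonicSeasonalFit(y, meta, K = 1)
  expect_lt(f$seasonal_r_squared, fc$seasonal_r_squared)
})

test_that("paired seasonal contrast detects a consistent shift", {
  ind <- paste0("M", 1:12)
  meta <- data.frame(
    individual_id = rep(ind, 2),
    date = as.Date(rep(c("2015-07-10", "2015-10-10"), each = 12)))
  base <- rnorm(12)
  ## identical values: t = 0, p = 1
  r0 <- pairedSeasonContrast(c(base, base), meta, 6:8, 9:11)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  ## constant shift with tiny noise: strongly significant
  set.seed(2)
  r1 <- pairedSeasonContrast(c(base, base + 1 + rnorm(12, 0, 0.01)),
                             meta, 6:8, 9:11)
  expect_lt(r1$p_value, 0.001)
  expect_gt(r1$t, 0)
  expect_equal(r1$n, 12)
  expect_error(pairedSeasonContrast(base, meta[1:12, ], 6:8, 9:11), ">= 2")
})

test_that("paired contrast sign matches the forced seasonal direction", {
  sim <- quickSim(seed = 61, sigma_individual = 0.3, seasonal_amplitude = 2,
                  seasonal_peak_day = 200, seasonal_fraction = 0.3,
                  n_ind = 20, days = 365, capture = 0.8)
  rel <- toRelative(sim$experiment)
  ## response: total share of the seasonal ASVs, peaking around day 200
  y <- colSums(abundances(rel)[sim$truth$seasonal_asv_ids, ])
  meta <- sampleData(rel)
  r <- pairedSeasonContrast(y, meta, 6:8, 10:12)
  expect_lt(r$t, 0)  # shares fall from mid-summer peak into winter
})

## brute-force PERMANOVA oracle: explicit projections, naive loops
oraclePermanovaF <- function(D, X) {
  n <- nrow(D)
  G <- matrix(0, n, n)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ssm <- sum(diag(H %*% G %*% H))
  sst <- sum(diag(G))
  dfm <- qr(X)$rank - 1
  dfr <- n - qr(X)$rank
  ((ssm) / dfm) / ((sst - ssm) / dfr)
}

test_that("pseudo-F matches a brute-force projection oracle", {
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(rpois(10 * 8, 6) + 0.0, nrow = 10)
    rel <- sweep(m, 1, rowSums(m), "/")
    rownames(rel) <- paste0("S", 1:10)
    D <- asDistanceMatrix(brayCurtis(toyExperiment(rel, mode = "relative")))
    g <- factor(rep(c("a", "b"), 5))
    X <- model.matrix(~ g)
    res <- permanova(D, ~ g, data.frame(g = g, sample_id = rownames(D)),
                     n_perm = 19, seed = rep)
    expect_equal(res$pseudo_F[1], oraclePermanovaF(D, X), tolerance = 1e-10)
  }
})

test_that("permanova agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rpois(12 * 10, 6) + 0.0, nrow = 12)
  rel <- sweep(m, 1, rowSums(m), "/")
  rownames(rel) <- paste0("S", 1:12)
  D <- brayCurtis(toyExperiment(rel, mode = "relative"))
  df <- data.frame(g = factor(rep(c("a", "b", "c"), 4)),
                   z = rnorm(12), sample_id = rownames(as.matrix(D)))
  res <- permanova(D, ~ g + z, df, n_perm = 99, mode = "marginal", seed = 1)
  ref <- vegan::adonis2(D ~ g + z, data = df, permutations = 99,
                        by = "margin")
  expect_equal(res$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(res$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
  resS <- permanova(D, ~ g + z, df, n_perm = 99, mode = "sequential", seed = 1)
  refS <- vegan::adonis2(D ~ g + z, data = df, permutations = 99,
                         by = "terms")
  expect_equal(resS$SS[1:2], refS$SumOfSqs[1:2], tolerance = 1e-8)
})

test_that("degenerate two-group geometry gives divergent F at the p floor", {
  ## within-group d = 0, between-group d = 1
  D <- matrix(1, 6, 6); D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("S", 1:6)
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(D, ~ g, data.frame(g = g, sample_id = rownames(D)),
                   n_perm = 99, seed = 1)
  expect_equal(res$SS[res$term == "Total"], 1.5)  # Anderson identity: sum d^2 / n
  expect_true(is.infinite(res$pseudo_F[1]))
  ## only block-preserving permutations (prob 2*3!*3!/6! = 0.1) reproduce
  ## the infinite F, so p sits near 0.1 with its floor at 1/(n_perm+1)
  expect_gte(res$p_value[1], 1 / 100)
  expect_lt(res$p_value[1], 0.3)
})

test_that("single-term marginal equals sequential; R2 sums to 1 in sequential mode", {
  set.seed(31)
  m <- matrix(rpois(10 * 6, 5) + 0.0, nrow = 10)
  rel <- sweep(m, 1, rowSums(m), "/")
  rownames(rel) <- paste0("S", 1:10)
  D <- brayCurtis(toyExperiment(rel, mode = "relative"))
  df <- data.frame(g = factor(rep(c("a", "b"), 5)),
                   sample_id = rownames(as.matrix(D)))
  rm_ <- permanova(D, ~ g, df, n_perm = 49, mode = "marginal", seed = 2)
  rs <- permanova(D, ~ g, df, n_perm = 49, mode = "sequential", seed = 2)
  expect_equal(rm_$SS, rs$SS, tolerance = 1e-12)
  expect_equal(sum(rs$partial_r2[rs$term != "Total"]), 1, tolerance = 1e-10)
})

test_that("rank-deficient designs error naming the aliased term", {
  D <- matrix(runif(36, 0.2, 0.8), 6); D <- (D + t(D)) / 2; diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("S", 1:6)
  df <- data.frame(a = rep(c("x", "y"), 3))
  df$b <- df$a   # perfectly aliased
  expect_error(permanova(D, ~ a + b, df, n_perm = 9), "aliased")
})

test_that("dispersion test separates tight from diffuse groups, not identical ones", {
  set.seed(41)
  tight <- matrix(rnorm(20 * 3, sd = 0.1), 20)
  diffuse <- matrix(rnorm(20 * 3, sd = 1.5), 20)
  X <- rbind(tight, diffuse)
  D <- as.matrix(dist(X)); rownames(D) <- colnames(D) <- paste0("S", 1:40)
  g <- rep(c("t", "d"), each = 20)
  r <- dispersionTest(D, g, n_perm = 199, seed = 1)
  expect_lt(r$p_value, 0.05)
  expect_lt(r$group_means[["t"]], r$group_means[["d"]])

  ## identical internal geometry: no dispersion difference
  same <- matrix(rnorm(12 * 3), 12)
  D2 <- as.matrix(dist(rbind(same, same + 10)))
  rownames(D2) <- colnames(D2) <- paste0("S", 1:24)
  r2 <- dispersionTest(D2, rep(c("a", "b"), each = 12), n_perm = 199, seed = 2)
  expect_gt(r2$p_value, 0.2)
  expect_error(dispersionTest(D2, rep("a", 24)), ">= 2 groups")
})

test_that("one sample per individual subsets reproducibly", {
  sim <- quickSim(seed = 71, n_ind = 8, days = 150)
  s1 <- oneSamplePerIndividual(sim$experiment, seed = 3)
  s2 <- oneSamplePerIndividual(sim$experiment, seed = 3)
  expect_identical(sampleIds(s1), sampleIds(s2))
  expect_equal(ncol(s1), length(unique(sampleData(sim$experiment)$individual_id)))
  ## distance-matrix input
  rel <- toRelative(sim$experiment)
  D <- asDistanceMatrix(brayCurtis(rel))
  d1 <- oneSamplePerIndividual(D, sampleData(rel), seed = 3)
  expect_identical(rownames(d1), sampleIds(s1))
  ## singly sampled individuals: identity
  keep <- !duplicated(sampleData(rel)$individual_id)
  ae1 <- sim$experiment[, keep]
  expect_equal(ncol(oneSamplePerIndividual(ae1, seed = 1)), sum(keep))
})

test_that("axis association ranks planted seasonal drivers highly", {
  sim <- quickSim(seed = 81, sigma_individual = 0.2, seasonal_amplitude = 2,
                  seasonal_fraction = 0.15, n_ind = 15, days = 365,
                  capture = 0.8)
  rel <- toRelative(sim$experiment)
  o <- pcoa(brayCurtis(rel))
  aa <- axisAssociation(rel, scores(o)[, 1])
  top10 <- aa$asv_id[1:10]
  expect_gt(length(intersect(top10, sim$truth$seasonal_asv_ids)), 2)
})
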