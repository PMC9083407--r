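pairMeta <- function() {
  data.frame(
    sample_id = paste0("S", 1:6),
    individual_id = c("M1", "M1", "M2", "M3", "M2", "M3"),
    session_id = c("s1", "s2", "s1", "s1", "s3", "s3"),
    date = as.Date(c("2015-01-05", "2015-02-04", "2015-01-05",
                     "2015-01-05", "2015-03-10", "2015-03-10")))
}

pairDist <- function(n = 6) {
  set.seed(2)
  D <- matrix(runif(n * n, 0.2, 0.9), n)
  D <- (D + t(D)) / 2; diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("S", seq_len(n))
  D
}

test_that("pairs are typed correctly and counts conserve", {
  p <- enumeratePairs(pairDist(), pairMeta())
  expect_equal(nrow(p), choose(6, 2))
  expect_equal(sum(p$pair_type == "same_mouse"), 3L)  # M1, M2, M3 resampled
  ## session s1 has 3 mice: C(3,2) same_date pairs; s3 adds 1 more
  expect_equal(sum(p$pair_type == "same_date"), 4L)
  sm <- p[p$pair_type == "same_mouse", ]
  expect_true(all(sm$interval_days > 0))
  expect_true(all(sm$individual_a == sm$individual_b))
  sd_ <- p[p$pair_type == "same_date", ]
  expect_true(all(sd_$interval_days == 0))
  ## month label is the earlier sample's calendar month
  expect_true(all(p$month[p$sample_a == "S1" & p$sample_b == "S2"] == "2015-01"))
})

test_that("duplicate (individual, session) samples are flagged and deduplicated", {
  meta <- pairMeta()
  meta$session_id[2] <- "s1"   # M1 now sampled twice in s1
  expect_warning(p <- enumeratePairs(pairDist(), meta), "duplicate")
  expect_equal(nrow(p), choose(5, 2))
})

test_that("permutation p matches the exhaustive oracle for tiny groups", {
  set.seed(10)
  for (rep in 1:5) {
    a <- runif(3); b <- runif(3) + 0.3
    for (sides in c("less", "greater", "two_sided")) {
      exact <- oracleRankPerm(a, b, sides)
      got <- rankPermutationTest(a, b, n_perm = 5000, seed = rep,
                                 sides = sides)
      expect_true(got$exact)
      expect_lt(abs(got$p_value - exact), 1 / 5001)
    }
  }
  ## sampled mode still approximates the oracle
  a <- runif(6); b <- runif(6) + 0.2      # choose(12,6) = 924 <= 5000: exact
  got <- rankPermutationTest(a, b, n_perm = 200, seed = 3, sides = "less")
  expect_false(got$exact)
  expect_lt(abs(got$p_value - oracleRankPerm(a, b, "less")), 0.12)
})

test_that("identical groups give large two-sided p and p is never below its floor", {
  v <- rep(c(1, 2, 3), 4)
  got <- rankPermutationTest(v, v, n_perm = 300, seed = 1, sides = "two_sided")
  expect_gte(got$p_value, 1 / 301)
  expect_gt(got$p_value, 0.5)
  expect_error(rankPermutationTest(numeric(), v), "nonempty")
  expect_error(rankPermutationTest(v, v, n_perm = 0), "n_perm")
})

test_that("the test has power when one group is shifted down", {
  set.seed(42)
  rejected <- vapply(1:20, function(r) {
    b <- rnorm(50)
    a <- rnorm(50) - 1.2
    rankPermutationTest(a, b, n_perm = 300, seed = r, sides = "less")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rejected), 0.95)
})

test_that("individuality test detects planted signatures and needs both pair types", {
  sim <- quickSim(seed = 31, sigma_individual = 1, seasonal_amplitude = 0,
                  n_ind = 15, days = 150)
  rel <- toRelative(sim$experiment)
  p <- enumeratePairs(brayCurtis(rel), sampleData(rel))
  tst <- individualityTest(p, n_perm = 300, seed = 1)
  expect_lt(tst$p_value, 0.01)
  expect_lt(tst$mean_same_mouse, tst$mean_same_date)
  ## single mouse: no same_date pairs
  one <- p[p$individual_a == "M_P1_01" & p$individual_b == "M_P1_01", ]
  expect_error(individualityTest(one), "same_date")
})

test_that("time-decay recovers a planted log-linear slope and rejects degenerate input", {
  set.seed(8)
  n <- 300
  dt <- sample(5:300, n, replace = TRUE)
  logsim <- -0.3 - 0.002 * dt + rnorm(n, 0, 0.1)
  pairs <- data.frame(
    sample_a = paste0("X", 1:n), sample_b = paste0("Y", 1:n),
    pair_type = "same_mouse", d = 1 - exp(logsim),
    interval_days = dt, month = "2015-01", month_of_year = 1,
    individual_a = rep(paste0("M", 1:30), 10),
    individual_b = rep(paste0("M", 1:30), 10))
  td <- timeDecay(pairs, min_captures = 0)
  expect_lt(abs(td$slope - (-0.002)), 2 * td$slope_se)
  expect_gt(td$F, 10)
  ## constant d: slope ~ 0
  pairs0 <- pairs; pairs0$d <- 0.5
  td0 <- suppressWarnings(timeDecay(pairs0, min_captures = 0))
  expect_equal(td0$slope, 0, tolerance = 1e-12)
  ## two pairs only: insufficient
  expect_error(timeDecay(pairs[1:2, ], min_captures = 0), ">= 3")
  ## zero-similarity pairs are dropped with a count
  pairs1 <- pairs; pairs1$d[1:5] <- 1
  td1 <- timeDecay(pairs1, min_captures = 0)
  expect_equal(td1$n_dropped_zero_similarity, 5L)
})

test_that("rate of change bins pairs and flags degenerate bins", {
  pairs <- data.frame(
    sample_a = "a", sample_b = "b", pair_type = "same_mouse",
    d = c(0.3, 0.4, 0.6), interval_days = c(30, 35, 100),
    month = "2015-01", month_of_year = 1,
    individual_a = "M1", individual_b = "M1")
  rc <- rateOfChange(pairs, lag_bins = c(0, 50, 150, 300))
  expect_equal(rc$mean_rate[1], mean(c(0.3 / 30, 0.4 / 35)))
  expect_equal(rc$mean_rate[2], 0.006)
  expect_equal(rc$flag[2], "single_pair")
  expect_equal(rc$flag[3], "empty")
})

test_that("rate of change declines with lag for a stationary individual process", {
  sim <- quickSim(seed = 77, sigma_individual = 1, seasonal_amplitude = 0,
                  n_ind = 20, days = 300)
  rel <- toRelative(sim$experiment)
  p <- enumeratePairs(brayCurtis(rel), sampleData(rel))
  rc <- rateOfChange(p, lag_bins = c(0, 40, 120, 365))
  rates <- rc$mean_rate[!is.na(rc$mean_rate)]
  expect_true(all(diff(rates) < 0))
})

test_that("monthly convergence finds the forced winter window", {
  sim <- quickSim(seed = 51, sigma_individual = 0.6, seasonal_amplitude = 2,
                  seasonal_peak_day = 200, seasonal_fraction = 0.3,
                  n_ind = 20, days = 365, capture = 0.7)
  rel <- toRelative(sim$experiment)
  p <- enumeratePairs(brayCurtis(rel), sampleData(rel))
  cv <- monthlyConvergence(p, n_perm = 200, seed = 1)
  s <- cv$summary
  best <- s$month_of_year[which.min(s$mean_inter)]
  ## forcing peaks mid-summer (day 200); hosts converge around the
  ## winter trough (~day 17), when communities contract onto the shared
  ## non-seasonal pool
  expect_true(best %in% c(12, 1, 2, 3))
  expect_true(is.finite(cv$reference_mean_same_mouse))
})

test_that("single-month data still yields one summary row", {
  meta <- pairMeta()[c(1, 3, 4), ]       # one session only
  D <- pairDist(6)[c(1, 3, 4), c(1, 3, 4)]
  ## give each mouse a second sample so same_mouse pairs exist
  meta2 <- rbind(meta, within(meta, {
    sample_id <- paste0(sample_id, "b"); session_id <- "s9"
    date <- date + 20
  }))
  set.seed(1)
  D2 <- matrix(runif(36, 0.3, 0.8), 6); D2 <- (D2 + t(D2)) / 2; diag(D2) <- 0
  rownames(D2) <- colnames(D2) <- meta2$sample_id
  p <- enumeratePairs(D2, meta2)
  cv <- monthlyConvergence(p, n_perm = 100, seed = 2)
  expect_gte(nrow(cv$summary), 1L)
})
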