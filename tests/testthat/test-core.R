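## Deterministic 6-mouse, 12-sample toy table with hand-planted abundances.
coreToy <- function() {
  mice <- rep(paste0("M", 1:6), each = 2)
  samples <- paste0("S", 1:12)
  m <- matrix(0, 12, 4, dimnames = list(samples,
              c("everywhere", "half", "rare", "onemouse")))
  m[, "everywhere"] <- 50
  m[seq(1, 12, by = 2), "half"] <- 10     # first sample of each mouse only
  m[1, "rare"] <- 1
  m[c(1, 2), "onemouse"] <- 5             # both samples of M1
  m[, 1] <- m[, 1] + seq_len(12)          # vary depths a little
  meta <- data.frame(sample_id = samples, individual_id = mice)
  toyExperiment(m, meta = meta)
}

test_that("subsampled prevalence matches hand computation in degenerate cases", {
  ae <- coreToy()
  P <- subsampledPrevalence(ae, n_iter = 50, seed = 2)
  expect_equal(unname(P["everywhere"]), 1)          # present in every sample
  expect_equal(unname(P["onemouse"]), 1 / 6)        # always M1's pick, never others'
  ## "half" is in exactly one of each mouse's two samples: P -> 0.5
  P2 <- subsampledPrevalence(ae, n_iter = 1000, seed = 3)
  ci <- qbinom(c(0.005, 0.995), 1000 * 6, 0.5) / (1000 * 6)
  expect_gte(unname(P2["half"]), ci[1])
  expect_lte(unname(P2["half"]), ci[2])
  ## determinism
  expect_identical(subsampledPrevalence(ae, n_iter = 1, seed = 9),
                   subsampledPrevalence(ae, n_iter = 1, seed = 9))
})

test_that("subsampled prevalence equals plain prevalence when each individual has one sample", {
  m <- randomCounts(8, 10, seed = 3, lambda = 1)
  ae <- toyExperiment(m)  # individual_id defaults to sample_id: singly sampled
  P <- subsampledPrevalence(ae, n_iter = 7, seed = 1)
  expect_equal(unname(P), unname(rowMeans(abundances(ae) > 0)))
})

test_that("persistence is the mean within-individual detection fraction", {
  ae <- coreToy()
  psi <- persistence(ae, min_captures = 2)
  expect_equal(attr(psi, "n_individuals"), 6L)
  expect_equal(unname(psi["everywhere"]), 1)
  expect_equal(unname(psi["half"]), 0.5)
  expect_equal(unname(psi["onemouse"]), 1 / 6)      # 1.0 for M1, 0 for the rest
  expect_equal(unname(psi["rare"]), 0.5 / 6)
  ## two eligible mice with fractions 1.0 and 0.25 average to 0.625
  m <- matrix(0, 6, 1, dimnames = list(paste0("S", 1:6), "a"))
  m[1:2, 1] <- 1; m[3, 1] <- 1
  meta <- data.frame(sample_id = rownames(m),
                     individual_id = c("M1", "M1", "M2", "M2", "M2", "M2"))
  m <- cbind(m, filler = 1)
  psi2 <- persistence(toyExperiment(m, meta = meta), min_captures = 2)
  expect_equal(unname(psi2["a"]), (1 + 0.25) / 2)
  ## no eligible individual -> error naming the threshold
  expect_error(persistence(coreToy(), min_captures = 5), "5")
})

test_that("Spearman correlation handles ties and perfect monotonicity", {
  P <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(prevalencePersistenceCorrelation(P, P)$rho, 1)
  expect_equal(prevalencePersistenceCorrelation(P, 1 - P)$rho, -1)
  ## tied example verified against the rank formula
  p <- c(1, 2, 2, 4); q <- c(1, 3, 2, 4)
  got <- prevalencePersistenceCorrelation(p, q)
  expect_equal(got$rho, cor(rank(p), rank(q)))
  expect_equal(got$rho,
               suppressWarnings(cor.test(p, q, method = "spearman")$estimate),
               ignore_attr = TRUE)
  expect_warning(prevalencePersistenceCorrelation(rep(1, 4), q), "constant")
})

test_that("core set applies the joint 60%/0.1% criterion inclusively", {
  n <- 10
  m <- matrix(0, n, 4, dimnames = list(paste0("S", 1:n),
              c("core_all", "too_rare", "edge", "fill")))
  m[, "core_all"] <- 0.002
  m[, "too_rare"] <- 0.0005
  m[1:6, "edge"] <- 0.001                  # exactly 0.1% in exactly 60%
  m[, "fill"] <- 1 - rowSums(m)
  rel <- toyExperiment(m, mode = "relative")
  core <- coreSet(rel)
  expect_setequal(core, c("core_all", "edge", "fill"))
  expect_error(coreSet(rel, prevalence_threshold = 1.2), "\\[0, 1\\]")
  ## zero thresholds: every ASV present anywhere
  expect_setequal(coreSet(rel, 0, 0), colnames(m))
})

test_that("raising either threshold never enlarges the core set", {
  set.seed(6)
  m <- matrix(rexp(200), 20, 10)
  m <- sweep(m, 1, rowSums(m), "/")
  rownames(m) <- paste0("S", 1:20)
  rel <- toyExperiment(m, mode = "relative")
  prev <- seq(0, 1, by = 0.25)
  ab <- c(0, 0.001, 0.05, 0.2)
  for (i in seq_along(prev)[-1])
    expect_true(all(coreSet(rel, prev[i], 0.05) %in% coreSet(rel, prev[i - 1], 0.05)))
  for (i in seq_along(ab)[-1])
    expect_true(all(coreSet(rel, 0.5, ab[i]) %in% coreSet(rel, 0.5, ab[i - 1])))
})

test_that("common abundant taxa outrank rare ones in prevalence and persistence", {
  sim <- quickSim(seed = 21, sigma_individual = 0.4, seasonal_amplitude = 0,
                  n_ind = 15, days = 200)
  ae <- sim$experiment
  eta <- sim$truth$eta[asvIds(ae)[!grepl("CONT", asvIds(ae))]]
  top <- names(sort(eta, decreasing = TRUE))[1:5]
  bottom <- names(sort(eta))[1:5]
  P <- subsampledPrevalence(ae, n_iter = 25, seed = 4)
  psi <- persistence(ae, min_captures = 3)
  expect_gt(mean(P[top]), mean(P[bottom]))
  expect_gt(mean(psi[top]), mean(psi[bottom]))
})

test_that("coreTaxaReport combines components reproducibly", {
  ae <- coreToy()
  r1 <- coreTaxaReport(ae, n_iter = 20, min_captures = 2, seed = 5)
  r2 <- coreTaxaReport(ae, n_iter = 20, min_captures = 2, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$prevalence >= 0 & r1$prevalence <= 1))
  expect_true(all(r1$persistence >= 0 & r1$persistence <= 1))
})
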