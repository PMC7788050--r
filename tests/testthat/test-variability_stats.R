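test_that("differential-site counting matches a per-probe loop oracle", {
  set.seed(71)
  p <- 200
  a <- make_beta(p, 6, seed = 72)
  b <- make_beta(p, 5, seed = 73)
  rownames(b) <- rownames(a)
  n <- dmr_count(a, b)
  oracle <- 0L
  for (i in seq_len(p))
    if (abs(mean(a[i, ]) - mean(b[i, ])) >= 0.3) oracle <- oracle + 1L
  expect_equal(n, oracle)
  ## identical groups give zero
  expect_equal(dmr_count(a, a), 0)
  ## boundary inclusive: means 0.10 vs 0.40 count as differential
  a1 <- matrix(0.10, 1, 3, dimnames = list("cg1", c("x", "y", "z")))
  b1 <- matrix(0.40, 1, 3, dimnames = list("cg1", c("u", "v", "w")))
  expect_equal(dmr_count(a1, b1), 1)
  expect_equal(dmr_count(a1, b1 - 1e-9), 0)
})

test_that("differential counting is symmetric and monotone in the threshold", {
  a <- make_beta(80, 5, seed = 74)
  b <- make_beta(80, 7, seed = 75)
  rownames(b) <- rownames(a)
  expect_equal(dmr_count(a, b), dmr_count(b, a))
  thresholds <- seq(0.05, 0.6, by = 0.05)
  counts <- vapply(thresholds, function(t) dmr_count(a, b, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
  ## missing values excluded from means; all-missing probes skipped
  a2 <- a; a2[1, ] <- NA; a2[2, 1:2] <- NA
  expect_message(n2 <- dmr_count(a2, b), "skipped")
  oracle <- sum(abs(rowMeans(a2[-1, ], na.rm = TRUE) -
                      rowMeans(b[-1, ], na.rm = TRUE)) >= 0.3)
  expect_equal(n2, oracle)
})

test_that("resampling with pools of exactly n gives zero variance", {
  beta <- make_beta(60, 10, seed = 76)
  a <- colnames(beta)[1:5]
  b <- colnames(beta)[6:10]
  res <- resampled_dmr_mean(beta, a, b, n = 5, reps = 20, seed = 1)
  expect_length(res$values, 20)
  expect_equal(res$sem, 0)
  expect_equal(res$mean, dmr_count(beta[, a], beta[, b]))
  expect_error(resampled_dmr_mean(beta, a, b, n = 6), "at least")
  ## reps = 1 with full pools equals the direct statistic
  res1 <- resampled_dmr_mean(beta, a, b, n = 5, reps = 1, seed = 2)
  expect_equal(res1$values, dmr_count(beta[, a], beta[, b]))
})

test_that("two pools from one homogeneous class have (almost) no differential sites", {
  ## tight within-class noise far below the 0.3 threshold
  set.seed(77)
  m <- rep(runif(300, 0.2, 0.8), 24)
  beta <- matrix(pmin(pmax(m + rnorm(300 * 24, 0, 0.02), 0), 1), 300, 24,
                 dimnames = list(sprintf("cg%03d", 1:300),
                                 sprintf("s%02d", 1:24)))
  res <- resampled_dmr_mean(beta, colnames(beta)[1:12],
                            colnames(beta)[13:24], n = 8, reps = 30,
                            seed = 3)
  expect_equal(res$mean, 0)
})

test_that("planted mean gaps are recovered by the resampled count", {
  set.seed(78)
  p <- 120
  gap_idx <- 1:50  # 50 probes with a 0.5 between-group gap
  mkgroup <- function(level_fun, n) {
    m <- matrix(runif(p * n, 0.4, 0.45), p, n)
    m[gap_idx, ] <- level_fun(length(gap_idx) * n)
    m
  }
  a <- mkgroup(function(k) runif(k, 0.05, 0.10), 20)
  b <- mkgroup(function(k) runif(k, 0.55, 0.60), 20)
  beta <- cbind(a, b)
  dimnames(beta) <- list(sprintf("cg%03d", 1:p), sprintf("s%02d", 1:40))
  res <- resampled_dmr_mean(beta, colnames(beta)[1:20],
                            colnames(beta)[21:40], n = 15, reps = 50,
                            seed = 4)
  expect_equal(res$mean, 50)
})

test_that("SD histogram conserves probes per replicate and flags high SD", {
  ## constant matrix: every probe lands in the lowest bin
  beta0 <- matrix(0.5, 40, 20,
                  dimnames = list(sprintf("cg%02d", 1:40),
                                  sprintf("s%02d", 1:20)))
  h0 <- sd_range_histogram(beta0, colnames(beta0), n = 10, reps = 5,
                           seed = 1)
  expect_equal(h0$bins$mean_count[1], 40)
  expect_equal(sum(h0$bins$mean_count), 40)
  expect_equal(h0$high_sd_mean_count, 0)
  ## random matrix: per-rep totals conserved
  beta <- make_beta(100, 25, seed = 79)
  h <- sd_range_histogram(beta, colnames(beta), n = 12, reps = 10, seed = 2)
  expect_equal(sum(h$bins$mean_count), 100)
  ## monotonicity: noisier data has more high-SD probes
  set.seed(80)
  quiet <- matrix(pmin(pmax(0.5 + rnorm(100 * 25, 0, 0.02), 0), 1), 100, 25,
                  dimnames = dimnames(beta))
  noisy <- matrix(pmin(pmax(0.5 + rnorm(100 * 25, 0, 0.15), 0), 1), 100, 25,
                  dimnames = dimnames(beta))
  hq <- sd_range_histogram(quiet, colnames(quiet), n = 12, reps = 10,
                           seed = 3)
  hn <- sd_range_histogram(noisy, colnames(noisy), n = 12, reps = 10,
                           seed = 3)
  expect_gt(hn$high_sd_mean_count, hq$high_sd_mean_count)
})

test_that("within-type variable-site counting uses the beta range", {
  beta0 <- matrix(0.2, 30, 16,
                  dimnames = list(sprintf("cg%02d", 1:30),
                                  sprintf("s%02d", 1:16)))
  res0 <- within_type_variable_count(beta0, colnames(beta0), n = 10,
                                     reps = 5, seed = 1)
  expect_equal(res0$mean, 0)
  ## one probe stepping 0.1 -> 0.5 across samples: range 0.4 >= 0.3
  beta1 <- beta0
  beta1[7, ] <- seq(0.1, 0.5, length.out = 16)
  res1 <- within_type_variable_count(beta1, colnames(beta1), n = 16,
                                     reps = 3, seed = 2)
  expect_equal(res1$mean, 1)
})

test_that("site profiles group samples correctly and expose spread", {
  co <- tiny_cohort(seed = 15, n_probes = 150)
  sites <- co$truth$probe_id[co$truth$archetype == "ipsc_variable"][1:3]
  prof <- site_methylation_profile(co$beta, sites, co$sheet,
                                   grouping = "cell_type")
  ## direct column extraction oracle for one site/group
  esc_cols <- co$sheet$sample_id[co$sheet$cell_type == "ESC"]
  got <- prof$values$beta[prof$values$probe_id == sites[1] &
                            prof$values$group == "ESC"]
  expect_setequal(got, co$beta[sites[1], esc_cols])
  ## planted iPSC-variable sites: iPSC SD exceeds ESC SD
  s <- prof$summary
  for (site in sites)
    expect_gt(s$sd[s$probe_id == site & s$group == "iPSC"],
              s$sd[s$probe_id == site & s$group == "ESC"])
  ## grouping by derivation method partitions exactly the iPSC samples
  prof2 <- site_methylation_profile(co$beta, sites, co$sheet,
                                    grouping = "derivation_method")
  ipsc_ids <- co$sheet$sample_id[co$sheet$cell_type == "iPSC"]
  covered <- unique(prof2$values$sample_id[
    prof2$values$group != "none"])
  expect_setequal(covered, ipsc_ids)
})
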