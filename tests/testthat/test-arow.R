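test_that("a fresh model has zero weights, unit confidences, zero scores", {
  m <- init_model(c("cg1", "cg2", "cg3"), r = 1)
  expect_equal(unname(m$mu), matrix(0, 3, 4))
  expect_equal(unname(m$sigma), matrix(1, 3, 4))
  expect_equal(m$epoch_count, 0L)
  s <- decision_scores(m, c(cg1 = 0.3, cg2 = 0.9, cg3 = 0.1))
  expect_equal(unname(s), rep(0, 4))
  expect_error(init_model(c("cg1"), r = 0), "positive")
  expect_error(init_model(c("cg1"), r = -2), "positive")
})

test_that("single AROW update matches the hand-computed worked example", {
  st <- list(mu = c(0, 0), sigma = c(1, 1), r = 1)
  out <- arow_update_binary(st, x = c(1, 0), y = +1)
  ## m = 0, beta = 1/(1+1) = 0.5, alpha = 0.5
  expect_equal(out$mu, c(0.5, 0))
  expect_equal(out$sigma, c(0.5, 1))
})

test_that("no update occurs at margin >= 1, nor on a zero input vector", {
  st <- list(mu = c(2, 0), sigma = c(0.4, 0.9), r = 1)
  expect_identical(arow_update_binary(st, c(0.5, 0.3), +1), st)  # m = 1
  expect_identical(arow_update_binary(st, c(0.6, 0.1), +1), st)  # m > 1
  out <- arow_update_binary(st, c(0, 0), -1)
  expect_equal(out$mu, st$mu)
  expect_equal(out$sigma, st$sigma)
  expect_error(arow_update_binary(st, c(1, 2, 3), 1), "length")
})

test_that("confidences stay positive and non-increasing over random update streams", {
  set.seed(101)
  p <- 8
  st <- list(mu = rep(0, p), sigma = rep(1, p), r = 0.7)
  n_updates <- 0L
  n_viol <- 0L
  for (i in 1:10000) {
    x <- runif(p)
    y <- sample(c(-1, 1), 1)
    margin <- y * sum(st$mu * x)
    prev_sigma <- st$sigma
    st2 <- arow_update_binary(st, x, y)
    expect_true(all(st2$sigma > 0))
    expect_true(all(st2$sigma <= prev_sigma + 1e-15))
    changed <- !isTRUE(all.equal(st2$mu, st$mu)) ||
      !isTRUE(all.equal(st2$sigma, st$sigma))
    if (margin < 1) n_viol <- n_viol + 1L
    if (changed) n_updates <- n_updates + 1L
    ## state changes exactly on margin violations (x is never zero here)
    expect_equal(changed, margin < 1)
    st <- st2
  }
  expect_equal(n_updates, n_viol)
})

test_that("decision scores equal a brute-force elementwise sum", {
  set.seed(7)
  m <- init_model(sprintf("cg%02d", 1:12), r = 1)
  m$mu[] <- rnorm(length(m$mu))
  x <- runif(12)
  names(x) <- m$probe_ids
  s <- decision_scores(m, x)
  oracle <- vapply(seq_along(m$classes), function(k) {
    acc <- 0
    for (j in 1:12) acc <- acc + m$mu[j, k] * x[[j]]
    acc
  }, numeric(1))
  expect_equal(unname(s), oracle)
  expect_error(decision_scores(m, c(cg01 = 0.5)), "lacks")
})

test_that("prediction is the argmax with ties broken by class order", {
  m <- init_model(c("cg1"), r = 1)
  m$mu[1, ] <- c(0.1, 0.9, 0.0, -0.2)
  expect_equal(unname(predict(m, matrix(1, 1, 1,
    dimnames = list("cg1", "s1")))), "iPSC")
  ## all-zero scores tie: first class in order wins
  m0 <- init_model(c("cg1"), r = 1)
  expect_equal(unname(predict(m0, matrix(0.4, 1, 1,
    dimnames = list("cg1", "s1")))), "ESC")
  ## 50 random score vectors match a linear-scan oracle
  set.seed(11)
  for (i in 1:50) {
    mm <- init_model(c("cg1"), r = 1)
    mm$mu[1, ] <- rnorm(4)
    x <- matrix(runif(1, 0.1, 1), 1, 1, dimnames = list("cg1", "s1"))
    scores <- drop(crossprod(mm$mu, x))
    best <- 1
    for (k in 2:4) if (scores[k] > scores[best]) best <- k
    expect_equal(unname(predict(mm, x)), mm$classes[best])
  }
})

test_that("an epoch visits each sample once and trains deterministically", {
  toy <- make_separable_toy()
  m <- init_model(rownames(toy$x), r = 1)
  m1 <- train_epoch(m, toy$x, toy$y, seed = 3)
  m2 <- train_epoch(m, toy$x, toy$y, seed = 3)
  expect_identical(m1$mu, m2$mu)
  expect_identical(m1$sigma, m2$sigma)
  expect_equal(m1$epoch_count, 1L)
  expect_error(train_epoch(m, toy$x, toy$y[-1]), "length|unlabeled")
  ## one-sample training set: all four class states receive an update
  x1 <- toy$x[, 1, drop = FALSE]
  m3 <- train_epoch(m, x1, toy$y[1])
  expect_true(all(colSums(m3$sigma < 1) > 0))
})

test_that("the learner fits a linearly separable toy set perfectly", {
  toy <- make_separable_toy()
  fit <- arow(toy$x, toy$y, r = 1, epochs = 20, seed = 1)
  expect_equal(unname(predict(fit, toy$x)), unname(toy$y))
  expect_equal(fit$epoch_count, 20L)
  ## margin violations shrink as training proceeds: the per-epoch weight
  ## change decays towards stationarity on separable data
  delta_at <- function(epochs) {
    f <- arow(toy$x, toy$y, r = 1, epochs = epochs, seed = 1)
    f2 <- train_epoch(f, toy$x, toy$y, seed = 99)
    max(abs(f2$mu - f$mu))
  }
  expect_lt(delta_at(300), delta_at(20) / 5)
})

test_that("training is invariant to probe permutation", {
  toy <- make_separable_toy()
  perm <- c(3, 1, 5, 2, 4)
  fit <- arow(toy$x, toy$y, r = 1, epochs = 5, seed = 2)
  fit_perm <- arow(toy$x[perm, , drop = FALSE], toy$y, r = 1, epochs = 5,
                   seed = 2)
  expect_equal(fit_perm$mu[rownames(toy$x), ], fit$mu)
  expect_equal(unname(predict(fit_perm, toy$x)),
               unname(predict(fit, toy$x)))
})

test_that("missing beta values contribute zero to scores and updates", {
  m <- init_model(c("cg1", "cg2"), r = 1)
  m$mu[, "iPSC"] <- c(1, 1)
  x <- c(cg1 = 0.8, cg2 = NA)
  expect_equal(decision_scores(m, x)[["iPSC"]], 0.8)
  ## training with an all-NA feature never touches its weight
  xm <- matrix(c(0.9, NA, 0.1, NA), 2, 2,
               dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
  fit <- suppressMessages(
    arow(xm, c("ESC", "iPSC"), r = 1, epochs = 3, seed = 1))
  expect_equal(unname(fit$mu["cg2", ]), rep(0, 4))
})

test_that("checkpoints round-trip bit-exactly and reject corrupt files", {
  toy <- make_separable_toy()
  fit <- arow(toy$x, toy$y, r = 0.5, epochs = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$mu, fit$mu)
  expect_identical(back$sigma, fit$sigma)
  expect_identical(back$r, fit$r)
  expect_identical(back$epoch_count, fit$epoch_count)
  expect_identical(back$probe_ids, fit$probe_ids)
  ## reloaded model predicts identically
  expect_identical(predict(back, toy$x), predict(fit, toy$x))
  ## truncated file
  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[1:20], trunc_path)
  expect_error(load_checkpoint(trunc_path), "cannot read|checkpoint")
  ## foreign rds
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_checkpoint(other), "not a methylarow checkpoint")
})
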