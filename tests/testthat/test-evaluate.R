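# exhaustive assignment oracle: maximize matches under the cap, then
# minimize the total matched distance
oracle_match <- function(result, truth, thr) {
  nr <- nrow(result); nt <- nrow(truth)
  A <- as.matrix(result[, c("X", "Y", "Z")])
  B <- as.matrix(truth[, c("X", "Y", "Z")])
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nr), nr + seq_len(nt),
                                           drop = FALSE]
  best_n <- -1; best_sum <- Inf
  idx <- seq_len(nt)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(idx)) {
    d <- D[cbind(seq_len(min(nr, nt)), p[seq_len(min(nr, nt))])]
    ok <- d < thr
    n <- sum(ok); s <- sum(d[ok])
    if (n > best_n || (n == best_n && s < best_sum)) {
      best_n <- n; best_sum <- s
    }
  }
  list(n = best_n, sum = best_sum)
}

test_that("perfect recoveries score precision = recall = 1, RMSE 0", {
  truth <- tibble::tibble(X = c(0, 30, -20), Y = c(0, 5, 8), Z = c(1, 2, 3))
  m <- evaluate_contacts(truth, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$rmse_mm, 0)
})

test_that("zero-denominator conventions are honored", {
  truth <- tibble::tibble(X = c(0, 30), Y = c(0, 0), Z = c(0, 0))
  empty <- truth[0, ]
  m <- evaluate_contacts(empty, truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0)
  m2 <- evaluate_contacts(truth, empty)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 1)
})

test_that("matching is one-to-one: a single detection cannot claim two", {
  truth <- tibble::tibble(X = c(0, 4), Y = 0, Z = 0)
  result <- tibble::tibble(X = 2, Y = 0, Z = 0)
  m <- evaluate_contacts(result, truth)
  expect_equal(m$n_matched, 1L)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 1)
})

test_that("optimal assignment agrees with exhaustive enumeration", {
  set.seed(23)
  for (trial in 1:40) {
    nr <- sample(1:6, 1); nt <- sample(1:6, 1)
    result <- tibble::tibble(X = runif(nr, -20, 20), Y = runif(nr, -20, 20),
                             Z = runif(nr, -20, 20))
    truth <- tibble::tibble(X = runif(nt, -20, 20), Y = runif(nt, -20, 20),
                            Z = runif(nt, -20, 20))
    m <- evaluate_contacts(result, truth, dist_threshold = 15)
    o <- if (nr <= nt) oracle_match(result, truth, 15)
         else oracle_match(truth, result, 15)
    expect_equal(m$n_matched, as.integer(o$n))
  }
})

test_that("the assignment solver minimizes total cost", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  set.seed(61)
  for (trial in 1:25) {
    n <- sample(2:6, 1); m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    asg <- thermaltouch:::cpp_hungarian(cost)
    got <- sum(cost[cbind(seq_len(n), asg)])
    best <- min(vapply(perms(seq_len(m)), function(p)
      sum(cost[cbind(seq_len(n), p[seq_len(n)])]), 0))
    expect_equal(got, best, tolerance = 1e-9)
    expect_equal(anyDuplicated(asg), 0L)
  }
})

test_that("run_scene drives localization plus mapping end to end", {
  suite <- make_benchmark_suite(n_scenes = 1, seed = 31)
  r <- run_scene(suite[[1]])
  expect_equal(r$metrics$precision, 1)
  expect_equal(r$metrics$recall, 1)
  expect_lt(r$metrics$rmse_mm, 3)
  expect_lt(glance(r$pose)$rms_residual_mm, 0.01)
})
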