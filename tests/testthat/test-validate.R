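# Agreement and distribution statistics against independent oracles.

test_that("regression slope matches closed-form normal equations", {
  # perfect fits warn about unreliable summaries; only the slope matters here
  expect_equal(suppressWarnings(regress_counts(1:10, 1:10))$beta, 1)
  expect_lt(suppressWarnings(regress_counts(1:10, 1:10))$p, 1e-6)
  expect_equal(suppressWarnings(regress_counts(1:10, 2 * (1:10)))$beta, 2)

  set.seed(7)
  for (rep in 1:5) {
    x <- rnorm(28, 40, 8)
    y <- 0.8 * x + rnorm(28, 0, 4)
    fit <- regress_counts(x, y)
    beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a_hat <- mean(y) - beta_hat * mean(x)
    resid <- y - a_hat - beta_hat * x
    se <- sqrt(sum(resid^2) / (28 - 2) / sum((x - mean(x))^2))
    p_hat <- 2 * stats::pt(abs(beta_hat / se), df = 26, lower.tail = FALSE)
    expect_equal(fit$beta, beta_hat, tolerance = 1e-10)
    expect_equal(fit$p, p_hat, tolerance = 1e-10)
  }
  expect_error(regress_counts(rep(3, 5), 1:5), "variance")
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:3, 11:13)$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3,
               tolerance = 1e-12)

  brute_D <- function(a, b) {
    xs <- sort(unique(c(a, b)))
    max(vapply(xs, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
  }
  set.seed(12)
  for (rep in 1:100) {
    a <- rnorm(sample(3:40, 1))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$D, brute_D(a, b), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("summary statistics match direct formula evaluation", {
  x <- c(1, 1, 1, 5)
  st <- summary_stats(x)
  n <- length(x); m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - 1))
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)   # adjusted Fisher-Pearson
  expect_equal(st$mean, m, tolerance = 1e-12)
  expect_equal(st$sd, s, tolerance = 1e-12)
  expect_equal(st$cv, s / m, tolerance = 1e-12)
  expect_equal(st$skewness, G1, tolerance = 1e-12)
  expect_equal(st$median, 1)
  expect_equal(st$range, 4)

  cst <- summary_stats(rep(2, 5))
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv, 0)
  expect_true(is.na(cst$skewness))
  expect_equal(summary_stats(c(1, 2, 3))$skewness, 0)
  # zero mean flags CV undefined
  expect_true(is.na(summary_stats(c(-1, 1))$cv))
})

test_that("detection scoring counts and matches correctly", {
  truth <- data.frame(id = 1:10, attach_x = seq(2, 20, by = 2),
                      attach_y = 0, attach_z = 0,
                      head_width = 0.5, neck_width = 0.2, length = 1.5,
                      head_volume = 0.1)
  perfect <- data.frame(id = 1:10, attach_x = seq(2, 20, by = 2),
                        attach_y = 0, attach_z = 0,
                        head_width = 0.5, neck_width = 0.2, length = 1.5,
                        head_volume = 0.1)
  sc <- score_detection(perfect, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)

  sc_miss <- score_detection(perfect[-3, ], truth)
  expect_equal(sc_miss$recall, 0.9)
  expect_equal(sc_miss$precision, 1)

  jit <- perfect
  jit$attach_y <- 0.2
  expect_equal(score_detection(jit, truth, tol = 0.5)$tp, 10)
  expect_equal(score_detection(jit, truth, tol = 0.1)$tp, 0)
  expect_error(score_detection(perfect, truth, tol = 0), "positive")

  # swapping roles swaps precision and recall
  sc_swap <- score_detection(truth, perfect[-3, ])
  expect_equal(sc_swap$precision, sc_miss$recall)
  expect_equal(sc_swap$recall, sc_miss$precision)
})

test_that("ecdf curves are monotone and end at 1", {
  cv <- ecdf_curve(rnorm(50))
  expect_true(all(diff(cv$x) >= 0))
  expect_true(all(diff(cv$ecdf) > 0))
  expect_equal(cv$ecdf[50], 1)
})
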