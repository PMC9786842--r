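test_that("carry-over weights are normalised geometric decays", {
  for (n in c(0, 3, 12)) for (l in c(0.1, 0.5, 1)) {
    w <- carryover_weights(n, l)
    expect_length(w, n + 1)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
    if (n > 0 && l < 1) expect_true(all(diff(w) < 0))
  }
  expect_equal(carryover_weights(2, 0.5), c(1, 0.5, 0.25) / 1.75)
  expect_error(carryover_weights(-1, 0.5), "integer")
  expect_error(carryover_weights(2, 0), "lambda")
  expect_error(carryover_weights(2, 1.2), "lambda")
})

test_that("carry-over integration matches hand evaluation and its limits", {
  d <- as.Date("2020-01-01") + 0:9
  x <- c(3, 2, 1, 4, 5, 2, 0, 1, 3, 2)
  # hand case: lambda 0.5, n 2 on (3, 2, 1)
  expect_equal(integrate_carryover(d[1:3], c(3, 2, 1), 2, 0.5)$value,
               (1 + 0.5 * 2 + 0.25 * 3) / 1.75)
  # n = 0 is the identity for every lambda
  for (l in c(0.1, 0.7, 1))
    expect_equal(integrate_carryover(d, x, 0, l)$value, x)
  # lambda = 1 is the unweighted moving average
  expect_equal(integrate_carryover(d, x, 2, 1)$value[1],
               mean(x[1:3]))
  # output lies within [min, max] of the window inputs
  out <- integrate_carryover(d, x, 3, 0.6)
  expect_true(all(out$value >= min(x) & out$value <= max(x)))
  # insufficient look-back coverage is an error
  expect_error(integrate_carryover(d, x, 3, 0.6, at = d[2]), "look-back")
  # flat weights reproduce the moving average at any lambda
  expect_equal(integrate_carryover(d, x, 2, 0.3, flat = TRUE)$value,
               integrate_carryover(d, x, 2, 1)$value)
})

test_that("rank correlations behave as rank statistics", {
  x <- c(5, 3, 9, 1, 7, 2, 8)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # invariance to strictly monotone transforms
  expect_equal(spearman_cor(x, exp(x / 3))$rho, 1)
  expect_equal(spearman_cor(x, x)$p, 0)
  expect_error(spearman_cor(x, rep(1, 7)), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  pc <- pearson_cor(x, 2 * x + 1)
  expect_equal(pc$r, 1)
  # p-value agrees with the t approximation
  r <- pearson_cor(x, c(4, 2, 8, 2, 6, 1, 9))
  tt <- r$r * sqrt(5 / (1 - r$r^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 5))
})

test_that("grid search finds the generating carry-over cell", {
  d <- as.Date("2018-05-01") + 0:59
  set.seed(31)
  drv <- data.frame(date = d, value = -26 + sin(1:60 / 5) + rnorm(60, sd = 1))
  # pool identical to driver: argmax at n = 0 with rho = 1
  pool <- data.frame(date = d[20:50], value = drv$value[20:50])
  gs <- carryover_grid_search(pool, drv)
  expect_s3_class(gs, "carryover_surface")
  expect_identical(gs$best$n, 0L + 0L)
  expect_equal(gs$best$rho, 1)
  expect_equal(nrow(gs$surface), 13 * 10)
  # pool generated with (n = 4, lambda = 0.8) is recovered
  w <- integrate_carryover(d, drv$value, 4, 0.8, at = d[20:50])
  gs2 <- carryover_grid_search(data.frame(date = w$date, value = w$value),
                               drv)
  expect_identical(as.integer(gs2$best$n), 4L)
  expect_equal(gs2$best$lambda, 0.8)
  # independent pools: significant cells occur near the nominal 5 % rate
  # (cells are correlated, so the fraction is averaged over replicates)
  set.seed(99)
  null_frac <- replicate(40, {
    null_pool <- data.frame(date = d[15:55], value = rnorm(41))
    mean(carryover_grid_search(null_pool, drv)$surface$significant)
  })
  expect_lt(mean(null_frac), 0.12)
  expect_error(carryover_grid_search(pool[1:3, ], drv), "fewer than 8")
})

test_that("needle-generation combination follows the per-pool rules", {
  d <- as.Date("2018-06-01") + c(0, 7, 14)
  s1 <- data.frame(date = d, value = c(-26, -27, -28))
  # identical sucrose series combine to themselves
  expect_equal(combine_generations(s1, s1, "sucrose")$value, s1$value)
  # WSC: the 0N offset is removed first, so the combination represents 1N
  w0 <- data.frame(date = d[1], value = -27.8)
  w1 <- data.frame(date = d[1], value = -28.4)
  expect_equal(combine_generations(w0, w1, "WSC", wsc_offset = 0.6)$value,
               -28.4)
  # non-overlapping dates pass through
  part <- combine_generations(s1[1:2, ], s1[2:3, ], "sucrose")
  expect_equal(part$value, s1$value)
  # pools with unstable generation offsets are refused
  expect_error(combine_generations(s1, s1, "starch"), "not combined")
  expect_error(combine_generations(s1, s1, "pinitol"), "not combined")
  expect_equal(combine_generations(s1, s1, "starch", force = TRUE)$value,
               s1$value)
})
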