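test_that("Gamma* temperature response matches independent evaluation", {
  expect_identical(gamma_star(25), 42.75)
  # independent evaluation of the exponential at 15 and 5 degC
  g <- function(Tl) 42.75 * exp(37830 * (Tl - 25) / (298 * 8.3145 * (Tl + 273.15)))
  expect_equal(gamma_star(15), g(15))
  expect_equal(gamma_star(15), 25.17, tolerance = 1e-3)
  expect_equal(gamma_star(5), 14.26, tolerance = 1e-3)
  expect_true(all(diff(gamma_star(seq(0, 40, 0.5))) > 0))
})

test_that("mitochondrial respiration equals R_d0 at 25 degC and scales with T", {
  rp <- resp_params(0.8, 40000)
  expect_equal(mitochondrial_respiration(25, rp), 0.8)
  expect_equal(mitochondrial_respiration(15, rp),
               0.8 * exp(40000 * (-10) / (298 * 8.3145 * 288.15)))
  expect_equal(mitochondrial_respiration(15, rp), 0.457, tolerance = 1e-3)
  expect_equal(mitochondrial_respiration(30, resp_params(0, 40000)), 0)
  expect_true(all(diff(mitochondrial_respiration(0:30, rp)) > 0))
})

test_that("respiration fit recovers generating parameters", {
  rp <- resp_params(0.8, 40000)
  Tl <- seq(2, 18, length.out = 40)
  efflux <- mitochondrial_respiration(Tl, rp)
  fit <- fit_respiration(Tl, efflux)
  expect_equal(fit$R_d0, 0.8, tolerance = 1e-6)
  expect_equal(fit$H_alpha, 40000, tolerance = 1e-6)
  expect_lt(attr(fit, "rmse"), 1e-8)
  # noisy recovery stays close
  set.seed(11)
  noisy <- efflux + rnorm(length(efflux), sd = 0.05)
  fit2 <- fit_respiration(Tl, noisy)
  expect_equal(fit2$R_d0, 0.8, tolerance = 0.1)
  # degenerate designs are refused
  expect_error(fit_respiration(rep(10, 10), rep(0.5, 10)), "span")
  expect_error(fit_respiration(c(5, 15), c(0.3, 0.6)), "at least 5")
})

test_that("the discrimination model reproduces hand-evaluated cases", {
  # simple two-term limit: gm infinite, Rd = 0, f = 0
  p0 <- disc_params(f = 0, g_m = Inf)
  r0 <- resp_params(0, 0)
  expect_equal(model_discrimination(5, 400, 280, 25, p0, r0),
               4.4 + 24.6 * 0.7)
  # full model, term-by-term hand evaluation at ci/ca = 0.7
  p <- disc_params()
  r1 <- resp_params(1, 40000)
  D <- model_discrimination(5, 400, 280, 25, p, r1)
  by_hand <- 4.4 + 24.6 * 0.7 - 27.2 * 5 / (0.127 * 400) - 8 * 42.75 / 400 -
    (1 / 6) * (-6) * (280 - 42.75) / 400
  expect_equal(D, by_hand)
  expect_equal(D, 18.68, tolerance = 1e-2)
  # photorespiration sensitivity: f = 11 vs 8 shifts Delta by 3*Gamma*/ca
  D11 <- model_discrimination(5, 400, 280, 25, disc_params(f = 11), r1)
  expect_equal(D - D11, 3 * 42.75 / 400)
  # light-inhibition switch zeroes the respiration term
  rL <- resp_params(1, 40000, light_inhibited = TRUE)
  DL <- model_discrimination(5, 400, 280, 25, p, rL)
  expect_equal(DL, 4.4 + 24.6 * 0.7 - 27.2 * 5 / (0.127 * 400) - 8 * 42.75 / 400)
  expect_error(model_discrimination(-2, 400, 280, 25, p, resp_params(1, 0)),
               "A \\+ R_d")
})

test_that("delta/discrimination conversion is an exact involution", {
  expect_equal(delta_from_discrimination(-8.5, 0), -8.5)
  expect_equal(delta_from_discrimination(-8.5, 18.68),
               1000 * (-8.5 - 18.68) / 1018.68)
  set.seed(3)
  d_air <- runif(1000, -12, -6)
  Delta <- runif(1000, 5, 30)
  back <- discrimination_from_delta(d_air,
                                    delta_from_discrimination(d_air, Delta))
  expect_lt(max(abs(back - Delta)), 1e-10)
  expect_error(delta_from_discrimination(-8.5, -1000.5), "-1000")
})

test_that("light-inhibited Rd has sub-0.5-permil impact when A >> Rd", {
  env <- generate_environment(dry_season())
  rp <- resp_params(0.8, 40000)
  truth <- generate_gas_exchange(env, pine_physiology(), disc_params(), rp)
  # restrict to records where assimilation dominates respiration
  day <- is.finite(truth$ci) &
    truth$A > 8 * mitochondrial_respiration(truth$Tl, rp)
  D_on <- model_discrimination(truth$A[day], env$ca[day], truth$ci[day],
                               truth$Tl[day], disc_params(), rp)
  D_off <- model_discrimination(truth$A[day], env$ca[day], truth$ci[day],
                                truth$Tl[day], disc_params(),
                                resp_params(0.8, 40000, light_inhibited = TRUE))
  expect_lt(max(abs(D_on - D_off)), 0.5)
})

test_that("modeled daily series tracks the generator truth at zero noise", {
  env <- generate_environment(dry_season())
  rp <- resp_params(0.8, 40000)
  truth <- generate_gas_exchange(env, pine_physiology(), disc_params(), rp)
  day <- is.finite(truth$deltaA_true) & truth$A > 0 & truth$E > 0
  rec <- data.frame(timestamp = env$timestamp, A = truth$A, E = truth$E,
                    Tl = truth$Tl, ca = env$ca,
                    delta13C_air = env$delta13C_air,
                    es = env$es, ea = env$ea, P_amb = env$P_amb)[day, ]
  model <- model_delta_series(rec, disc_params(), rp)
  tru <- truth_deltaA_daily(truth)
  m <- merge(model, tru, by = "date")
  expect_gt(nrow(m), 30)
  expect_gt(cor(m$delta13C_A_model, m$value), 0.99)
  expect_error(model_delta_series(rec[setdiff(names(rec), "A")]),
               "missing columns")
  expect_warning(model_delta_series(rec[0, ], disc_params(), rp),
                 "no usable")
})
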