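# minimal hand-built fit objects for summary-stage unit tests
fake_fit <- function(draws, blocks, y = NULL, deviance = NULL,
                     eta_mean = NULL, knots = list(), zones = character(0)) {
  structure(list(draws = draws, deviance = deviance, eta_mean = eta_mean,
                 y = y,
                 param_info = data.frame(parameter = colnames(draws),
                                         block = blocks,
                                         stringsAsFactors = FALSE),
                 knots = knots, zones = zones),
            class = "bstar_fit")
}

test_that("posterior summaries report mean, SD, quantiles and odds ratios", {
  d <- cbind(`(Intercept)` = rep(2, 50), credityes = rep(log(0.23), 50))
  s <- summarize_posterior(fake_fit(d, c("fixed", "fixed")))
  expect_equal(s$mean, c(2, log(0.23)))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$q2.5, s$q97.5)
  # exp-transform reporting convention for fixed-effect contrasts
  expect_equal(s$or[2], 0.23)
  expect_equal(s$or_low[2], 0.23)
  expect_true(is.na(s$or[1])) # no OR for the intercept

  set.seed(10)
  z <- matrix(rnorm(1000), dimnames = list(NULL, "x"))
  sz <- summarize_posterior(fake_fit(z, "fixed"))
  expect_lt(abs(sz$q2.5 - (-1.96)), 0.1)
  expect_lt(abs(sz$q97.5 - 1.96), 0.1)

  # permutation invariance in draw order
  perm <- sample(nrow(z))
  sz2 <- summarize_posterior(fake_fit(z[perm, , drop = FALSE], "fixed"))
  expect_equal(sz, sz2)

  expect_error(summarize_posterior(fake_fit(z[1, , drop = FALSE], "fixed")),
               "2 retained")
})

test_that("DIC reduces to the plug-in deviance for a degenerate chain", {
  # single repeated state: p_d = 0, DIC = that state's deviance
  # n = 1, y = 1, pi = 0.5 across draws: deviance 2 log 2
  f <- fake_fit(matrix(0, 2, 1, dimnames = list(NULL, "a")), "fixed",
                y = 1, deviance = rep(2 * log(2), 2), eta_mean = 0)
  dic <- compute_dic(f)
  expect_equal(dic$p_d, 0, tolerance = 1e-12)
  expect_equal(dic$dic, 2 * log(2), tolerance = 1e-12)

  f$deviance[2] <- NaN
  expect_error(compute_dic(f), "draw 2")
})

test_that("autocorrelation has unit lag-0, small iid lags, and degenerate flag", {
  set.seed(5)
  x <- rnorm(10000)
  a <- autocorrelation(x, max_lag = 5)
  expect_equal(a$acf[1], 1)
  expect_false(a$degenerate)
  expect_lt(abs(a$acf[2]), 0.03)
  ac <- autocorrelation(rep(3, 100), max_lag = 5)
  expect_true(ac$degenerate)
  expect_true(all(is.na(ac$acf)))
  expect_error(autocorrelation(1:5, max_lag = 10))
})

test_that("effect curves summarise smooth draws pointwise", {
  kn <- c(1, 2, 3)
  d <- matrix(rep(c(0.5, 0.5, 0.5), each = 20), 20, 3,
              dimnames = list(NULL, sprintf("f_age[%d]", 1:3)))
  f <- fake_fit(d, rep("smooth:age", 3), knots = list(age = kn))
  cv <- effect_curve(f, "age")
  expect_equal(cv$knot, kn)
  expect_equal(cv$mean, rep(0.5, 3))
  expect_equal(cv$q97.5 - cv$q2.5, rep(0, 3))
  expect_error(effect_curve(f, "schooling"), "no smooth term")
})

test_that("credible bands shrink as the sample size grows", {
  g <- make_zone_lattice(2, 2)
  tr <- default_truth(g, seed = 2, tau2_str = 0.05, tau2_uns = 0.05)
  cfg <- mcmc_config(iterations = 2500, burn_in = 500, thin = 2, seed = 3)
  width <- sapply(c(800, 4000), function(n) {
    d <- generate_households(g, tr, n = n, seed = 19)
    fit <- suppressMessages(
      run_chain(d, geoadd_spec(g, max_bins = 12), cfg))
    cv <- effect_curve(fit, "schooling")
    mean(cv$q97.5 - cv$q2.5)
  })
  expect_lt(width[2], width[1])
})

test_that("zone effect table carries constrained structured means", {
  zs <- c("A", "B")
  d <- matrix(0, 10, 4,
              dimnames = list(NULL, c("f_str[A]", "f_str[B]",
                                      "f_uns[A]", "f_uns[B]")))
  f <- fake_fit(d, rep(c("spatial_str", "spatial_uns"), each = 2), zones = zs)
  zt <- zone_effect_table(f)
  expect_equal(zt$zone, zs)
  expect_true(all(zt[, -1] == 0))

  s <- small_sim(n = 300, seed = 23)
  fit <- suppressMessages(run_chain(
    s$data, geoadd_spec(s$graph, max_bins = 6),
    mcmc_config(iterations = 600, burn_in = 100, thin = 1, seed = 2)))
  zt2 <- zone_effect_table(fit)
  expect_equal(sum(zt2$str_mean), 0, tolerance = 1e-6)
  expect_error(zone_effect_table(fake_fit(d[, 1:2], rep("fixed", 2))),
               "no spatial")
})

test_that("draws persist to CSV with side-car and read back identically", {
  s <- small_sim(n = 150, seed = 29)
  fit <- suppressMessages(run_chain(
    s$data, geoadd_spec(s$graph, max_bins = 6),
    mcmc_config(iterations = 400, burn_in = 100, thin = 3, seed = 8)))
  fp <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, fp)
  expect_true(file.exists(paste0(fp, ".info")))
  back <- read_draws(fp)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_equal(back$deviance, fit$deviance, tolerance = 1e-12)
})
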