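test_that("Polya-Gamma draws are reproducible and match closed-form moments", {
  set.seed(42)
  a <- rpg(5, 1.3)
  set.seed(42)
  expect_identical(a, rpg(5, 1.3))
  expect_true(all(a > 0))

  set.seed(1)
  x0 <- rpg(100000, 0)
  expect_lt(abs(mean(x0) - 0.25), 3 * sd(x0) / sqrt(length(x0)))
  x2 <- rpg(100000, 2)
  expect_lt(abs(mean(x2) - tanh(1) / 4), 3 * sd(x2) / sqrt(length(x2)))
  # PG(1, c) is symmetric in the sign of c
  xm <- rpg(100000, -2)
  expect_lt(abs(mean(xm) - tanh(1) / 4), 3 * sd(xm) / sqrt(length(xm)))
})

test_that("Gaussian block update matches scalar algebra and dense-solve oracles", {
  set.seed(2)
  n <- 60
  omega <- rgamma(n, 2, 2)
  kappa <- rnorm(n)

  # intercept-only, flat prior: mean sum(kappa)/sum(omega), precision sum(omega)
  Z <- matrix(1, n, 1)
  up <- update_gaussian_block(Z, matrix(0, 1, 1), omega, kappa)
  expect_equal(up$mean, sum(kappa) / sum(omega), tolerance = 1e-12)
  expect_equal(drop(up$precision), sum(omega), tolerance = 1e-12)

  # essentially-infinite prior precision pins the draw at the prior mean 0
  up0 <- update_gaussian_block(Z, matrix(1e12, 1, 1), omega, kappa)
  expect_lt(abs(up0$draw), 1e-4)

  # 3-knot RW2 block: mean solves (Z'OmegaZ + K/tau2) mu = Z'kappa
  idx <- sample(1:3, n, replace = TRUE)
  Zs <- outer(idx, 1:3, "==") + 0
  tau2 <- 0.5
  K <- rw2_penalty(3) / tau2
  ups <- update_gaussian_block(Zs, K, omega, kappa)
  oracle <- solve(t(Zs) %*% (Zs * omega) + K, crossprod(Zs, kappa))
  expect_equal(ups$mean, drop(oracle), tolerance = 1e-8)
})

test_that("variance update draws from the conjugate inverse-Gamma", {
  # zero coefficients: InverseGamma(a + rank/2, b)
  set.seed(3)
  d0 <- replicate(20000, update_variance(rep(0, 5), diag(5), 5, a = 4, b = 3))
  expect_equal(mean(d0), 3 / (4 + 5 / 2 - 1), tolerance = 0.02)

  # rank-18 RW2 with quadratic form 3.6: shape 9.001, scale 1.801
  K <- rw2_penalty(20)
  set.seed(4)
  f <- rnorm(20)
  f <- f * sqrt(3.6 / drop(f %*% K %*% f))
  d1 <- replicate(100000, update_variance(f, K, 18, a = 0.001, b = 0.001))
  ig_mean <- 1.801 / 8.001
  ig_sd <- 1.801 / (8.001 * sqrt(7.001))
  expect_lt(abs(mean(d1) - ig_mean), 3 * ig_sd / sqrt(length(d1)))

  expect_warning(update_variance(c(1, 1), -diag(2), 2, 1, 1), "clamped")
})

test_that("intercept-only chain matches the quadrature posterior", {
  d <- data.frame(y = c(rep(1, 7), rep(0, 3)))
  spec <- model_spec()
  fit <- run_chain(d, spec, mcmc_config(iterations = 7000, burn_in = 2000,
                                        thin = 1, seed = 77))
  expect_equal(nrow(fit$draws), 5000)
  chain_p <- mean(plogis(fit$draws[, "(Intercept)"]))
  expect_lt(abs(chain_p - quadrature_mean_p(7, 10)), 0.02)
})

test_that("chains are deterministic given the config seed", {
  s <- small_sim(n = 200, seed = 13)
  spec <- geoadd_spec(s$graph, max_bins = 8)
  cfg <- mcmc_config(iterations = 300, burn_in = 100, thin = 2, seed = 5)
  f1 <- suppressMessages(run_chain(s$data, spec, cfg))
  f2 <- suppressMessages(run_chain(s$data, spec, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("posterior means agree with maximum likelihood when priors are flat", {
  g <- make_zone_lattice(2, 2)
  tr <- default_truth(g, seed = 4, tau2_str = 0, tau2_uns = 0)
  d <- generate_households(g, tr, n = 3000, seed = 14)
  spec <- model_spec(fixed = c("sex", "shock", "credit"),
                     linear = c("schooling", "asset"),
                     ref = list(sex = "male", shock = "yes", credit = "no"))
  fit <- run_chain(d, spec, mcmc_config(iterations = 4000, burn_in = 1000,
                                        thin = 3, seed = 6))
  s <- summarize_posterior(fit)
  ml <- glm(y ~ relevel(factor(sex), "male") + relevel(factor(shock), "yes") +
              relevel(factor(credit), "no") + schooling + asset,
            binomial(), data = d)
  expect_true(all(abs(s$mean - unname(coef(ml))) < 3 * s$sd))
})

test_that("chain transitions preserve the prior in a successive-conditional check", {
  # 'getting it right': alternating prior/data/parameter draws leave the
  # joint invariant, so tau2 samples must reproduce the IG(3, 2) prior
  # moments (mean 1) within Monte-Carlo error
  g <- path_graph()
  spec <- model_spec(graph = g, a = 3, b = 2, intercept = FALSE)
  d <- data.frame(y = rep(0L, 30), zone = rep(g$zones, 10))
  cycles <- 4000
  t_str <- t_uns <- numeric(cycles)
  set.seed(99)
  state <- list(tau2_str = 1 / rgamma(1, 3, 2), tau2_uns = 1 / rgamma(1, 3, 2))
  state$funs <- rnorm(3, 0, sqrt(state$tau2_uns))
  state$fstr <- unname(sample_icar_field(g, state$tau2_str, seed = 1))
  for (cy in seq_len(cycles)) {
    eta <- state$fstr[match(d$zone, g$zones)] + state$funs[match(d$zone, g$zones)]
    d$y <- rbinom(30, 1, plogis(eta))
    state <- bstar:::gibbs_kernel(d, spec, state, scans = 1)
    t_str[cy] <- state$tau2_str
    t_uns[cy] <- state$tau2_uns
  }
  mcse <- function(x, nb = 40) {
    bm <- colMeans(matrix(x, ncol = nb))
    sd(bm) / sqrt(nb)
  }
  expect_lt(abs(mean(t_str) - 1), 4 * mcse(t_str))
  expect_lt(abs(mean(t_uns) - 1), 4 * mcse(t_uns))
})

test_that("larger IG scale b stochastically raises the variance posterior mean", {
  s <- small_sim(n = 400, seed = 17)
  means <- sapply(1:5, function(sd0) {
    sapply(c(0.001, 0.5, 2), function(bb) {
      spec <- model_spec(smooth = "schooling", b = bb, a = 0.001, max_bins = 10)
      fit <- run_chain(s$data, spec,
                       mcmc_config(iterations = 1200, burn_in = 200,
                                   thin = 1, seed = sd0))
      mean(fit$draws[, "tau2_schooling"])
    })
  })
  avg <- rowMeans(means)
  expect_true(all(diff(avg) > 0))
})

test_that("schema mismatches are rejected before sampling", {
  s <- small_sim(n = 100, seed = 3)
  spec <- geoadd_spec(s$graph)
  d <- s$data
  d$zone <- NULL
  expect_error(run_chain(d, spec, mcmc_config(300, 100, 1, seed = 1)), "zone")
  d2 <- s$data
  d2$zone[1] <- "nowhere"
  expect_error(run_chain(d2, spec, mcmc_config(300, 100, 1, seed = 1)),
               "nowhere")
  expect_error(model_spec(fixed = "age", smooth = "age"), "both")
  expect_error(mcmc_config(iterations = 100, burn_in = 90, thin = 10),
               "retained")
})
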