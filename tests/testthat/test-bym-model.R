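test_that("Poisson log-likelihood matches closed forms", {
  expect_equal(poisson_loglik(0, 1, 0), -1)
  expect_equal(poisson_loglik(1, 1, 0), -1)  # log(1 * e^-1)
  # limit: eta -> -Inf with Y = 0 gives loglik -> 0
  expect_equal(poisson_loglik(0, 1, -50), -exp(-50) * 1, tolerance = 1e-12)
  # agrees with dpois at arbitrary values
  y <- c(0, 3, 7)
  E <- c(0.5, 2, 4)
  eta <- c(-0.2, 0.1, 0.4)
  expect_equal(poisson_loglik(y, E, eta),
               sum(dpois(y, E * exp(eta), log = TRUE)))
  expect_error(poisson_loglik(c(1.5), 1, 0), "integer")
  expect_error(poisson_loglik(c(-1), 1, 0), "integer")
})

test_that("linear predictor composes coefficients and random effects", {
  d <- data.frame(exposure = c(1, 2), z1 = c(3, 3))
  expect_equal(linear_predictor(list(), d), c(0, 0))
  expect_equal(linear_predictor(list(gamma = 2), d, covariates = "z1"),
               c(6, 6))
  p <- list(beta0 = 0.5, beta_x = -1, gamma = 2, phi = c(0.1, -0.1),
            theta = c(0, 0.2))
  expect_equal(linear_predictor(p, d, covariates = "z1"),
               0.5 - 1 * c(1, 2) + 6 + c(0.1, -0.1) + c(0, 0.2))
  # internal consistency: exp(eta) * E is the Poisson mean of the likelihood
  eta <- linear_predictor(p, d, covariates = "z1")
  E <- c(2, 3)
  y <- c(1, 4)
  expect_equal(poisson_loglik(y, E, eta),
               sum(dpois(y, E * exp(eta), log = TRUE)))
})

test_that("fit_bym is deterministic given the spec seed", {
  st <- generate_study(quick_cfg(n_areas = 36, seed = 2), seed = 2)
  sp <- bym_spec(iterations = 150, burn_in = 50, seed = 9,
                 covariates = c("z_urban", "z_income"))
  f1 <- fit_bym(st$areas, st$graph, sp)
  f2 <- fit_bym(st$areas, st$graph, sp)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$random_effects, f2$random_effects)
  f3 <- fit_bym(st$areas, st$graph,
                bym_spec(iterations = 150, burn_in = 50, seed = 10,
                         covariates = c("z_urban", "z_income")))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("structured effect sums to zero per component at every saved draw", {
  st <- generate_study(quick_cfg(n_areas = 30, seed = 3), seed = 3)
  # add an island by dropping its edges
  keep <- !(st$graph$edges[, 1] == 1L | st$graph$edges[, 2] == 1L)
  g <- build_graph(cbind(st$graph$ids[st$graph$edges[keep, 1]],
                         st$graph$ids[st$graph$edges[keep, 2]]),
                   st$graph$ids)
  f <- fit_bym(st$areas, g, bym_spec(iterations = 200, burn_in = 100,
                                     seed = 4))
  phi <- f$random_effects$phi
  for (cc in unique(g$component[!g$isolated])) {
    idx <- g$component == cc & !g$isolated
    expect_lt(max(abs(rowSums(phi[, idx, drop = FALSE]))), 1e-10)
  }
  # islands carry no structured effect
  expect_true(all(phi[, g$isolated] == 0))
  # recorded acceptance rates are proper probabilities
  expect_true(all(f$meta$acceptance$beta > 0 & f$meta$acceptance$beta < 1))
  expect_gt(f$meta$acceptance$phi, 0)
  expect_lt(f$meta$acceptance$phi, 1)
})

test_that("Gaussian hook: coefficient posterior matches conjugate closed form", {
  set.seed(11)
  n <- 80
  x <- runif(n, 0, 3)
  beta_true <- c(0.4, -0.6)
  sdy <- 0.7
  y <- beta_true[1] + beta_true[2] * x + rnorm(n, 0, sdy)
  d <- data.frame(area_id = sprintf("a%03d", 1:n), y_late = y,
                  expected = rep(1, n), exposure = x)
  g <- generate_graph(quick_cfg(n_areas = n, seed = 1), seed = 1)
  sp <- bym_spec(iterations = 24000, burn_in = 2000, seed = 5,
                 likelihood = "gaussian", gaussian_sd = sdy,
                 include_structured = FALSE, include_unstructured = FALSE,
                 prior_sd = 10, save_random_effects = FALSE)
  f <- fit_bym(d, g, sp)

  X <- cbind(1, x)
  P <- crossprod(X) / sdy^2 + diag(2) / 100
  m <- solve(P, crossprod(X, y) / sdy^2)
  post_sd <- sqrt(diag(solve(P)))
  for (k in 1:2) {
    ch <- f$draws[, k]
    mcse <- 3 * nabym:::mcse_mean(ch)
    expect_lt(abs(mean(ch) - m[k]), max(2 * mcse, 0.02 * post_sd[k] + mcse))
    expect_lt(abs(sd(ch) - post_sd[k]), 0.15 * post_sd[k])
  }
})

test_that("null exposure effect is recovered within posterior uncertainty", {
  cfg <- quick_cfg(n_areas = 64, seed = 6, beta_x = 0, delta = 0,
                   gamma = numeric(0))
  st <- generate_study(cfg, seed = 6)
  f <- fit_bym(st$areas, st$graph,
               bym_spec(iterations = 2500, burn_in = 500, seed = 7,
                        save_random_effects = FALSE))
  ch <- f$draws[, "beta_x"]
  expect_lt(abs(mean(ch)), 3 * sd(ch))
})

test_that("posterior for the exposure effect contracts as areas quadruple", {
  sds <- sapply(c(60, 240), function(n) {
    mean(sapply(c(13, 14), function(s) {
      cfg <- quick_cfg(n_areas = n, seed = s, delta = 0, sigma_u = 0.05,
                       gamma = numeric(0))
      st <- generate_study(cfg, seed = s)
      f <- fit_bym(st$areas, st$graph,
                   bym_spec(iterations = 2500, burn_in = 500, seed = s + 1,
                            save_random_effects = FALSE))
      sd(f$draws[, "beta_x"])
    }))
  })
  expect_lt(sds[2], sds[1])
})

test_that("sampler kernel preserves the joint prior-data law (Geweke check)", {
  # marginal-conditional vs successive-conditional moments of beta_x under a
  # tame prior; unstructured-effect-only model on a 20-area lattice
  n <- 20
  g <- generate_graph(quick_cfg(n_areas = n, seed = 21), seed = 21)
  set.seed(77)
  x <- runif(n, 0, 2)
  E <- rep(5, n)
  prior_sd <- 0.4
  vp <- c(shape = 3, rate = 0.5)   # finite-variance IG for the check
  draw_y <- function(state) {
    eta <- state$beta[1] + state$beta[2] * x + state$theta
    rpois(n, E * exp(eta))
  }
  n_cycle <- 4000
  set.seed(101)
  state <- list(beta = rnorm(2, 0, prior_sd),
                sigma2_theta = 1 / rgamma(1, vp[1], rate = vp[2]))
  state$theta <- rnorm(n, 0, sqrt(state$sigma2_theta))
  chain <- numeric(n_cycle)
  for (t in seq_len(n_cycle)) {
    y <- draw_y(state)
    d <- data.frame(area_id = g$ids, y_late = y, expected = E, exposure = x)
    sp <- bym_spec(iterations = 1, burn_in = 0, seed = 1000 + t,
                   prior_sd = prior_sd, variance_prior = vp,
                   include_structured = FALSE,
                   save_random_effects = FALSE)
    f <- fit_bym(d, g, sp, init = state)
    state <- list(beta = f$state$beta, theta = f$state$theta,
                  sigma2_theta = f$state$sigma2_theta)
    chain[t] <- f$state$beta[2]
  }
  # prior moments of beta_x: mean 0, var prior_sd^2; the successive chain is
  # strongly autocorrelated, so standard errors use wide batches
  wide_se <- function(x, n_batch = 20) {
    b <- length(x) %/% n_batch
    bm <- colMeans(matrix(x[seq_len(b * n_batch)], nrow = b))
    sd(bm) / sqrt(n_batch)
  }
  expect_lt(abs(mean(chain)), 3 * wide_se(chain))
  expect_lt(abs(mean(chain^2) - prior_sd^2), 3 * wide_se(chain^2))
})

test_that("mismatched orderings and bad inputs are rejected", {
  st <- generate_study(quick_cfg(n_areas = 16, seed = 1), seed = 1)
  d <- st$areas
  d$area_id <- rev(d$area_id)
  expect_error(fit_bym(d, st$graph, bym_spec(iterations = 10, burn_in = 0)),
               "ordering")
  d2 <- st$areas
  d2$expected[1] <- 0
  expect_error(fit_bym(d2, st$graph, bym_spec(iterations = 10, burn_in = 0)),
               "expected")
  expect_error(bym_spec(iterations = 0), "positive")
  expect_error(bym_spec(prior_sd = 0), "prior_sd")
})
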