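test_that("confounder conditional law follows the smoothed-exposure coupling", {
  g <- path3()
  sp <- na_spec(smoother_order = 1)
  # delta = 0: mean-zero GMRF independent of X
  law0 <- joint_exposure_confounder_model(c(1, 5, 2), g, sp, delta = 0)
  expect_equal(law0$mean, rep(0, 3))
  # constant exposure: smoother preserves constants
  lawc <- joint_exposure_confounder_model(rep(2, 3), g, sp, delta = 0.5)
  expect_equal(lawc$mean, rep(1, 3))
  # hand-computed smoother action on the path
  law <- joint_exposure_confounder_model(c(0, 3, 0), g, sp, delta = 1)
  expect_equal(law$mean, c(3, 0, 3))
  # precision is the proper CAR scaled by 1/sigma2_u
  expect_equal(as.matrix(law$precision),
               as.matrix(proper_car_precision(g, 1, sp$alpha_u)$Q))
  expect_error(na_spec(u_car_variant = "icar"), "proper")
})

test_that("confounder imputation is seed-reproducible and prior-dominated at high precision", {
  st <- generate_study(quick_cfg(n_areas = 36, seed = 5), seed = 5)
  g <- st$graph
  n <- g$n_areas
  y <- st$areas$y_late
  E <- st$areas$expected
  Q1 <- proper_car_precision(g, 10, 0.5)$Q
  set.seed(1)
  a <- impute_confounder(y, E, numeric(n), numeric(n), Q1, numeric(n))
  set.seed(1)
  b <- impute_confounder(y, E, numeric(n), numeric(n), Q1, numeric(n))
  expect_identical(a$U, b$U)

  # with eta fitting Y perfectly in expectation and delta = 0, |U| shrinks as
  # the prior precision grows
  eta_fit <- log(pmax(y, 0.5) / E)
  mean_abs <- sapply(c(1, 100, 10000), function(tau) {
    Q <- proper_car_precision(g, tau, 0.5)$Q
    U <- numeric(n)
    set.seed(3)
    for (k in 1:50) U <- impute_confounder(y, E, U, numeric(n), Q, eta_fit)$U
    mean(abs(U))
  })
  expect_true(all(diff(mean_abs) < 0))
  expect_lt(mean_abs[3], 0.02)
})

test_that("Gaussian hook: confounder full conditional matches the linear-Gaussian posterior", {
  g <- generate_graph(quick_cfg(n_areas = 25, seed = 8), seed = 8)
  n <- g$n_areas
  set.seed(12)
  mu <- rnorm(n, 0, 0.3)
  Qu <- proper_car_precision(g, 4, 0.6)$Q
  sdy <- 0.5
  eta_rest <- rnorm(n, 0, 0.2)
  y <- eta_rest + mu + rnorm(n, 0, sdy)
  # closed form: precision Qu + I/sd^2, mean P^-1 (Qu mu + (y - eta)/sd^2)
  P <- as.matrix(Qu) + diag(n) / sdy^2
  m <- solve(P, as.numeric(Qu %*% mu) + (y - eta_rest) / sdy^2)
  V <- solve(P)

  # block route: exact Gaussian draw
  set.seed(31)
  blocks <- replicate(4000, impute_confounder(
    y, rep(1, n), numeric(n), mu, Qu, eta_rest,
    likelihood = "gaussian", gaussian_sd = sdy, method = "block")$U)
  expect_lt(max(abs(rowMeans(blocks) - m)), 4 * sqrt(max(diag(V)) / 4000) + 1e-8)
  expect_lt(max(abs(apply(blocks, 1, var) - diag(V))), 0.15 * max(diag(V)))

  # site route: Markov chain whose stationary law is the same posterior
  U <- numeric(n)
  set.seed(32)
  sums <- numeric(n)
  sums2 <- numeric(n)
  n_sweep <- 6000
  for (k in seq_len(n_sweep)) {
    U <- impute_confounder(y, rep(1, n), U, mu, Qu, eta_rest,
                           likelihood = "gaussian", gaussian_sd = sdy,
                           method = "site")$U
    if (k > 500) {
      sums <- sums + U
      sums2 <- sums2 + U^2
    }
  }
  kept <- n_sweep - 500
  expect_lt(max(abs(sums / kept - m)), 0.05)
  expect_lt(max(abs(sums2 / kept - (sums / kept)^2 - diag(V))),
            0.25 * max(diag(V)))
})

test_that("with the confounder machinery pinned off the NA posterior collapses to the unadjusted fit", {
  # the no-confounding limit: delta pinned at ~0 and the confounder variance
  # pinned near zero make the NA sampler target the plain Poisson posterior;
  # a free delta / free U variance always add ridge width, so the exact
  # distributional coincidence is a property of this pinned limit
  cfg <- quick_cfg(n_areas = 50, seed = 9, delta = 0, sigma_u = 0,
                   gamma = numeric(0), pop_meanlog = log(50000))
  st <- generate_study(cfg, seed = 9)
  # centre the exposure so intercept and slope decorrelate: the random-walk
  # chains then mix fast enough that the effective sample supports the KS bound
  st$areas$exposure <- st$areas$exposure - mean(st$areas$exposure)
  fn <- fit_na(st$areas, st$graph,
               na_spec(iterations = 40000, burn_in = 1000, seed = 2,
                       delta_prior_sd = 1e-6,
                       variance_prior = c(shape = 1e8, rate = 100),
                       save_random_effects = FALSE))
  fp <- fit_bym(st$areas, st$graph,
                bym_spec(iterations = 40000, burn_in = 1000, seed = 3,
                         include_structured = FALSE,
                         include_unstructured = FALSE,
                         save_random_effects = FALSE))
  expect_lt(ks_distance(fn$draws[, "beta_x"], fp$draws[, "beta_x"]), 0.05)
  # and at delta = 0 truth with a free coupling, the posterior means agree
  fn2 <- fit_na(st$areas, st$graph,
                na_spec(iterations = 6000, burn_in = 1000, seed = 4,
                        save_random_effects = FALSE))
  expect_lt(abs(mean(fn2$draws[, "beta_x"]) - mean(fp$draws[, "beta_x"])),
            3 * sd(fn2$draws[, "beta_x"]))
})

test_that("imputed confounder tracks delta * SX across replicates", {
  ok <- 0L
  for (s in 1:5) {
    cfg <- quick_cfg(n_areas = 60, seed = s)
    st <- generate_study(cfg, seed = s)
    fn <- fit_na(st$areas, st$graph,
                 na_spec(covariates = c("z_urban", "z_income"),
                         iterations = 1200, burn_in = 400, seed = s))
    expect_true(all(is.finite(fn$random_effects$u)))
    u_mean <- colMeans(fn$random_effects$u)
    sx <- fn$meta$smoothed_exposure
    ok <- ok + (cor(u_mean, st$config$delta * sx) > 0)
  }
  expect_equal(ok, 5L)
})

test_that("generator warns when the identification scale assumption is violated", {
  cfg <- quick_cfg(n_areas = 25, seed = 4, alpha_x = 0.3, alpha_u = 0.8,
                   exposure_smooth = 0L)
  expect_warning(generate_study(cfg, seed = 4), "identification")
  expect_error(na_spec(alpha_u = 0.95, alpha_x = 0.5), "identification")
  expect_no_error(na_spec(alpha_u = 0.95, alpha_x = 0.5,
                          enforce_identification = FALSE))
})

test_that("bias gap compares posterior means with a shrinking MC error", {
  st <- generate_study(quick_cfg(n_areas = 25, seed = 2), seed = 2)
  f <- fit_bym(st$areas, st$graph, bym_spec(iterations = 300, burn_in = 100,
                                            seed = 5))
  expect_equal(bias_gap(f, f)$gap, 0)

  # the headline contrast: naive -0.025 vs adjusted -0.037 gives +0.012
  d_bym <- matrix(rep(-0.025, 400), dimnames = list(NULL, "beta_x"))
  d_na <- matrix(rep(-0.037, 400), dimnames = list(NULL, "beta_x"))
  expect_equal(bias_gap(d_bym, d_na)$gap, 0.012)

  # MC-SE halves (within tolerance) when draws quadruple
  set.seed(6)
  x1 <- rnorm(2000)
  x4 <- rnorm(8000)
  r <- nabym:::mcse_mean(x4) / nabym:::mcse_mean(x1)
  expect_lt(abs(r - 0.5), 0.2)
  expect_error(bias_gap(matrix(numeric(0), 0, 1,
                               dimnames = list(NULL, "beta_x")),
                        d_na), "empty")
})

test_that("fit_na is deterministic and purges confounding on average", {
  cfg <- quick_cfg(n_areas = 80, seed = 31)
  st <- generate_study(cfg, seed = 31)
  sp <- na_spec(covariates = c("z_urban", "z_income"),
                iterations = 400, burn_in = 200, seed = 7)
  f1 <- fit_na(st$areas, st$graph, sp)
  f2 <- fit_na(st$areas, st$graph, sp)
  expect_identical(f1$draws, f2$draws)

  # short de-confounding check over 3 replicates: the adjusted estimate sits
  # below the naive one on average under positive coupling
  gaps <- sapply(1:3, function(s) {
    stt <- generate_study(quick_cfg(n_areas = 80, seed = 40 + s), seed = 40 + s)
    gl <- coef(fit_poisson_glm(stt$areas,
                               covariates = c("z_urban", "z_income")))[["exposure"]]
    fn <- fit_na(stt$areas, stt$graph,
                 na_spec(covariates = c("z_urban", "z_income"),
                         iterations = 1500, burn_in = 500, seed = s,
                         save_random_effects = FALSE))
    gl - mean(fn$draws[, "beta_x"])
  })
  expect_gt(mean(gaps), 0)
})
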