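test_that("grid graphs have the lattice edge count and seeds reproduce", {
  cfg <- generator_config(n_areas = 16, graph_type = "grid")
  g <- generate_graph(cfg, seed = 1)
  expect_equal(g$n_areas, 16L)
  expect_equal(nrow(g$edges), 24L)  # 2 * 4 * 3 for a 4x4 lattice
  expect_equal(max(g$component), 1L)

  cfgG <- generator_config(n_areas = 80, graph_type = "gabriel")
  g1 <- generate_graph(cfgG, seed = 7)
  g2 <- generate_graph(cfgG, seed = 7)
  expect_identical(g1$edges, g2$edges)
  expect_false(identical(g1$edges, generate_graph(cfgG, seed = 8)$edges))
  # connected planar-like contiguity with moderate mean degree
  expect_equal(max(g1$component), 1L)
  expect_true(all(g1$degree >= 1L))
  md <- mean(g1$degree)
  expect_gte(md, 3)
  expect_lte(md, 8)
})

test_that("exposure fields are nonnegative with the configured location", {
  cfg <- generator_config(n_areas = 120, graph_type = "grid")
  g <- generate_graph(cfg, seed = 3)
  x <- generate_exposure(g, cfg, seed = 3)
  expect_true(all(x >= 0))
  expect_equal(median(x), 1.4, tolerance = 0.25)

  cfg0 <- generator_config(n_areas = 120, graph_type = "grid",
                           exposure_sd = 0)
  expect_equal(generate_exposure(g, cfg0, seed = 3), rep(1.4, 120))
})

test_that("the full generator chain is a pure function of (config, seed)", {
  cfg <- quick_cfg(n_areas = 40, seed = 5)
  s1 <- generate_study(cfg, seed = 5)
  s2 <- generate_study(cfg, seed = 5)
  expect_identical(s1$areas, s2$areas)
  expect_identical(s1$strata, s2$strata)
  expect_identical(s1$U, s2$U)
  s3 <- generate_study(cfg, seed = 6)
  keep <- setdiff(names(truth_report(s1)), "seed")
  expect_identical(truth_report(s1)[keep], truth_report(s3)[keep])
  expect_false(identical(s1$areas$y_late, s3$areas$y_late))
})

test_that("generated studies satisfy the standardization calibration identity", {
  for (s in 1:3) {
    st <- generate_study(quick_cfg(n_areas = 50, seed = s), seed = s)
    E_int <- expected_counts(st$strata, area_order = st$graph$ids)
    expect_equal(sum(E_int), sum(st$strata$cases), tolerance = 1e-9)
    # emitted per-area counts equal the strata allocation
    expect_equal(as.integer(tapply(st$strata$cases, st$strata$area_id,
                                   sum)[st$graph$ids]),
                 st$areas$y_late)
  }
})

test_that("null generator gives Poisson counts around the expected offsets", {
  cfg <- quick_cfg(n_areas = 400, seed = 11, beta_x = 0, delta = 0,
                   sigma_u = 0, gamma = numeric(0))
  st <- generate_study(cfg, seed = 11)
  rr <- st$areas$y_late / st$areas$expected
  se <- sqrt(1 / mean(st$areas$expected) / nrow(st$areas))
  expect_lt(abs(mean(rr) - 1), 3 * se * 2)
  # dispersion consistent with Poisson: variance of Y about E
  z <- (st$areas$y_late - st$areas$expected) / sqrt(st$areas$expected)
  expect_lt(abs(var(z) - 1), 0.25)
})

test_that("an independent IRLS oracle recovers the generating slope at large n", {
  cfg <- generator_config(n_areas = 5000, graph_type = "grid", seed = 17,
                          delta = 0, sigma_u = 0, gamma = numeric(0))
  st <- generate_study(cfg, seed = 17)
  X <- cbind(1, st$areas$exposure)
  slope <- irls_poisson(X, st$areas$y_late, log(st$areas$expected))[2]
  expect_lt(abs(slope - (-0.03)), 0.01)
})

test_that("default-scale draws respect the stated magnitude and scale ordering", {
  S_ratio <- numeric(0)
  for (s in 1:10) {
    cfg <- generator_config(seed = s)   # full default: 356 areas, gabriel
    st <- generate_study(cfg, seed = s)
    expect_gte(sum(st$areas$y_late), 0.5 * sum(st$areas$expected))
    expect_lte(sum(st$areas$y_late), 2.0 * sum(st$areas$expected))
    S <- neighbourhood_smoother(st$graph, 1)
    unoise <- st$U - st$config$delta * as.numeric(S %*% st$exposure)
    S_ratio <- c(S_ratio, morans_i(st$exposure, st$graph) -
                   morans_i(unoise, st$graph))
  }
  # exposure autocorrelation exceeds the confounder noise's on every draw
  expect_true(all(S_ratio > 0))
})

test_that("truth stays out of the observed files and round-trips as JSON", {
  st <- generate_study(quick_cfg(n_areas = 30, seed = 21), seed = 21)
  dir <- tempfile()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c("areas.csv", "strata.csv",
                                               "edges.txt", "truth.json")))))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(tr$beta_x, truth_report(st)$beta_x)
  expect_equal(tr$delta, truth_report(st)$delta)

  loaded <- load_study(dir)
  expect_identical(as.matrix(loaded$graph$W), as.matrix(st$graph$W))
  expect_equal(loaded$areas$y_late, st$areas$y_late)
  expect_error(truth_report(loaded), "truth unknown")
})

test_that("overflow guard rejects explosive configurations", {
  cfg <- quick_cfg(n_areas = 16, seed = 1, beta0 = 15)
  expect_error(generate_study(cfg, seed = 1), "1e6")
})

test_that("simulated stage tables split near the configured late share", {
  st <- generate_study(quick_cfg(n_areas = 200, seed = 13), seed = 13)
  tab <- simulate_stage_table(st, seed = 13)
  sp <- stage_proportions(tab)
  expect_equal(sp$late_pct[sp$group == "total"], 78.5, tolerance = 1.5)
  expect_true(all(tab$early + tab$late == sp$total))
})
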