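# Small graphs, tables and independent oracles shared across the test files.

path3 <- function() {
  build_graph(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
}

cycle4 <- function() {
  build_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")),
              c("a", "b", "c", "d"))
}

pair_graph <- function() {
  build_graph(rbind(c("a", "b")), c("a", "b"))
}

# a 2x2-table strata fixture with hand-computable rates
tiny_strata <- function() {
  data.frame(area_id = rep(c("x", "y"), each = 2),
             stratum = rep(c("F0_74", "F75p"), 2),
             population = c(100, 50, 300, 150),
             cases = c(1, 1, 3, 3),
             stringsAsFactors = FALSE)
}

# random valid strata tables for property checks
random_strata <- function(n_areas, seed) {
  set.seed(seed)
  ids <- sprintf("a%02d", seq_len(n_areas))
  strata <- expand.grid(area_id = ids, stratum = STRATUM_LEVELS,
                        stringsAsFactors = FALSE)
  strata$population <- round(runif(nrow(strata), 50, 5000))
  strata$cases <- rpois(nrow(strata), strata$population * 0.01)
  strata
}

quick_cfg <- function(n_areas = 60, seed = 1, ...) {
  generator_config(n_areas = n_areas, graph_type = "grid", seed = seed, ...)
}

# Independent quasi-Poisson oracle: iteratively reweighted least squares,
# written without glm() so generator recovery is checked against a second
# route.
irls_poisson <- function(X, y, offset, tol = 1e-10, maxit = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- offset + as.numeric(X %*% beta)
    mu <- exp(eta)
    z <- (eta - offset) + (y - mu) / mu
    WX <- X * mu
    beta_new <- solve(crossprod(X, WX), crossprod(WX, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Kolmogorov-Smirnov distance between two samples (no p-value machinery).
ks_distance <- function(a, b) {
  all_v <- sort(c(a, b))
  Fa <- ecdf(a)(all_v)
  Fb <- ecdf(b)(all_v)
  max(abs(Fa - Fb))
}
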