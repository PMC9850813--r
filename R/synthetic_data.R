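# Fully synthetic municipality studies with the statistical structure the
# analysis assumes: a contiguity graph, a spatially smooth exposure field, a
# shorter-range latent confounder coupled to the exposure, four age-sex
# strata, and Poisson late-stage counts against indirectly standardized
# expected counts. The generating truth is carried separately from the
# "observed" tables so pipelines cannot peek.

#' Configuration of the synthetic study generator
#'
#' Defaults emulate a Norway-like municipality study: 356 areas, physician
#' density around a median of 1.4 per 10,000 with long-range spatial
#' structure, a shorter-range confounder positively coupled to exposure, and
#' late-stage count magnitudes (tens of cases per median-population area over
#' a pooled multi-year period).
#'
#' @param n_areas Number of areas (default 356).
#' @param graph_type `"gabriel"` (Gabriel graph on random points — a
#'   random-planar contiguity stand-in), `"grid"` (near-square lattice), or
#'   `"edges"` (use `edge_list`).
#' @param edge_list Two-column edge list when `graph_type = "edges"`.
#' @param exposure_mean,exposure_sd Location/scale of the exposure field on
#'   the per-10,000 scale (defaults 1.4 / 0.5); the field is truncated at 0.
#' @param alpha_x Proper-CAR range of the smooth (regional) exposure
#'   component in `[0, 1)`.
#' @param exposure_smooth Extra smoothing passes applied to the smooth
#'   exposure component to enforce its larger spatial scale.
#' @param local_mix Variance share of an iid area-local exposure component
#'   (urban-centre spikes) mixed with the smooth regional component; the
#'   local variation is what separates the exposure effect from the latent
#'   confounder, whose conditional mean tracks only the smoothed exposure.
#' @param delta Exposure-confounder coupling (confounding strength).
#' @param alpha_u Proper-CAR range of the confounder noise (must not exceed
#'   `alpha_x` for the identification assumption to hold by construction).
#' @param sigma_u Marginal SD of the confounder noise field.
#' @param coupling_order Smoother order in the coupling \eqn{\delta S^k X}.
#' @param beta0,beta_x True intercept and exposure effect (log scale).
#' @param gamma Named vector of true covariate effects; covariates with these
#'   names are generated as iid standard normals.
#' @param pop_meanlog,pop_sdlog Log-normal parameters of area populations.
#' @param strata_shares Shares of the four age-sex strata (must sum to 1).
#' @param rates Baseline late-stage rates per stratum (pooled study period).
#' @param late_share Late-stage share used when simulating an early/late
#'   stage table (cosmetic companion, default 0.785).
#' @param seed Default seed for [generate_study()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_areas = 356L,
                             graph_type = c("gabriel", "grid", "edges"),
                             edge_list = NULL,
                             exposure_mean = 1.4, exposure_sd = 0.5,
                             alpha_x = 0.95, exposure_smooth = 2L,
                             local_mix = 0.5,
                             delta = 0.15, alpha_u = 0.7, sigma_u = 0.15,
                             coupling_order = 1L,
                             beta0 = 0, beta_x = -0.03,
                             gamma = c(z_urban = 0.05, z_income = -0.05),
                             pop_meanlog = log(5200), pop_sdlog = 1,
                             strata_shares = c(F0_74 = 0.38, F75p = 0.12,
                                               M0_74 = 0.38, M75p = 0.12),
                             rates = c(F0_74 = 0.002, F75p = 0.02,
                                       M0_74 = 0.002, M75p = 0.022),
                             late_share = 0.785,
                             seed = 1L) {
  graph_type <- match.arg(graph_type)
  if (n_areas < 4L) stop("`n_areas` must be at least 4")
  if (exposure_sd < 0 || sigma_u < 0) stop("scales must be >= 0")
  if (alpha_x < 0 || alpha_x >= 1 || alpha_u < 0 || alpha_u >= 1) {
    stop("CAR range parameters must lie in [0, 1)")
  }
  if (local_mix < 0 || local_mix > 1) stop("`local_mix` must lie in [0, 1]")
  if (abs(sum(strata_shares) - 1) > 1e-8) {
    stop("`strata_shares` must sum to 1")
  }
  if (!identical(sort(names(strata_shares)), sort(names(rates)))) {
    stop("`strata_shares` and `rates` must cover the same strata")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic contiguity graph
#'
#' @param config A [generator_config()].
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return An `area_graph` with ids `"a001"`, `"a002"`, ...
#' @export
generate_graph <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(config$n_areas)
  ids <- sprintf("a%03d", seq_len(n))
  edges <- switch(config$graph_type,
    grid = grid_edges(n),
    gabriel = gabriel_edges(cbind(runif(n), runif(n))),
    edges = {
      if (is.null(config$edge_list)) {
        stop("graph_type \"edges\" requires `edge_list` in the config")
      }
      return(build_graph(config$edge_list, ids))
    })
  build_graph(cbind(ids[edges[, 1]], ids[edges[, 2]]), ids)
}

# Near-square lattice over the first n nodes in row-major order.
grid_edges <- function(n) {
  rows <- floor(sqrt(n))
  cols <- ceiling(n / rows)
  idx <- function(r, c) (r - 1L) * cols + c
  from <- integer(0)
  to <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      v <- idx(r, c)
      if (v > n) next
      if (c < cols && idx(r, c + 1L) <= n) {
        from <- c(from, v); to <- c(to, idx(r, c + 1L))
      }
      if (r < rows && idx(r + 1L, c) <= n) {
        from <- c(from, v); to <- c(to, idx(r + 1L, c))
      }
    }
  }
  cbind(from, to)
}

# Gabriel graph: (i, j) is an edge iff no third point lies strictly inside
# the circle with diameter ij. Connected (it contains the Euclidean MST) and
# planar, with mean degree around 4 — a reasonable municipality stand-in.
gabriel_edges <- function(pts) {
  n <- nrow(pts)
  D2 <- as.matrix(stats::dist(pts))^2
  from <- integer(0)
  to <- integer(0)
  for (i in seq_len(n - 1L)) {
    C <- D2[i, ] + D2          # C[k, j] = d2(i,k) + d2(k,j)
    cols <- (i + 1L):n
    m <- apply(C[, cols, drop = FALSE], 2, min)
    ok <- m >= D2[i, cols] * (1 - 1e-12)
    if (any(ok)) {
      from <- c(from, rep.int(i, sum(ok)))
      to <- c(to, cols[ok])
    }
  }
  cbind(from, to)
}

#' Generate the two-scale exposure field
#'
#' Physician-density-like exposure with two variance components: a smooth
#' regional gradient (proper-CAR field at range `alpha_x`, smoothed
#' `exposure_smooth` extra passes — the component whose spatial scale
#' dominates the confounder's) and an iid area-local component with variance
#' share `local_mix` (urban-centre spikes). The mixture is rescaled to the
#' configured mean/SD on the per-10,000 scale and truncated at zero.
#'
#' @param graph An `area_graph`.
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return Nonnegative exposure vector.
#' @export
generate_exposure <- function(graph, config, seed = NULL) {
  stopifnot(inherits(graph, "area_graph"),
            inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- graph$n_areas
  if (config$exposure_sd == 0) {
    return(rep(max(config$exposure_mean, 0), n))
  }
  smooth <- sample_gmrf(proper_car_precision(graph, 1, config$alpha_x))
  if (config$exposure_smooth >= 1L) {
    S <- neighbourhood_smoother(graph, 1L)
    for (k in seq_len(config$exposure_smooth)) {
      smooth <- as.numeric(S %*% smooth)
    }
  }
  smooth <- (smooth - mean(smooth)) / stats::sd(smooth)
  raw <- sqrt(1 - config$local_mix) * smooth +
    sqrt(config$local_mix) * rnorm(n)
  x <- config$exposure_mean +
    config$exposure_sd * (raw - mean(raw)) / stats::sd(raw)
  pmax(x, 0)
}

# Area populations split into the four strata by fixed national shares.
generate_strata_populations <- function(n, ids, config) {
  total <- rlnorm(n, config$pop_meanlog, config$pop_sdlog)
  shares <- config$strata_shares
  strata <- names(shares)
  data.frame(
    area_id = rep(ids, each = length(strata)),
    stratum = rep(strata, times = n),
    population = as.numeric(round(rep(total, each = length(strata)) *
                                    rep(unname(shares), times = n))),
    cases = 0L,
    stringsAsFactors = FALSE)
}

#' Generate the confounded outcome given a graph and exposure
#'
#' Draws the latent confounder \eqn{U = \delta S X + } proper-CAR noise,
#' computes expected counts by indirect standardization of the configured
#' stratum rates, and draws
#' \eqn{Y_i \sim \mathrm{Poisson}(E_i \exp(\beta_0 + \beta_X X_i + \gamma^T
#' Z_i + U_i))}. Stratum-level case counts are allocated from \eqn{Y_i}
#' proportionally to stratum expected counts, so internal re-standardization
#' of the emitted strata table satisfies the calibration identity.
#'
#' @param graph An `area_graph`.
#' @param X Exposure vector.
#' @param strata Strata table with populations filled in (cases overwritten).
#' @param config A [generator_config()].
#' @param seed Optional seed.
#' @return A `synthetic_study` object.
#' @export
generate_confounded_outcome <- function(graph, X, strata, config,
                                        seed = NULL) {
  stopifnot(inherits(graph, "area_graph"),
            inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- graph$n_areas
  ids <- graph$ids
  if (config$alpha_u > config$alpha_x) {
    warning("generator violates the identification assumption: confounder ",
            "range alpha_u (", config$alpha_u, ") exceeds exposure range ",
            "alpha_x (", config$alpha_x, "); recovery by the ",
            "neighbourhood-adjustment model is expected to degrade")
  }

  S <- neighbourhood_smoother(graph, config$coupling_order)
  SX <- as.numeric(S %*% X)
  if (config$sigma_u > 0) {
    noise <- sample_gmrf(proper_car_precision(graph, 1, config$alpha_u))
    noise <- noise / stats::sd(noise) * config$sigma_u
  } else {
    noise <- numeric(n)
  }
  U <- config$delta * SX + noise

  gamma <- config$gamma
  Z <- if (length(gamma)) {
    zm <- matrix(rnorm(n * length(gamma)), n,
                 dimnames = list(NULL, names(gamma)))
    zm
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }

  E <- expected_counts(strata, rates = config$rates, area_order = ids)
  eta <- config$beta0 + config$beta_x * X +
    (if (ncol(Z)) as.numeric(Z %*% gamma) else 0) + U
  mu <- E * exp(eta)
  if (any(mu > 1e6)) {
    stop("configuration produces mean counts above 1e6; ",
         "check rates/effect sizes (overflow guard)")
  }
  Y <- rpois(n, mu)

  # Allocate each area's cases to strata in proportion to stratum expected
  # counts, so the emitted strata table is internally consistent.
  rate_vec <- config$rates[as.character(strata$stratum)]
  contrib <- strata$population * rate_vec
  strata$cases <- 0L
  row_index <- split(seq_len(nrow(strata)), strata$area_id)[ids]
  for (i in seq_len(n)) {
    rows <- row_index[[i]]
    pr <- contrib[rows]
    if (sum(pr) <= 0 || Y[i] == 0) next
    strata$cases[rows] <- as.integer(stats::rmultinom(1, Y[i], pr / sum(pr)))
  }

  areas <- data.frame(area_id = ids, y_late = as.integer(Y),
                      expected = as.numeric(E), exposure = X,
                      stringsAsFactors = FALSE)
  if (ncol(Z)) areas <- cbind(areas, as.data.frame(Z))

  truth <- list(beta0 = config$beta0, beta_x = config$beta_x,
                gamma = as.list(config$gamma), delta = config$delta,
                sigma_u = config$sigma_u, alpha_u = config$alpha_u,
                alpha_x = config$alpha_x,
                exposure_smooth = config$exposure_smooth,
                coupling_order = config$coupling_order,
                seed = config$seed)
  structure(list(graph = graph, strata = strata, areas = areas,
                 exposure = X, U = U, truth = truth, config = config),
            class = "synthetic_study")
}

#' Generate a complete synthetic municipality study
#'
#' Runs the whole generator chain — graph, exposure field, strata
#' populations, confounded Poisson outcome — under a single seed, so the
#' study is a pure function of `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (default taken from the config).
#' @return A `synthetic_study`.
#' @export
generate_study <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  config$seed <- as.integer(seed)
  graph <- generate_graph(config)
  X <- generate_exposure(graph, config)
  strata <- generate_strata_populations(graph$n_areas, graph$ids, config)
  generate_confounded_outcome(graph, X, strata, config)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic municipality study:", x$graph$n_areas, "areas,",
      sum(x$areas$y_late), "late-stage cases (sum E =",
      round(sum(x$areas$expected), 1), ")\n")
  invisible(x)
}

#' Report the generating truth of a synthetic study
#'
#' @param study A `synthetic_study` produced by this generator.
#' @return The list of true parameters.
#' @export
truth_report <- function(study) {
  if (!inherits(study, "synthetic_study") || is.null(study$truth)) {
    stop("generating truth unknown: study was not produced by this generator")
  }
  study$truth
}

#' Simulate an early/late stage table for a study
#'
#' Cosmetic companion to the outcome generator: given the late-stage counts,
#' draws early-stage counts so the late share matches the configured value in
#' expectation, grouped as total / men / women / 75+.
#'
#' @param study A `synthetic_study`.
#' @param seed Optional seed.
#' @param late_share Late-stage share; defaults to the study config's value
#'   (or its standard default for studies loaded from files).
#' @return A stage table suitable for [stage_proportions()].
#' @export
simulate_stage_table <- function(study, seed = NULL,
                                 late_share = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  st <- study$strata
  ls <- late_share %||%
    (if (!is.null(study$config)) study$config$late_share else 0.785)
  late_by <- function(rows) sum(st$cases[rows])
  men <- grepl("^M", st$stratum)
  old <- grepl("75p$", st$stratum)
  groups <- list(total = seq_len(nrow(st)), men = which(men),
                 women = which(!men), older_75p = which(old))
  late <- vapply(groups, late_by, numeric(1))
  early <- rpois(length(late), late * (1 - ls) / ls)
  data.frame(group = names(groups), early = as.integer(early),
             late = as.integer(late), row.names = NULL)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `areas.csv`, `strata.csv`, `edges.txt` (the observed study) and
#' `truth.json` (the generating truth, kept in a separate file precisely so
#' analysis pipelines consume only the observed tables).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$areas, file.path(dir, "areas.csv"), row.names = FALSE)
  write.csv(study$strata, file.path(dir, "strata.csv"), row.names = FALSE)
  write_edge_list(study$graph, file.path(dir, "edges.txt"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a study from its observed plain-text files
#'
#' Reads the observed tables written by [write_study()]; the generating truth
#' is deliberately not loaded, so [truth_report()] errors on the result.
#'
#' @param dir Directory containing `areas.csv`, `strata.csv`, `edges.txt`.
#' @return A list with `graph`, `areas`, `strata` (class `synthetic_study`
#'   with `truth = NULL`).
#' @export
load_study <- function(dir) {
  areas <- read_area_table(file.path(dir, "areas.csv"))
  strata <- read_strata_table(file.path(dir, "strata.csv"))
  edges <- read_edge_list(file.path(dir, "edges.txt"))
  graph <- build_graph(edges, areas$area_id)
  structure(list(graph = graph, strata = strata, areas = areas,
                 exposure = areas$exposure, U = NULL, truth = NULL,
                 config = NULL),
            class = "synthetic_study")
}
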