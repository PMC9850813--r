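# The Besag-York-Mollie (BYM) disease-mapping model:
#   Y_i ~ Poisson(E_i exp(eta_i)),
#   eta_i = beta0 + beta_x X_i + gamma' Z_i + phi_i + theta_i,
# with phi an intrinsic-CAR structured effect (smoothing towards neighbours,
# sum-to-zero per connected component) and theta iid N(0, sigma_theta^2)
# (smoothing towards the overall mean). Fit by Metropolis-within-Gibbs.

#' Specification for the BYM sampler
#'
#' Collects the model and sampler settings: exposure/covariate columns,
#' iteration counts (defaults 10,000 kept draws after 1,000 burn-in),
#' Gaussian coefficient priors with mean 0 and standard deviation 10, and
#' inverse-gamma variance hyperpriors. A Gaussian-likelihood test hook
#' (`likelihood = "gaussian"`) replaces the Poisson likelihood with
#' \eqn{Y_i \sim N(\eta_i, \sigma^2)} so sampler conditionals can be checked
#' against closed-form conjugate posteriors.
#'
#' @param exposure Name of the exposure column in the area table.
#' @param covariates Character vector of covariate column names (may be empty).
#' @param iterations Total MCMC iterations after burn-in (saved draws).
#' @param burn_in Burn-in iterations (adaptation happens only here).
#' @param seed Integer RNG seed; the fit is a pure function of
#'   (data, graph, spec).
#' @param prior_sd Prior standard deviation for all regression coefficients.
#' @param variance_prior Length-2 vector `c(shape, rate)` of the inverse-gamma
#'   prior on the random-effect variances (default `c(1, 0.01)`).
#' @param likelihood `"poisson"` (the model) or `"gaussian"` (test hook).
#' @param gaussian_sd Known error SD for the Gaussian hook.
#' @param include_structured,include_unstructured Toggle the two BYM random
#'   effects (both `TRUE` for the full model; both `FALSE` gives a plain
#'   Bayesian Poisson regression).
#' @param save_random_effects Keep per-iteration random-effect vectors.
#' @return An object of class `bym_spec`.
#' @export
bym_spec <- function(exposure = "exposure", covariates = character(),
                     iterations = 10000L, burn_in = 1000L, seed = 1L,
                     prior_sd = 10, variance_prior = c(shape = 1, rate = 0.01),
                     likelihood = c("poisson", "gaussian"), gaussian_sd = 1,
                     include_structured = TRUE, include_unstructured = TRUE,
                     save_random_effects = TRUE) {
  likelihood <- match.arg(likelihood)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (burn_in < 0L) stop("`burn_in` must be >= 0")
  if (iterations <= 0L) stop("`iterations` must be positive")
  if (prior_sd <= 0) stop("`prior_sd` must be > 0")
  if (length(variance_prior) != 2L || any(variance_prior <= 0)) {
    stop("`variance_prior` must be positive c(shape, rate)")
  }
  structure(list(exposure = exposure, covariates = as.character(covariates),
                 iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed), prior_sd = prior_sd,
                 variance_prior = c(shape = unname(variance_prior[1]),
                                    rate = unname(variance_prior[2])),
                 likelihood = likelihood, gaussian_sd = gaussian_sd,
                 include_structured = isTRUE(include_structured),
                 include_unstructured = isTRUE(include_unstructured),
                 save_random_effects = isTRUE(save_random_effects)),
            class = "bym_spec")
}

#' Poisson log-likelihood with expected-count offset
#'
#' \eqn{\sum_i [Y_i(\log E_i + \eta_i) - E_i e^{\eta_i} - \log Y_i!]} — the
#' exact log-likelihood of the offset Poisson outcome model, constants
#' included.
#'
#' @param y Nonnegative integer counts.
#' @param expected Expected counts \eqn{E_i > 0}.
#' @param eta Linear predictor (offset excluded).
#' @return Scalar log-likelihood.
#' @examples
#' poisson_loglik(0, 1, 0)  # -1
#' @export
poisson_loglik <- function(y, expected, eta) {
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must contain nonnegative integer counts")
  }
  if (any(expected <= 0)) stop("`expected` must be > 0")
  sum(y * (log(expected) + eta) - expected * exp(eta) - lgamma(y + 1))
}

#' Linear predictor of the disease-mapping models
#'
#' \eqn{\eta_i = \beta_0 + \beta_X X_i + \gamma^T Z_i + \phi_i + \theta_i}
#' (any omitted component defaults to zero).
#'
#' @param params List with elements `beta0`, `beta_x`, optionally `gamma`
#'   (named by covariate column), `phi`, `theta` (or `u`).
#' @param data Area table with the exposure/covariate columns.
#' @param exposure,covariates Column names, as in [bym_spec()].
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(params, data, exposure = "exposure",
                             covariates = character()) {
  n <- nrow(data)
  eta <- rep(params$beta0 %||% 0, n) +
    (params$beta_x %||% 0) * as.numeric(data[[exposure]])
  if (length(covariates)) {
    gamma <- params$gamma %||% numeric(length(covariates))
    if (length(gamma) != length(covariates)) {
      stop("`gamma` length does not match `covariates`")
    }
    eta <- eta + as.numeric(as.matrix(data[, covariates, drop = FALSE]) %*%
                              gamma)
  }
  for (re in c("phi", "theta", "u")) {
    v <- params[[re]]
    if (!is.null(v)) {
      if (length(v) != n) stop("random effect `", re, "` has wrong length")
      eta <- eta + v
    }
  }
  eta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Re-centre a structured effect to sum to zero within each connected
# component; isolated areas carry no structured effect.
center_by_component <- function(phi, component, isolated) {
  for (cc in unique(component[!isolated])) {
    idx <- component == cc & !isolated
    phi[idx] <- phi[idx] - mean(phi[idx])
  }
  phi[isolated] <- 0
  phi
}

#' Fit the BYM model by Metropolis-within-Gibbs
#'
#' Samples the posterior of the BYM Poisson log-link model with
#' expected-count offset. Regression coefficients are updated by adaptive
#' random-walk Metropolis (one coordinate at a time, adaptation frozen after
#' burn-in), the unstructured effect by single-site Metropolis with its iid
#' normal prior, the structured effect by single-site Metropolis under the
#' intrinsic-CAR full conditional with per-component re-centring each sweep,
#' and the two variances by conjugate inverse-gamma Gibbs draws.
#'
#' @param data Area table (columns `y_late`, `expected`, exposure,
#'   covariates; optional `area_id` checked against the graph ordering).
#' @param graph An [build_graph()] contiguity graph sharing the row ordering.
#' @param spec A [bym_spec()].
#' @param init Optional list of starting values (`beta`, `theta`, `phi`,
#'   `sigma2_theta`, `sigma2_phi`) — used e.g. to chain sampler transitions in
#'   kernel-correctness checks.
#' @return A `posterior_draws` object: `draws` is a matrix with one row per
#'   saved iteration and columns `beta0`, `beta_x`, `gamma_*`,
#'   `sigma2_theta`, `sigma2_phi`; `random_effects` holds `phi`/`theta` draw
#'   matrices; `meta` records the seed and per-block acceptance rates;
#'   `state` is the final sampler state.
#' @export
fit_bym <- function(data, graph, spec = bym_spec(), init = NULL) {
  stopifnot(inherits(graph, "area_graph"), inherits(spec, "bym_spec"))
  mf <- model_frame(data, graph, spec)
  n <- graph$n_areas
  p <- ncol(mf$design)
  lik <- lik_code(spec$likelihood)
  gsd <- spec$gaussian_sd
  csr <- graph_csr(graph)
  Micar <- Matrix::Diagonal(n, graph$degree) - graph$W
  n_noniso <- sum(!graph$isolated)
  n_comp_edge <- length(unique(graph$component[!graph$isolated]))
  ig_a <- spec$variance_prior[["shape"]]
  ig_b <- spec$variance_prior[["rate"]]

  set.seed(spec$seed)
  beta <- init$beta %||% numeric(p)
  theta <- init$theta %||% numeric(n)
  phi <- init$phi %||% numeric(n)
  if (!spec$include_unstructured) theta[] <- 0
  if (!spec$include_structured) phi[] <- 0
  s2t <- init$sigma2_theta %||% 0.1
  s2p <- init$sigma2_phi %||% 0.1
  eta <- as.numeric(mf$design %*% beta) + theta + phi

  step_beta <- rep(0.1, p)
  step_theta <- rep(0.3, n)
  step_phi <- rep(0.3, n)
  batch <- 50L
  acc_beta_batch <- numeric(p)
  acc_theta_batch <- numeric(n)
  acc_phi_batch <- numeric(n)
  acc_beta_tot <- numeric(p)
  acc_theta_tot <- 0
  acc_phi_tot <- 0

  total_iter <- spec$burn_in + spec$iterations
  n_save <- spec$iterations
  par_names <- c(colnames(mf$design), "sigma2_theta", "sigma2_phi")
  draws <- matrix(NA_real_, n_save, length(par_names),
                  dimnames = list(NULL, par_names))
  re_phi <- if (spec$save_random_effects && spec$include_structured) {
    matrix(NA_real_, n_save, n)
  }
  re_theta <- if (spec$save_random_effects && spec$include_unstructured) {
    matrix(NA_real_, n_save, n)
  }

  for (it in seq_len(total_iter)) {
    # -- regression coefficients: single-coordinate random-walk Metropolis
    cur_ll <- data_loglik(mf$y, mf$E, eta, lik, gsd)
    for (k in seq_len(p)) {
      prop <- beta[k] + step_beta[k] * rnorm(1)
      eta_prop <- eta + (prop - beta[k]) * mf$design[, k]
      prop_ll <- data_loglik(mf$y, mf$E, eta_prop, lik, gsd)
      la <- prop_ll - cur_ll - (prop^2 - beta[k]^2) / (2 * spec$prior_sd^2)
      if (is.finite(la) && log(runif(1)) < la) {
        beta[k] <- prop
        eta <- eta_prop
        cur_ll <- prop_ll
        acc_beta_batch[k] <- acc_beta_batch[k] + 1
        if (it > spec$burn_in) acc_beta_tot[k] <- acc_beta_tot[k] + 1
      }
    }

    # -- unstructured effect theta (iid normal prior) + variance
    if (spec$include_unstructured) {
      rest <- eta - theta
      sw <- sweep_iid_re(theta, mf$y, mf$E, rest, s2t, step_theta, lik, gsd)
      theta <- sw$value
      eta <- rest + theta
      acc_theta_batch <- acc_theta_batch + sw$accept
      if (it > spec$burn_in) acc_theta_tot <- acc_theta_tot + mean(sw$accept)
      s2t <- 1 / rgamma(1, shape = ig_a + n / 2,
                        rate = ig_b + sum(theta^2) / 2)
    }

    # -- structured effect phi (ICAR full conditionals) + variance
    if (spec$include_structured) {
      rest <- eta - phi
      sw <- sweep_icar_re(phi, mf$y, mf$E, rest, 1 / s2p,
                          csr$ptr, csr$idx, step_phi, lik, gsd)
      phi <- center_by_component(sw$value, graph$component, graph$isolated)
      eta <- rest + phi
      acc_phi_batch <- acc_phi_batch + sw$accept
      if (it > spec$burn_in) acc_phi_tot <- acc_phi_tot + mean(sw$accept)
      qf <- as.numeric(t(phi) %*% (Micar %*% phi))
      s2p <- 1 / rgamma(1, shape = ig_a + (n_noniso - n_comp_edge) / 2,
                        rate = ig_b + qf / 2)
    }

    if (!is.finite(data_loglik(mf$y, mf$E, eta, lik, gsd))) {
      stop("divergent chain: non-finite log-likelihood at iteration ", it)
    }

    # -- adaptation (burn-in only, every `batch` iterations)
    if (it <= spec$burn_in && it %% batch == 0L) {
      bi <- it %/% batch
      step_beta <- adapt_steps(step_beta, acc_beta_batch, batch, bi)
      step_theta <- adapt_steps(step_theta, acc_theta_batch, batch, bi)
      step_phi <- adapt_steps(step_phi, acc_phi_batch, batch, bi)
      acc_beta_batch[] <- 0
      acc_theta_batch[] <- 0
      acc_phi_batch[] <- 0
    }

    if (it > spec$burn_in) {
      s <- it - spec$burn_in
      draws[s, ] <- c(beta, s2t, s2p)
      if (!is.null(re_phi)) re_phi[s, ] <- phi
      if (!is.null(re_theta)) re_theta[s, ] <- theta
    }
  }

  acc <- list(beta = acc_beta_tot / n_save,
              theta = if (spec$include_unstructured) acc_theta_tot / n_save,
              phi = if (spec$include_structured) acc_phi_tot / n_save)
  new_posterior_draws(
    draws = draws,
    random_effects = list(phi = re_phi, theta = re_theta),
    model = "bym", spec = spec,
    meta = list(seed = spec$seed, iterations = spec$iterations,
                burn_in = spec$burn_in, acceptance = acc),
    state = list(beta = beta, theta = theta, phi = phi,
                 sigma2_theta = s2t, sigma2_phi = s2p))
}

#' Unadjusted Poisson regression comparator
#'
#' Maximum-likelihood Poisson log-link fit with the expected-count offset and
#' no random effects — the "naive" comparator whose exposure coefficient
#' absorbs any spatial confounding bias.
#'
#' @param data Area table.
#' @param exposure,covariates Column names.
#' @return The fitted [stats::glm()] object.
#' @export
fit_poisson_glm <- function(data, exposure = "exposure",
                            covariates = character()) {
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fm <- stats::as.formula(paste("y_late ~", rhs, "+ offset(log(expected))"))
  glm(fm, family = poisson(), data = data)
}
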