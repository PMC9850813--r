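# The neighbourhood-adjustment (NA) model. Outcome:
#   Y_i ~ Poisson(E_i exp(beta0 + beta_x X_i + gamma' Z_i + U_i)),
# where U is an unmeasured spatial confounder handled as missing data. The
# joint law of (X, U) is concretized as a linear-Gaussian coupling through the
# neighbourhood smoother S:
#   U | X ~ N(delta S^order X, Q_U^{-1}),  Q_U proper CAR,
# so the confounding bias functional is B(X) = delta S^order X and U is
# re-imputed from its full conditional every Gibbs sweep. Identification rests
# on the exposure field varying on a spatial scale at least as large as the
# confounder's (long-range X vs short-range CAR noise in U).

#' Specification for the neighbourhood-adjustment sampler
#'
#' Extends [bym_spec()] with the confounder-side settings: the proper-CAR
#' structure of the latent confounder (`alpha_u`), the smoother order of the
#' exposure-confounder coupling, the Gaussian prior SD of the coupling
#' coefficient delta, and the declared exposure spatial range `alpha_x` used
#' to record (and optionally enforce) the identification assumption that the
#' exposure's spatial range is at least the confounder's.
#'
#' @inheritParams bym_spec
#' @param alpha_u Propriety/range parameter of the confounder's proper CAR
#'   prior, in `[0, 1)` (default 0.5; shorter range than typical exposures).
#' @param u_car_variant Must be `"proper"`: the confounder prior has to be a
#'   proper distribution for the imputation to be well defined.
#' @param smoother_order Number of smoothing passes in the coupling
#'   \eqn{\delta S^{order} X} (default 1).
#' @param delta_prior_sd Prior SD of the coupling coefficient delta.
#' @param alpha_x Declared spatial-range parameter of the exposure field (for
#'   the identification record; default 0.9).
#' @param enforce_identification If `TRUE` (default), constructing a spec with
#'   `alpha_u > alpha_x` fails, since the method is not identified when the
#'   confounder is rougher-ranged than the exposure; set `FALSE` to study that
#'   regime deliberately.
#' @param residual_effects If `TRUE`, retain a BYM-style iid residual effect
#'   alongside U (default `FALSE`).
#' @return An object of class `c("na_spec", "bym_spec")`.
#' @export
na_spec <- function(exposure = "exposure", covariates = character(),
                    iterations = 10000L, burn_in = 1000L, seed = 1L,
                    prior_sd = 10, variance_prior = c(shape = 1, rate = 0.01),
                    likelihood = c("poisson", "gaussian"), gaussian_sd = 1,
                    alpha_u = 0.5, u_car_variant = "proper",
                    smoother_order = 1L, delta_prior_sd = 10,
                    alpha_x = 0.9, enforce_identification = TRUE,
                    residual_effects = FALSE, save_random_effects = TRUE) {
  base <- bym_spec(exposure = exposure, covariates = covariates,
                   iterations = iterations, burn_in = burn_in, seed = seed,
                   prior_sd = prior_sd, variance_prior = variance_prior,
                   likelihood = likelihood, gaussian_sd = gaussian_sd,
                   include_structured = FALSE,
                   include_unstructured = isTRUE(residual_effects),
                   save_random_effects = save_random_effects)
  if (!identical(u_car_variant, "proper")) {
    stop("the latent confounder's CAR prior must be proper ",
         "(`u_car_variant = \"proper\"`)")
  }
  if (alpha_u < 0 || alpha_u >= 1) stop("`alpha_u` must lie in [0, 1)")
  if (delta_prior_sd <= 0) stop("`delta_prior_sd` must be > 0")
  if (isTRUE(enforce_identification) && alpha_u > alpha_x) {
    stop("identification assumption violated: confounder range `alpha_u` (",
         alpha_u, ") exceeds exposure range `alpha_x` (", alpha_x, "); ",
         "set `enforce_identification = FALSE` to proceed anyway")
  }
  base$alpha_u <- alpha_u
  base$u_car_variant <- u_car_variant
  base$smoother_order <- as.integer(smoother_order)
  base$delta_prior_sd <- delta_prior_sd
  base$alpha_x <- alpha_x
  base$enforce_identification <- isTRUE(enforce_identification)
  base$residual_effects <- isTRUE(residual_effects)
  class(base) <- c("na_spec", "bym_spec")
  base
}

#' Conditional law of the latent confounder given exposure
#'
#' The joint exposure-confounder model reduced to its working conditional:
#' \eqn{U | X \sim N(\delta S^{order} X, Q_U^{-1})} with \eqn{Q_U} the proper
#' confounder CAR precision. The conditional mean is the confounding bias
#' functional \eqn{B(X)}.
#'
#' @param X Exposure vector over the graph's areas.
#' @param graph An `area_graph`.
#' @param spec An [na_spec()].
#' @param delta Coupling coefficient (current parameter value).
#' @param sigma2_u Confounder variance scale (\eqn{Q_U = (D - \alpha_U W) /
#'   \sigma_U^2}).
#' @return List with `mean` (= B(X)), `precision` (sparse \eqn{Q_U}), and the
#'   `smoother` matrix used.
#' @export
joint_exposure_confounder_model <- function(X, graph, spec, delta,
                                            sigma2_u = 1) {
  stopifnot(inherits(graph, "area_graph"), inherits(spec, "na_spec"))
  if (length(X) != graph$n_areas) stop("`X` has wrong length")
  if (sigma2_u <= 0) stop("`sigma2_u` must be > 0")
  S <- neighbourhood_smoother(graph, spec$smoother_order)
  Qu <- proper_car_precision(graph, tau = 1 / sigma2_u, alpha = spec$alpha_u)
  list(mean = as.numeric(delta * (S %*% X)), precision = Qu$Q, smoother = S)
}

#' One Gibbs imputation sweep of the latent confounder
#'
#' Updates U from its full conditional, proportional to
#' Poisson\eqn{(Y | E e^{\eta + U})} times \eqn{N(U | B(X), Q_U^{-1})}.
#' `method = "site"` performs single-site Metropolis-adjusted updates with a
#' Gaussian proposal from a local quadratic expansion of the Poisson
#' log-likelihood (exact, acceptance 1, under the Gaussian hook).
#' `method = "block"` draws the whole vector exactly by sparse Cholesky and is
#' available only for the Gaussian likelihood, where the full conditional is
#' Gaussian with precision \eqn{Q_U + \sigma^{-2} I}.
#'
#' @param y Outcome vector.
#' @param expected Expected counts (Poisson offset scale).
#' @param U Current confounder vector.
#' @param prior_mean Conditional prior mean \eqn{B(X) = \delta S X}.
#' @param Q Sparse confounder precision \eqn{Q_U}.
#' @param eta_rest Linear predictor excluding U.
#' @param likelihood `"poisson"` or `"gaussian"`.
#' @param gaussian_sd Error SD under the Gaussian hook.
#' @param method `"site"` or `"block"`.
#' @return List with the updated `U` and per-site `accept` indicator (all 1
#'   for the block update).
#' @export
impute_confounder <- function(y, expected, U, prior_mean, Q, eta_rest,
                              likelihood = c("poisson", "gaussian"),
                              gaussian_sd = 1, method = c("site", "block")) {
  likelihood <- match.arg(likelihood)
  method <- match.arg(method)
  if (!all(is.finite(U)) || !all(is.finite(prior_mean))) {
    stop("current confounder state must be finite")
  }
  if (method == "block") {
    if (likelihood != "gaussian") {
      stop("the exact block update requires the Gaussian likelihood hook")
    }
    n <- length(U)
    P <- Q + Matrix::Diagonal(n, 1 / gaussian_sd^2)
    b <- as.numeric(Q %*% prior_mean) + (y - eta_rest) / gaussian_sd^2
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(P),
                                       "CsparseMatrix"),
                           LDL = FALSE, perm = TRUE)
    m <- as.numeric(Matrix::solve(P, b))
    z <- rnorm(n)
    eps <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                    system = "Pt"))
    return(list(U = m + eps, accept = rep(1L, n)))
  }
  pc <- precision_csr(Q)
  sw <- sweep_confounder(U, y, expected, eta_rest, prior_mean,
                         pc$p, pc$i, pc$x, lik_code(likelihood), gaussian_sd)
  list(U = sw$value, accept = sw$accept)
}

#' Fit the neighbourhood-adjustment model
#'
#' Metropolis-within-Gibbs sampler for the NA model. Per iteration:
#' regression coefficients by adaptive random-walk Metropolis; an
#' "interweaving" ridge move proposing \eqn{(\beta_X + \epsilon,\; U -
#' \epsilon X,\; \delta - \epsilon)} jointly, along which the outcome
#' likelihood is exactly invariant so acceptance is governed by the
#' identification term \eqn{\epsilon (X - SX)}; the confounder sweep of
#' [impute_confounder()]; an exact conjugate Gibbs draw of delta; and a
#' conjugate inverse-gamma draw of the confounder variance. The exposure
#' coefficient draws are thus purged of the bias \eqn{B(X)}, which is carried
#' by delta instead.
#'
#' @inheritParams fit_bym
#' @param spec An [na_spec()].
#' @return A `posterior_draws` object with columns `beta0`, `beta_x`,
#'   `gamma_*`, `delta`, `sigma2_u` (plus `sigma2_theta` when
#'   `residual_effects`); `random_effects$u` holds the imputed confounder
#'   draws.
#' @export
fit_na <- function(data, graph, spec = na_spec(), init = NULL) {
  stopifnot(inherits(graph, "area_graph"), inherits(spec, "na_spec"))
  mf <- model_frame(data, graph, spec)
  n <- graph$n_areas
  p <- ncol(mf$design)
  lik <- lik_code(spec$likelihood)
  gsd <- spec$gaussian_sd
  ig_a <- spec$variance_prior[["shape"]]
  ig_b <- spec$variance_prior[["rate"]]

  S <- neighbourhood_smoother(graph, spec$smoother_order)
  Mu <- proper_car_precision(graph, tau = 1, alpha = spec$alpha_u)$M
  pc <- precision_csr(Mu)
  v <- as.numeric(S %*% mf$X)          # smoothed exposure, B(X) = delta * v
  w <- mf$X - v                        # identification direction X - SX
  Mv <- as.numeric(Mu %*% v)
  Mw <- as.numeric(Mu %*% w)
  vMv <- sum(v * Mv)
  wMw <- sum(w * Mw)

  set.seed(spec$seed)
  beta <- init$beta %||% numeric(p)
  U <- init$U %||% numeric(n)
  delta <- init$delta %||% 0
  s2u <- init$sigma2_u %||% 0.1
  theta <- init$theta %||% numeric(n)
  if (!spec$residual_effects) theta[] <- 0
  s2t <- init$sigma2_theta %||% 0.1
  eta <- as.numeric(mf$design %*% beta) + U + theta

  step_beta <- rep(0.1, p)
  step_ridge <- 0.05
  batch <- 50L
  acc_beta_batch <- numeric(p)
  acc_ridge_batch <- 0
  acc_theta_batch <- numeric(n)
  step_theta <- rep(0.3, n)
  acc_beta_tot <- numeric(p)
  acc_ridge_tot <- 0
  acc_u_tot <- 0
  acc_theta_tot <- 0

  total_iter <- spec$burn_in + spec$iterations
  n_save <- spec$iterations
  par_names <- c(colnames(mf$design), "delta", "sigma2_u",
                 if (spec$residual_effects) "sigma2_theta")
  draws <- matrix(NA_real_, n_save, length(par_names),
                  dimnames = list(NULL, par_names))
  re_u <- if (spec$save_random_effects) matrix(NA_real_, n_save, n)
  re_theta <- if (spec$save_random_effects && spec$residual_effects) {
    matrix(NA_real_, n_save, n)
  }

  for (it in seq_len(total_iter)) {
    # -- regression coefficients
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

    # -- interweaving ridge move along the weakly identified direction:
    #    (beta_x, U, delta) -> (beta_x + e, U - e X, delta - e).
    #    eta is unchanged, so only the U-prior and the coefficient priors move:
    #    residual r = U - delta v changes by -e w, w = X - S X.
    e <- step_ridge * rnorm(1)
    r <- U - delta * v
    rMw <- sum(r * Mw)
    dquad <- -e * rMw + 0.5 * e^2 * wMw     # 0.5*(r'Mr' - r'Mr) with r' = r - e w
    bx <- beta[2L]
    la <- -dquad / s2u -
      ((bx + e)^2 - bx^2) / (2 * spec$prior_sd^2) -
      ((delta - e)^2 - delta^2) / (2 * spec$delta_prior_sd^2)
    if (is.finite(la) && log(runif(1)) < la) {
      beta[2L] <- bx + e
      U <- U - e * mf$X
      delta <- delta - e
      acc_ridge_batch <- acc_ridge_batch + 1
      if (it > spec$burn_in) acc_ridge_tot <- acc_ridge_tot + 1
    }

    # -- confounder imputation sweep (full conditional, quadratic proposals)
    rest <- eta - U
    sw <- sweep_confounder(U, mf$y, mf$E, rest, delta * v,
                           pc$p, pc$i, pc$x / s2u, lik, gsd)
    U <- sw$value
    eta <- rest + U
    if (it > spec$burn_in) acc_u_tot <- acc_u_tot + mean(sw$accept)

    # -- delta: exact conjugate Gaussian draw
    prec_d <- vMv / s2u + 1 / spec$delta_prior_sd^2
    mean_d <- sum(Mv * U) / s2u / prec_d
    delta <- rnorm(1, mean_d, sqrt(1 / prec_d))

    # -- confounder variance: conjugate inverse-gamma
    r <- U - delta * v
    qf <- as.numeric(t(r) %*% (Mu %*% r))
    s2u <- 1 / rgamma(1, shape = ig_a + n / 2, rate = ig_b + qf / 2)

    # -- optional iid residual effect
    if (spec$residual_effects) {
      rest <- eta - theta
      swt <- sweep_iid_re(theta, mf$y, mf$E, rest, s2t, step_theta, lik, gsd)
      theta <- swt$value
      eta <- rest + theta
      acc_theta_batch <- acc_theta_batch + swt$accept
      if (it > spec$burn_in) acc_theta_tot <- acc_theta_tot + mean(swt$accept)
      s2t <- 1 / rgamma(1, shape = ig_a + n / 2,
                        rate = ig_b + sum(theta^2) / 2)
    }

    if (!is.finite(data_loglik(mf$y, mf$E, eta, lik, gsd))) {
      stop("divergent chain: non-finite log-likelihood at iteration ", it)
    }

    if (it <= spec$burn_in && it %% batch == 0L) {
      bi <- it %/% batch
      step_beta <- adapt_steps(step_beta, acc_beta_batch, batch, bi)
      step_ridge <- adapt_steps(step_ridge, acc_ridge_batch, batch, bi,
                                target = 0.3)
      step_theta <- adapt_steps(step_theta, acc_theta_batch, batch, bi)
      acc_beta_batch[] <- 0
      acc_ridge_batch <- 0
      acc_theta_batch[] <- 0
    }

    if (it > spec$burn_in) {
      s <- it - spec$burn_in
      draws[s, ] <- c(beta, delta, s2u,
                      if (spec$residual_effects) s2t)
      if (!is.null(re_u)) re_u[s, ] <- U
      if (!is.null(re_theta)) re_theta[s, ] <- theta
    }
  }

  acc <- list(beta = acc_beta_tot / n_save,
              ridge = acc_ridge_tot / n_save,
              u = acc_u_tot / n_save,
              theta = if (spec$residual_effects) acc_theta_tot / n_save)
  new_posterior_draws(
    draws = draws,
    random_effects = list(u = re_u, theta = re_theta),
    model = "na", spec = spec,
    meta = list(seed = spec$seed, iterations = spec$iterations,
                burn_in = spec$burn_in, acceptance = acc,
                smoothed_exposure = v),
    state = list(beta = beta, U = U, delta = delta, sigma2_u = s2u,
                 theta = theta, sigma2_theta = s2t))
}

#' Gap between the naive and the de-confounded exposure estimates
#'
#' Difference of posterior means of the exposure coefficient, BYM minus NA,
#' with a Monte-Carlo standard error (batch means, chains treated as
#' independent). A positive gap indicates upward bias of the naive estimator,
#' the signature of positive exposure-confounder coupling.
#'
#' @param draws_bym,draws_na `posterior_draws` objects (or draw matrices)
#'   containing the parameter.
#' @param parameter Parameter name (default `"beta_x"`).
#' @return List with `gap` and `mc_se`.
#' @export
bias_gap <- function(draws_bym, draws_na, parameter = "beta_x") {
  b <- param_chain(draws_bym, parameter)
  a <- param_chain(draws_na, parameter)
  list(gap = mean(b) - mean(a),
       mc_se = sqrt(mcse_mean(b)^2 + mcse_mean(a)^2))
}
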