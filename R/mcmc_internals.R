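# Shared machinery for the MCMC fitters: model-frame extraction, adjacency in
# compressed form for the C++ sweeps, adaptive step-size bookkeeping, and
# Monte-Carlo standard errors.

LIK_POISSON <- 0L
LIK_GAUSSIAN <- 1L

lik_code <- function(likelihood) {
  switch(likelihood, poisson = LIK_POISSON, gaussian = LIK_GAUSSIAN,
         stop("unknown likelihood: ", likelihood))
}

# Adjacency of an area_graph in 0-based compressed column form (symmetric, so
# columns double as rows), as the C++ sweeps expect.
graph_csr <- function(graph) {
  W <- methods::as(methods::as(graph$W, "generalMatrix"), "CsparseMatrix")
  list(ptr = W@p, idx = W@i)
}

# Sparse symmetric precision in compressed slots for sweep_confounder().
precision_csr <- function(Q) {
  Q <- methods::as(methods::as(Q, "generalMatrix"), "CsparseMatrix")
  list(p = Q@p, i = Q@i, x = Q@x)
}

# Total data log-likelihood given the linear predictor eta (offset excluded;
# it is absorbed into Emu for the Poisson case). Constants in Y are dropped.
data_loglik <- function(y, Emu, eta, lik, gauss_sd) {
  if (lik == LIK_POISSON) {
    sum(y * eta) - sum(Emu * exp(eta))
  } else {
    -0.5 * sum((y - eta)^2) / gauss_sd^2
  }
}

# Extract and validate the pieces of the outcome model from an area table.
model_frame <- function(data, graph, spec) {
  if (nrow(data) != graph$n_areas) {
    stop("area table has ", nrow(data), " rows but graph has ",
         graph$n_areas, " areas")
  }
  if ("area_id" %in% names(data) &&
      !identical(as.character(data$area_id), graph$ids)) {
    stop("area ordering of `data` does not match the graph's area ids")
  }
  if (!spec$exposure %in% names(data)) {
    stop("exposure column `", spec$exposure, "` not found in area table")
  }
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss)) {
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  }
  y <- data$y_late
  E <- data$expected
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("expected counts must be finite and > 0 for every modelled area")
  }
  if (spec$likelihood == "poisson") {
    if (any(y < 0) || any(y != round(y))) {
      stop("Poisson outcome requires nonnegative integer counts")
    }
  }
  X <- as.numeric(data[[spec$exposure]])
  Z <- if (length(spec$covariates)) {
    as.matrix(data[, spec$covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  design <- cbind(intercept = 1, exposure = X, Z)
  colnames(design) <- c("beta0", "beta_x",
                        if (ncol(Z)) paste0("gamma_", spec$covariates))
  list(y = as.numeric(y), E = as.numeric(E), X = X, Z = Z, design = design)
}

# Robbins-Monro-flavoured batch adaptation of log step sizes toward a target
# acceptance rate. Only called during burn-in; scales are frozen afterwards.
adapt_steps <- function(step, acc_count, batch_size, batch_index,
                        target = 0.44) {
  gain <- min(0.25, 2 / sqrt(batch_index))
  rate <- acc_count / batch_size
  step * exp(gain * (rate - target))
}

# Batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) chain.
mcse_mean <- function(x) {
  n <- length(x)
  if (n < 10L) return(stats::sd(x) / sqrt(max(n, 1L)))
  b <- max(2L, floor(sqrt(n)))
  nb <- floor(n / b)
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}

new_posterior_draws <- function(draws, random_effects, model, spec, meta,
                                state) {
  structure(list(draws = draws, random_effects = random_effects,
                 model = model, spec = spec, meta = meta, state = state),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws (", x$model, " model): ", nrow(x$draws),
      " saved iterations (", x$meta$iterations, " total, ",
      x$meta$burn_in, " burn-in), seed ", x$meta$seed, "\n", sep = "")
  cat("Parameters:", paste(colnames(x$draws), collapse = ", "), "\n")
  invisible(x)
}

# Extract a named scalar parameter's chain from a posterior_draws object (or
# pass a plain matrix/vector through).
param_chain <- function(draws, parameter) {
  if (inherits(draws, "posterior_draws")) draws <- draws$draws
  if (is.matrix(draws)) {
    if (!parameter %in% colnames(draws)) {
      stop("unknown parameter `", parameter, "`; available: ",
           paste(colnames(draws), collapse = ", "))
    }
    draws <- draws[, parameter]
  }
  if (!length(draws)) stop("empty draws")
  as.numeric(draws)
}
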