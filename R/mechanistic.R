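#' Parameters of the covariate-modulated annual plant competition model
#'
#' The classic Beverton-Holt annual plant form, with an optional named
#' abiotic covariate modulating both intrinsic fecundity (log-linearly) and
#' pairwise interactions (additively, clipped at zero):
#' \deqn{E[X_i] = \lambda_i e^{\beta_i E} \, X_i / (1 + \sum_j \max(0, \alpha_{ij} + \gamma_{ij} E) X_j)}
#'
#' @param lambda per-species intrinsic fecundity, > 0.
#' @param alpha non-negative interaction matrix (row i: suppression of
#'   species i by species j).
#' @param beta per-species covariate coefficient on log fecundity
#'   (default 0).
#' @param gamma covariate modulation of `alpha` (default 0 matrix).
#' @param covariate name of the abiotic covariate the coefficients refer
#'   to, or `NULL`.
#' @return an `annual_plant_params` list.
#' @export
annual_plant_params <- function(lambda, alpha, beta = NULL, gamma = NULL,
                                covariate = NULL) {
  m <- length(lambda)
  if (any(lambda <= 0)) stop_validation("lambda must be strictly positive")
  alpha <- as.matrix(alpha)
  if (any(alpha < 0)) stop_validation("alpha must be non-negative")
  stopifnot(nrow(alpha) == m, ncol(alpha) == m)
  beta <- beta %||% numeric(m)
  gamma <- if (is.null(gamma)) matrix(0, m, m) else as.matrix(gamma)
  species <- names(lambda) %||% rownames(alpha) %||% sprintf("SP%02d", seq_len(m))
  structure(list(lambda = stats::setNames(as.numeric(lambda), species),
                 alpha = alpha, beta = as.numeric(beta), gamma = gamma,
                 covariate = covariate, species = species),
            class = "annual_plant_params")
}

# Interaction matrix at covariate value E; clipped at zero so modulated
# competition never turns facilitative by accident.
alpha_at <- function(params, E) {
  al <- params$alpha + params$gamma * E
  al[al < 0] <- 0
  al
}

#' Expected abundances under the annual plant model
#'
#' @param params an [annual_plant_params()].
#' @param abundances non-negative abundance matrix (observations x species)
#'   or a single vector.
#' @param covariate covariate value per observation (recycled); ignored
#'   when the parameter set carries no covariate.
#' @return matrix of expected abundances, same shape as `abundances`.
#' @export
predict_mechanistic <- function(params, abundances, covariate = 0) {
  A <- if (is.matrix(abundances)) abundances else matrix(abundances, nrow = 1)
  if (any(A < 0)) stop_validation("abundances must be non-negative")
  m <- length(params$lambda)
  stopifnot(ncol(A) == m)
  E <- rep_len(covariate, nrow(A))
  out <- matrix(NA_real_, nrow(A), m, dimnames = list(NULL, params$species))
  for (r in seq_len(nrow(A))) {
    al <- alpha_at(params, E[r])
    denom <- 1 + as.numeric(al %*% A[r, ])
    out[r, ] <- params$lambda * exp(params$beta * E[r]) * A[r, ] / denom
  }
  out
}

# Solve the snapshot fixed point X_i = lambda_i(E) u_i / (1 + sum_j alpha_ij(E) X_j)
# by damped iteration (alpha >= 0 makes the map monotone; damping ensures
# convergence for moderate interaction strengths).
bh_fixed_point <- function(lambda_eff, alpha, tol = 1e-12, max_iter = 1000) {
  x <- lambda_eff
  for (it in seq_len(max_iter)) {
    xn <- lambda_eff / (1 + as.numeric(alpha %*% x))
    x_new <- 0.5 * x + 0.5 * xn
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

#' Simulate mutually consistent snapshot communities (synthetic)
#'
#' Generates communities whose abundances satisfy the snapshot
#' Beverton-Holt relation simultaneously for every species, by fixed-point
#' iteration. Exogenous variation comes from the covariate and from
#' per-species lognormal environmental heterogeneity on fecundity
#' (`env_sd`); with `env_sd = 0` and a constant covariate all communities
#' are identical. Used by the parameter-recovery tests; the data are
#' synthetic stand-ins, not survey records.
#'
#' @param params an [annual_plant_params()].
#' @param covariate covariate value per community.
#' @param env_sd log-scale SD of the fecundity heterogeneity.
#' @param n number of communities (default: length of `covariate`).
#' @param seed integer seed.
#' @return list with `abundances` (n x m matrix) and `covariate`.
#' @export
simulate_mechanistic <- function(params, covariate = 0, env_sd = 0.5,
                                 n = length(covariate), seed = 1) {
  E <- rep_len(covariate, n)
  m <- length(params$lambda)
  U <- with_seed(derive_seed(seed, 61L),
                 matrix(exp(stats::rnorm(n * m, 0, env_sd)), n, m))
  A <- matrix(NA_real_, n, m, dimnames = list(NULL, params$species))
  for (r in seq_len(n)) {
    lam <- params$lambda * exp(params$beta * E[r]) * U[r, ]
    A[r, ] <- bh_fixed_point(lam, alpha_at(params, E[r]))
  }
  list(abundances = A, covariate = E)
}

#' Fit the annual plant model to community snapshots
#'
#' Estimates, independently for each focal species, the fecundity and
#' interaction parameters of the snapshot Beverton-Holt form
#' \eqn{\mu_i = \lambda_i e^{\beta_i E} / (1 + \sum_{j \ne i} \max(0, \alpha_{ij} + \gamma_{ij} E) X_j)}
#' by penalized least squares on log1p abundances, with a ridge penalty on
#' the interaction terms to tame the quadratic growth of the parameter
#' count with community richness. With `covariate = NULL`, `beta` and
#' `gamma` are fixed at zero (the nested biotic-only model). The covariate
#' model is initialized at the biotic-only solution, so its training error
#' never exceeds the nested model's.
#'
#' @param table a [community_table()] (abundances and, if used, the
#'   covariate column).
#' @param covariate abiotic covariate name, or `NULL` for the biotic-only
#'   model.
#' @param ridge ridge penalty weight on `alpha` and `gamma` (default 0.1).
#' @param holdout_fraction fraction of communities held out for the
#'   reported predictive RMSE (default 0.2).
#' @param seed integer seed for the holdout split.
#' @param maxit optimizer iteration cap per focal species.
#' @return list with `params` ([annual_plant_params()]), `train_error`
#'   (penalized objective, summed over focal species), `train_rmse` and
#'   `holdout_rmse` (log1p scale), and `converged`.
#' @export
fit_mechanistic <- function(table, covariate = NULL, ridge = 0.1,
                            holdout_fraction = 0.2, seed = 1, maxit = 300) {
  sp <- species_names(table)
  m <- length(sp)
  A <- as.matrix(tibble::as_tibble(unclass_table(table))[sp])
  storage.mode(A) <- "double"
  n <- nrow(A)
  if (n < 5) stop_validation("too few communities to fit the mechanistic model")
  E <- if (is.null(covariate)) rep(0, n) else {
    if (!covariate %in% names(table)) stop_validation("covariate '%s' absent from table", covariate)
    v <- table[[covariate]]
    (v - mean(v)) / (stats::sd(v) + (stats::sd(v) == 0))
  }
  n_hold <- max(1L, round(holdout_fraction * n))
  hold <- with_seed(derive_seed(seed, 71L), sample.int(n, n_hold))
  tr <- setdiff(seq_len(n), hold)

  use_cov <- !is.null(covariate)
  lambda <- numeric(m); beta <- numeric(m)
  alpha <- matrix(0, m, m, dimnames = list(sp, sp))
  gamma <- matrix(0, m, m, dimnames = list(sp, sp))
  conv <- logical(m); obj_total <- 0

  # warm start for the covariate model: the biotic-only fit
  base <- if (use_cov) fit_mechanistic(table, covariate = NULL, ridge = ridge,
                                       holdout_fraction = holdout_fraction,
                                       seed = seed, maxit = maxit)

  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    Xo <- A[tr, others, drop = FALSE]
    y <- log1p(A[tr, i])
    Ei <- E[tr]
    k <- length(others)
    objective <- function(par) {
      loglam <- par[1]
      b <- if (use_cov) par[2] else 0
      al <- par[seq_len(k) + 1 + use_cov]
      ga <- if (use_cov) par[seq_len(k) + 1 + use_cov + k] else numeric(k)
      al_eff <- pmax(0, outer(Ei, ga) + rep(al, each = length(Ei)))
      denom <- 1 + rowSums(al_eff * Xo)
      mu <- exp(loglam + b * Ei) / denom
      sum((y - log1p(mu))^2) + ridge * (sum(al^2) + sum(ga^2))
    }
    init <- if (use_cov) {
      c(log(base$params$lambda[i]), 0, base$params$alpha[i, others], rep(0, k))
    } else {
      c(log(mean(A[tr, i]) + 0.5), rep(0.01, k))
    }
    lower <- if (use_cov) c(-10, -5, rep(0, k), rep(-5, k)) else c(-10, rep(0, k))
    upper <- if (use_cov) c(15, 5, rep(10, k), rep(5, k)) else c(15, rep(10, k))
    fit <- stats::optim(init, objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = maxit))
    conv[i] <- fit$convergence == 0
    obj_total <- obj_total + fit$value
    lambda[i] <- exp(fit$par[1])
    if (use_cov) beta[i] <- fit$par[2]
    alpha[i, others] <- fit$par[seq_len(k) + 1 + use_cov]
    if (use_cov) gamma[i, others] <- fit$par[seq_len(k) + 1 + use_cov + k]
  }
  params <- annual_plant_params(stats::setNames(lambda, sp), alpha,
                                beta = beta, gamma = gamma,
                                covariate = covariate)
  pred_mu <- function(ix) {
    sapply(seq_len(m), function(i) {
      others <- setdiff(seq_len(m), i)
      al_eff <- pmax(0, outer(E[ix], gamma[i, others]) +
                       rep(alpha[i, others], each = length(ix)))
      denom <- 1 + rowSums(al_eff * A[ix, others, drop = FALSE])
      lambda[i] * exp(beta[i] * E[ix]) / denom
    })
  }
  train_rmse <- rmse(as.vector(log1p(A[tr, , drop = FALSE])), as.vector(log1p(pred_mu(tr))))
  holdout_rmse <- rmse(as.vector(log1p(A[hold, , drop = FALSE])), as.vector(log1p(pred_mu(hold))))
  if (!any(conv)) stop_validation("mechanistic fit failed to converge for every species")
  list(params = params, train_error = obj_total, train_rmse = train_rmse,
       holdout_rmse = holdout_rmse, converged = conv)
}
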