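#' Fit a Bayesian CAR Poisson model for small-area prevalence
#'
#' Fits `Y_i ~ Poisson(E_i exp(eta_i))` by Markov chain Monte Carlo, with
#' the offset `log(E_i)` (the child population) supplied through the model
#' formula, and one of two spatial structures on the linear predictor:
#'
#' * **Leroux** (`prior = "leroux"`): `eta_i = x_i' beta + phi_i` with
#'   random effects `phi` under the Leroux conditional-autoregressive prior,
#'   precision `tau2^-1 [rho (D - W) + (1 - rho) I]` on the binary queen
#'   adjacency `W`. Full conditionals are
#'   `phi_i | . ~ N(rho sum_j w_ij phi_j / (rho d_i + 1 - rho),
#'   tau2 / (rho d_i + 1 - rho))`, sampled by Metropolis-within-Gibbs;
#'   `tau2` has a conjugate inverse-gamma update; `rho` a Metropolis step
#'   on (0, 1) with the exact log-determinant via the eigenvalues of
#'   `D - W`. `phi` is recentred to mean zero each sweep with the mean
#'   absorbed into the intercept.
#' * **Localised clusters** (`prior = "localised"`): `eta_i = x_i' beta +
#'   lambda_{Z_i} + theta_i` with at most `G` strictly increasing cluster
#'   intercepts `lambda_1 < ... < lambda_G` (ordering enforced by rejecting
#'   violating proposals), iid `theta_i ~ N(0, sigma2)`, per-area class
#'   labels `Z_i` updated by discrete Gibbs under the penalty prior
#'   `f(Z_i = g | delta) propto exp(-delta (g - G*)^2)`, `G* = (G + 1)/2`,
#'   and `delta ~ Uniform(1, 10)`. The design intercept is dropped (the
#'   cluster intercepts absorb the level).
#'
#' Priors: `beta ~ N(0, 1e5)` per coefficient, variance parameters
#' `~ InvGamma(1, 0.01)`, `rho ~ Uniform(0, 1)`, `delta ~ Uniform(1, 10)`.
#' Proposal scales are auto-tuned during burn-in only. The per-draw
#' pointwise log-likelihood is retained for WAIC.
#'
#' @param formula model formula with the count response and an offset term,
#'   e.g. `asthma_count ~ seifa_category + indigenous_group +
#'   offset(log(child_pop))`.
#' @param data area table (a data frame).
#' @param weights an `area_weights` or `area_graph`; the binary adjacency is
#'   used, and the graph must be connected.
#' @param prior `"leroux"` or `"localised"`.
#' @param G maximum number of clusters (localised only; typically 3 or 5).
#' @param n_iter,burn_in,thin MCMC settings; defaults 30000/10000/10 are the
#'   routine test scale, while full analyses use 300000/100000.
#' @param prior_beta_var Gaussian prior variance for each coefficient.
#' @param prior_sigma2 inverse-gamma (shape, scale) for the random-effect
#'   variance; default `c(1, 0.01)`.
#' @param prior_delta uniform bounds for the cluster penalty parameter;
#'   default `c(1, 10)`.
#' @param fix_rho,fix_tau2 optionally fix the Leroux dependence/variance
#'   parameters instead of sampling them.
#' @param prior_only sample from the priors with the likelihood switched
#'   off (sampler validation).
#' @param phi_method for `prior_only` Leroux runs: `"auto"` (exact
#'   Cholesky draws of `phi`, the default) or `"mh"` (the same
#'   Metropolis-within-Gibbs sweep used with data).
#' @param seed optional integer seed; fixed seed gives bitwise-identical
#'   chains.
#' @param verbose print progress information.
#' @return An object of class `car_fit` with components `chains` (posterior
#'   draws), `loglik` (retained-draw by area log-likelihood matrix),
#'   `accept` (acceptance rates), and the model frame ingredients.
#' @seealso [posterior_summary()], [compute_waic()], [geweke_diagnostic()]
#' @export
fit_car <- function(formula, data, weights,
                    prior = c("leroux", "localised"), G = NULL,
                    n_iter = 30000, burn_in = 10000, thin = 10,
                    prior_beta_var = 1e5,
                    prior_sigma2 = c(1, 0.01),
                    prior_delta = c(1, 10),
                    fix_rho = NULL, fix_tau2 = NULL,
                    prior_only = FALSE,
                    phi_method = c("auto", "mh"),
                    seed = NULL, verbose = FALSE) {
  prior <- match.arg(prior)
  phi_method <- match.arg(phi_method)
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  if (thin < 1 || thin != floor(thin)) stop("`thin` must be a positive integer", call. = FALSE)
  if (any(prior_sigma2 <= 0)) stop("inverse-gamma parameters must be positive", call. = FALSE)
  w <- .as_weights(weights, "binary")
  graph <- w$graph
  n <- length(graph$ids)
  if (max(graph_components(graph)) > 1L)
    stop("weights graph is disconnected; rerun exclusions", call. = FALSE)

  mf <- stats::model.frame(formula, data)
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  off <- stats::model.offset(mf)
  if (is.null(off))
    stop("the model requires an offset term, e.g. offset(log(child_pop))",
         call. = FALSE)
  X <- stats::model.matrix(tt, mf)
  if (nrow(X) != n)
    stop("data rows (", nrow(X), ") do not match the number of areas (", n, ")",
         call. = FALSE)
  if (!prior_only) {
    if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
      stop("response must be nonnegative integer counts", call. = FALSE)
  } else if (is.null(y)) {
    y <- rep(0L, n)
  }
  if (prior == "localised") {
    if (is.null(G)) stop("`G` is required for the localised model", call. = FALSE)
    if (G < 2 || G > 10 || G != floor(G))
      stop("`G` must be an integer in 2..10", call. = FALSE)
    ic <- match("(Intercept)", colnames(X))
    if (!is.na(ic)) X <- X[, -ic, drop = FALSE]  # lambdas absorb the level
  }

  if (!is.null(seed)) set.seed(seed)

  if (prior_only && (prior == "localised" || phi_method == "auto")) {
    fitlist <- .prior_only_run(prior, w, X, G, n_iter, burn_in, thin,
                               prior_beta_var, prior_sigma2, prior_delta,
                               fix_rho, fix_tau2)
  } else if (prior == "leroux") {
    has_int <- "(Intercept)" %in% colnames(X)
    beta_init <- rep(0, ncol(X))
    if (!prior_only) {
      g0 <- suppressWarnings(stats::glm.fit(X, y, offset = off,
                                            family = stats::poisson()))
      if (all(is.finite(g0$coefficients))) beta_init <- g0$coefficients
    }
    evals <- if (is.null(fix_rho)) {
      D <- Matrix::Diagonal(n, Matrix::rowSums(w$W))
      eigen(as.matrix(D - w$W), symmetric = TRUE, only.values = TRUE)$values
    } else rep(0, n)
    nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))
    fitlist <- .leroux_mcmc_cpp(
      as.integer(y), as.numeric(off), X, nb0, as.numeric(evals),
      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
      prior_beta_var, prior_sigma2[1], prior_sigma2[2],
      if (is.null(fix_rho)) -1 else fix_rho,
      if (is.null(fix_tau2)) -1 else fix_tau2,
      !prior_only, !prior_only && has_int, as.numeric(beta_init))
    colnames(fitlist$beta) <- colnames(X)
  } else {
    beta_init <- rep(0, ncol(X))
    raw <- log((y + 0.5) / exp(off))
    lambda_init <- sort(stats::quantile(raw, probs = seq_len(G) / (G + 1),
                                        names = FALSE))
    lambda_init <- lambda_init + cumsum(c(0, rep(1e-6, G - 1)))  # strict order
    z_init <- apply(outer(raw, lambda_init, function(a, b) abs(a - b)), 1,
                    which.min) - 1L
    fitlist <- .localised_mcmc_cpp(
      as.integer(y), as.numeric(off), X, as.integer(G),
      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
      prior_beta_var, prior_beta_var,
      prior_sigma2[1], prior_sigma2[2],
      prior_delta[1], prior_delta[2],
      !prior_only, as.numeric(lambda_init), as.integer(z_init),
      as.numeric(beta_init))
    if (ncol(X)) colnames(fitlist$beta) <- colnames(X)
  }

  loglik <- fitlist$loglik
  fitlist$loglik <- NULL
  accept <- fitlist$accept
  fitlist$accept <- NULL
  out <- structure(list(
    chains = fitlist,
    loglik = if (prior_only) NULL else loglik,
    accept = accept,
    model = prior, G = G,
    y = y, offset = off, X = X,
    weights = w,
    terms = tt, xlevels = stats::.getXlevels(tt, mf),
    spec = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                prior_beta_var = prior_beta_var,
                prior_sigma2 = prior_sigma2, prior_delta = prior_delta,
                fix_rho = fix_rho, fix_tau2 = fix_tau2,
                prior_only = prior_only, seed = seed),
    call = match.call()),
    class = "car_fit")
  if (verbose) print(out)
  out
}

#' @rdname fit_car
#' @export
fit_car_leroux <- function(data, weights,
                           formula = asthma_count ~ seifa_category +
                             indigenous_group + offset(log(child_pop)),
                           ...) {
  fit_car(formula, data, weights, prior = "leroux", ...)
}

#' @rdname fit_car
#' @export
fit_car_localised <- function(data, weights, G,
                              formula = asthma_count ~ seifa_category +
                                indigenous_group + offset(log(child_pop)),
                              ...) {
  fit_car(formula, data, weights, prior = "localised", G = G, ...)
}

## Prior-only Gibbs runs in R with exact conditional draws where available.
.prior_only_run <- function(prior, w, X, G, n_iter, burn_in, thin,
                            beta_var, ig, delta_bounds, fix_rho, fix_tau2) {
  n <- length(w$graph$ids)
  p <- ncol(X)
  n_keep <- (n_iter - burn_in) %/% thin
  keep_at <- burn_in + thin * (seq_len(n_keep) - 1L)
  if (prior == "leroux") {
    DW <- diag(Matrix::rowSums(w$W)) - as.matrix(w$W)   # D - W, dense
    In <- diag(n)
    evals <- eigen(DW, symmetric = TRUE, only.values = TRUE)$values
    tau2 <- if (is.null(fix_tau2)) 1 else fix_tau2
    rho <- if (is.null(fix_rho)) 0.5 else fix_rho
    phi <- rep(0, n)
    beta_d <- matrix(stats::rnorm(n_keep * p, 0, sqrt(beta_var)), n_keep, p,
                     dimnames = list(NULL, colnames(X)))
    phi_d <- matrix(0, n_keep, n)
    tau2_d <- rho_d <- numeric(n_keep)
    sd_rho <- 0.1
    k <- 0L
    for (iter in 0:(n_iter - 1L)) {
      Q1 <- rho * DW + (1 - rho) * In    # tau2-free part of the precision
      R <- chol(Q1 / tau2)
      phi <- backsolve(R, stats::rnorm(n))
      qf_dw <- as.numeric(crossprod(phi, DW %*% phi))
      qf_id <- sum(phi^2)
      qf <- rho * qf_dw + (1 - rho) * qf_id
      if (is.null(fix_tau2))
        tau2 <- 1 / stats::rgamma(1, ig[1] + n / 2, rate = ig[2] + qf / 2)
      if (is.null(fix_rho)) {
        rnew <- rho + sd_rho * stats::rnorm(1)
        if (rnew > 0 && rnew < 1 - 1e-8) {
          qf_new <- rnew * qf_dw + (1 - rnew) * qf_id
          lr <- 0.5 * sum(log(rnew * evals + 1 - rnew) -
                          log(rho * evals + 1 - rho)) -
            (qf_new - qf) / (2 * tau2)
          if (is.finite(lr) && log(stats::runif(1)) < lr) rho <- rnew
        }
      }
      if (k < n_keep && iter == keep_at[k + 1L]) {
        k <- k + 1L
        phi_d[k, ] <- phi; tau2_d[k] <- tau2; rho_d[k] <- rho
      }
    }
    list(beta = beta_d, phi = phi_d, tau2 = tau2_d, rho = rho_d,
         loglik = NULL, accept = list(beta = NA, phi = NA, rho = NA))
  } else {
    Gstar <- (G + 1) / 2
    delta <- mean(delta_bounds)
    z <- rep(1L, n)
    sigma2 <- 1
    beta_d <- matrix(stats::rnorm(n_keep * max(p, 1), 0, sqrt(beta_var)),
                     n_keep, max(p, 1))
    if (p) colnames(beta_d) <- colnames(X)
    theta_d <- matrix(0, n_keep, n)
    lambda_d <- matrix(0, n_keep, G)
    z_d <- matrix(0L, n_keep, n)
    sigma2_d <- delta_d <- numeric(n_keep)
    sd_delta <- 0.5
    k <- 0L
    for (iter in 0:(n_iter - 1L)) {
      theta <- stats::rnorm(n, 0, sqrt(sigma2))
      sigma2 <- 1 / stats::rgamma(1, ig[1] + n / 2,
                                  rate = ig[2] + sum(theta^2) / 2)
      pr <- exp(-delta * (seq_len(G) - Gstar)^2)
      z <- sample.int(G, n, replace = TRUE, prob = pr)
      dnew <- delta + sd_delta * stats::rnorm(1)
      if (dnew > delta_bounds[1] && dnew < delta_bounds[2]) {
        S2 <- sum((z - Gstar)^2)
        lr <- -(dnew - delta) * S2 -
          n * (log(sum(exp(-dnew * (seq_len(G) - Gstar)^2))) -
               log(sum(exp(-delta * (seq_len(G) - Gstar)^2))))
        if (is.finite(lr) && log(stats::runif(1)) < lr) delta <- dnew
      }
      lambda <- sort(stats::rnorm(G, 0, sqrt(beta_var)))
      if (k < n_keep && iter == keep_at[k + 1L]) {
        k <- k + 1L
        theta_d[k, ] <- theta; lambda_d[k, ] <- lambda; z_d[k, ] <- z
        sigma2_d[k] <- sigma2; delta_d[k] <- delta
      }
    }
    list(beta = beta_d, theta = theta_d, lambda = lambda_d, Z = z_d,
         sigma2 = sigma2_d, delta = delta_d, loglik = NULL,
         accept = list(beta = NA, theta = NA, lambda = NA, delta = NA))
  }
}
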