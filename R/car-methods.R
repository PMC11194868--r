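#' @method print car_fit
#' @export
print.car_fit <- function(x, ...) {
  cat("Bayesian CAR Poisson fit (",
      if (x$model == "leroux") "Leroux prior"
      else paste0("localised clusters, G = ", x$G), ")\n", sep = "")
  cat("  areas: ", length(x$y),
      ", retained draws: ", nrow(x$chains$beta),
      " (", x$spec$n_iter, " iterations, ", x$spec$burn_in, " burn-in, thin ",
      x$spec$thin, ")\n", sep = "")
  if (x$spec$prior_only) cat("  prior-only run (likelihood switched off)\n")
  acc <- unlist(x$accept)
  acc <- acc[is.finite(acc)]
  if (length(acc))
    cat("  acceptance rates: ",
        paste(names(acc), sprintf("%.2f", acc), sep = " = ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @method coef car_fit
#' @export
coef.car_fit <- function(object, ...) {
  colMeans(object$chains$beta)
}

#' Posterior mean fitted values (expected counts)
#' @param object a `car_fit`.
#' @param ... unused.
#' @return Posterior mean of `E_i exp(eta_i)` per area.
#' @export
fitted.car_fit <- function(object, ...) {
  if (is.null(object$loglik)) stop("no fitted values for a prior-only run", call. = FALSE)
  ch <- object$chains
  S <- nrow(ch$beta)
  eta <- tcrossprod(object$X, ch$beta)       # n x S (x'beta per draw)
  if (object$model == "leroux") {
    eta <- eta + t(ch$phi)
  } else {
    lam <- vapply(seq_len(S), function(s) ch$lambda[s, ch$Z[s, ]], numeric(length(object$y)))
    eta <- eta + lam + t(ch$theta)
  }
  rowMeans(exp(object$offset + eta))
}

#' Pearson residuals at the posterior mean fit
#' @param object a `car_fit`.
#' @param ... unused.
#' @export
residuals.car_fit <- function(object, ...) {
  mu <- fitted(object)
  (object$y - mu) / sqrt(mu)
}

#' @method summary car_fit
#' @export
summary.car_fit <- function(object, prob = 0.95, ...) {
  structure(list(
    fit = object,
    coefficients = posterior_summary(object, prob = prob),
    waic = if (!is.null(object$loglik)) compute_waic(object) else NULL,
    variance = if (object$model == "leroux")
      c(tau2 = stats::median(object$chains$tau2),
        rho = stats::median(object$chains$rho))
    else
      c(sigma2 = stats::median(object$chains$sigma2),
        delta = stats::median(object$chains$delta))),
    class = "summary.car_fit")
}

#' @method print summary.car_fit
#' @export
print.summary.car_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPrevalence ratios (posterior median, 95% CrI):\n")
  tab <- x$coefficients
  disp <- data.frame(
    variable = tab$variable,
    PR = sprintf("%.2f", tab$PR),
    CrI = ifelse(tab$reference, "(reference)",
                 sprintf("(%.2f-%.2f)", tab$PR_lower, tab$PR_upper)),
    geweke_z = ifelse(is.na(tab$geweke_z), "", sprintf("%.2f", tab$geweke_z)))
  print(disp, row.names = FALSE)
  cat("\nVariance parameters (posterior medians): ",
      paste(names(x$variance), sprintf("%.4f", x$variance),
            sep = " = ", collapse = ", "), "\n", sep = "")
  if (!is.null(x$waic)) print(x$waic)
  invisible(x)
}

#' Trace plots of the main model parameters
#' @param x a `car_fit`.
#' @param pars parameter names to plot (default: all regression
#'   coefficients plus the variance parameters).
#' @param ... passed to [graphics::plot()].
#' @export
plot.car_fit <- function(x, pars = NULL, ...) {
  ch <- x$chains
  series <- as.list(as.data.frame(ch$beta))
  if (x$model == "leroux") {
    series$tau2 <- ch$tau2; series$rho <- ch$rho
  } else {
    series$sigma2 <- ch$sigma2; series$delta <- ch$delta
  }
  if (!is.null(pars)) series <- series[pars]
  old <- graphics::par(mfrow = c(ceiling(length(series) / 2), 2),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(series))
    graphics::plot(series[[nm]], type = "l", xlab = "retained draw",
                   ylab = nm, main = nm, ...)
  invisible(x)
}

#' Simulate counts from the posterior predictive distribution
#' @param object a `car_fit`.
#' @param nsim number of posterior-predictive replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix, areas by `nsim`.
#' @export
simulate.car_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ch <- object$chains
  S <- nrow(ch$beta)
  n <- length(object$y)
  idx <- sample.int(S, nsim, replace = nsim > S)
  out <- matrix(0L, n, nsim)
  for (k in seq_len(nsim)) {
    s <- idx[k]
    eta <- drop(object$X %*% ch$beta[s, ])
    eta <- eta + if (object$model == "leroux") ch$phi[s, ]
                 else ch$lambda[s, ch$Z[s, ]] + ch$theta[s, ]
    out[, k] <- stats::rpois(n, exp(object$offset + eta))
  }
  out
}
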